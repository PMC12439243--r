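#' Plot a simulated record
#'
#' Draws the real channel of the spectrum against ppm (decreasing left to
#' right, the conventional display), optionally overlaying the retained
#' ground-truth baseline and residual-water components.
#'
#' @param x A `sim_record`.
#' @param ground_truth Overlay stored nuisance ground truths.
#' @param xlim ppm window (plotted reversed); defaults to the full axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sim_record <- function(x, ground_truth = TRUE, xlim = NULL, ...) {
  spec <- if (is.null(x$spectrum)) to_spectrum(x$fid, x$axes) else x$spectrum
  ppm <- x$axes$ppm
  if (is.null(xlim)) xlim <- rev(range(ppm))
  graphics::plot(ppm, Re(spec), type = "l", xlim = xlim,
                 xlab = "chemical shift (ppm)", ylab = "real signal (a.u.)",
                 ...)
  if (ground_truth) {
    gt <- x$ground_truth
    if (!is.null(gt$baseline)) {
      graphics::lines(ppm, Re(gt$baseline), col = "darkgreen")
    }
    if (!is.null(gt$water)) {
      graphics::lines(ppm, Re(gt$water), col = "purple")
    }
  }
  invisible(x)
}

#' Plot a basis set
#'
#' One magnitude spectrum per basis function, stacked, ppm reversed.
#'
#' @param x An `mrs_basis`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrs_basis <- function(x, ...) {
  ax <- basis_axes(x)
  specs <- sapply(x$names, function(nm) Mod(to_spectrum(x$fids[, nm], ax)))
  offset <- max(specs) * 1.1
  graphics::plot(NA, xlim = rev(range(ax$ppm)),
                 ylim = c(0, offset * length(x$names)),
                 xlab = "chemical shift (ppm)", ylab = "", yaxt = "n", ...)
  for (i in seq_along(x$names)) {
    graphics::lines(ax$ppm, specs[, i] + (i - 1) * offset)
    graphics::text(max(ax$ppm), (i - 0.5) * offset, x$names[i], pos = 4,
                   xpd = NA, cex = 0.8)
  }
  invisible(x)
}
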
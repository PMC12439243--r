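#' Construct a metabolite basis set
#'
#' A basis set bundles one complex time-domain signal (FID) per basis
#' function — metabolite, macromolecule or lipid — together with the
#' acquisition metadata needed to interpret it. Each basis FID is taken to
#' represent the signal from 1.0 mM of its compound, so amplitude scaling
#' factors can be read directly as millimolar concentrations.
#'
#' @param fids Complex matrix, `n_points` rows by one column per basis
#'   function; column names identify the basis functions.
#' @param spectral_width Spectral width, Hz.
#' @param f0 Spectrometer frequency, MHz.
#' @param ppm_ref Chemical-shift reference, ppm.
#' @param group Character vector, one of `"metabolite"` or `"mm_lipid"` per
#'   basis function (recycled if length 1). Drives which group-level Gaussian
#'   broadening applies.
#' @param meta Free-form list of sequence metadata (e.g. sequence, TE).
#' @return An object of class `mrs_basis`.
#' @seealso [make_toy_basis()], [load_basis()], [save_basis()]
#' @export
new_basis <- function(fids, spectral_width, f0, ppm_ref = 4.65,
                      group = "metabolite", meta = list()) {
  abort_if(!is.matrix(fids) || !is.complex(fids) || nrow(fids) < 2,
           "`fids` must be a complex matrix with >= 2 rows")
  nm <- colnames(fids)
  abort_if(is.null(nm) || anyDuplicated(nm) > 0 || any(nm == ""),
           "`fids` must have unique, non-empty column names")
  abort_if(spectral_width <= 0 || f0 <= 0,
           "`spectral_width` and `f0` must be positive")
  group <- rep_len(as.character(group), ncol(fids))
  abort_if(!all(group %in% c("metabolite", "mm_lipid")),
           "`group` entries must be 'metabolite' or 'mm_lipid'")
  names(group) <- nm
  structure(
    list(names = nm, fids = fids, spectral_width = spectral_width,
         n_points = nrow(fids), f0 = f0, ppm_ref = ppm_ref,
         group = group, meta = meta),
    class = "mrs_basis")
}

#' @export
print.mrs_basis <- function(x, ...) {
  cat(sprintf("<mrs_basis> %d basis functions x %d points, sw %.6g Hz, f0 %.6g MHz\n",
              length(x$names), x$n_points, x$spectral_width, x$f0))
  cat("  ", paste0(x$names, " (", substr(x$group, 1, 3), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Axes matching a basis set's acquisition grid
#' @param basis An `mrs_basis` object.
#' @return The `mrs_axes` for the basis grid.
#' @export
basis_axes <- function(basis) {
  abort_if(!inherits(basis, "mrs_basis"), "`basis` must be an `mrs_basis`")
  make_axes(basis$spectral_width, basis$n_points, basis$f0, basis$ppm_ref)
}

#' Synthesize an analytic toy basis set
#'
#' Builds basis FIDs as sums of damped complex exponentials at user-specified
#' chemical shifts — a stand-in for externally simulated (density-matrix)
#' basis functions, adequate for testing the physics model and for examples.
#' A resonance at shift \eqn{\delta} ppm contributes
#' \eqn{a \exp(-2i\pi(\delta-\mathrm{ppm.ref}) f_0 t)\exp(-d_0 t)}, so the
#' magnitude spectrum of each FID peaks at the requested shifts and the peak
#' heights are proportional to the requested amplitudes. The mild fixed
#' Lorentzian decay `decay` (s^-1) keeps the spectra integrable; it is a
#' documented constant of the generator, not a model parameter.
#'
#' @param peaks Data frame with columns `name`, `group`, `shift` (ppm) and
#'   `amp` (relative amplitude), one row per resonance. A name with no rows
#'   cannot be expressed here; use zero amplitudes for an all-zero FID.
#' @param spectral_width,n_points,f0,ppm_ref Acquisition grid, as
#'   [make_axes()].
#' @param decay Fixed Lorentzian decay rate applied to every resonance, s^-1.
#' @param seed Accepted for interface compatibility; the generator is fully
#'   deterministic and the value is ignored.
#' @return An `mrs_basis` object.
#' @examples
#' b <- make_toy_basis(data.frame(name = "naa", group = "metabolite",
#'                                shift = 2.01, amp = 1))
#' ax <- basis_axes(b)
#' ax$ppm[which.max(Mod(to_spectrum(b$fids[, 1], ax)))] # ~2.01 ppm
#' @export
make_toy_basis <- function(peaks, spectral_width = 2000, n_points = 4096,
                           f0 = 127.7, ppm_ref = 4.65, decay = 2,
                           seed = NULL) {
  abort_if(!is.data.frame(peaks) || nrow(peaks) < 1 ||
             !all(c("name", "group", "shift", "amp") %in% names(peaks)),
           "`peaks` must be a data.frame with columns name, group, shift, amp")
  abort_if(decay < 0, "`decay` must be >= 0")
  ax <- make_axes(spectral_width, n_points, f0, ppm_ref)
  span <- range(ax$ppm)
  abort_if(any(peaks$shift < span[1] | peaks$shift > span[2]),
           sprintf("peak shifts must lie within the ppm span [%.3f, %.3f]",
                   span[1], span[2]))
  nms <- unique(as.character(peaks$name))
  fids <- sapply(nms, function(nm) {
    rows <- peaks[peaks$name == nm, , drop = FALSE]
    fid <- complex(real = numeric(ax$n_points))
    for (i in seq_len(nrow(rows))) {
      f_hz <- (rows$shift[i] - ppm_ref) * f0
      fid <- fid + rows$amp[i] * exp(-2i * pi * f_hz * ax$t)
    }
    fid * exp(-decay * ax$t)
  })
  grp <- vapply(nms, function(nm) as.character(peaks$group[peaks$name == nm][1]),
                character(1))
  new_basis(fids, spectral_width, f0, ppm_ref, group = grp,
            meta = list(source = "toy", decay = decay))
}

#' A small default toy brain basis
#'
#' Singlet-style stand-ins for the major short-echo brain resonances (NAA,
#' total creatine, choline, myo-inositol) plus one macromolecule feature,
#' with relative amplitudes loosely reflecting healthy-brain concentration
#' ratios. Intended for examples and tests.
#'
#' @inheritParams make_toy_basis
#' @return An `mrs_basis` object.
#' @export
toy_brain_basis <- function(spectral_width = 2000, n_points = 4096,
                            f0 = 127.7, ppm_ref = 4.65) {
  peaks <- data.frame(
    name  = c("naa", "cr", "cr", "cho", "mi", "mm09"),
    group = c("metabolite", "metabolite", "metabolite", "metabolite",
              "metabolite", "mm_lipid"),
    shift = c(2.01, 3.03, 3.91, 3.19, 3.56, 0.90),
    amp   = c(1.00, 0.55, 0.45, 0.30, 0.45, 0.35))
  make_toy_basis(peaks, spectral_width, n_points, f0, ppm_ref)
}

#' Save or load a basis set
#'
#' The on-disk form is the package's keyed container: a JSON document whose
#' complex arrays are base64-encoded little-endian IEEE-754 doubles
#' (interleaved real/imaginary), so save/load round-trips are bit-exact.
#'
#' @param basis An `mrs_basis` object.
#' @param path File path (conventionally `.json`).
#' @return `load_basis()` returns the `mrs_basis`; `save_basis()` returns
#'   `path` invisibly.
#' @export
save_basis <- function(basis, path) {
  abort_if(!inherits(basis, "mrs_basis"), "`basis` must be an `mrs_basis`")
  obj <- list(
    container = "mrsim_basis", version = 1L,
    names = basis$names,
    spectral_width = basis$spectral_width,
    n_points = basis$n_points,
    f0 = basis$f0,
    ppm_ref = basis$ppm_ref,
    group = as.list(basis$group),
    meta = basis$meta,
    fids = lapply(basis$names, function(nm) encode_doubles(basis$fids[, nm])))
  names(obj$fids) <- basis$names
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("names", "spectral_width", "n_points", "f0", "ppm_ref",
                "group", "fids")
  missing <- setdiff(required, names(obj))
  abort_if(length(missing) > 0,
           sprintf("malformed basis container: missing field(s) %s",
                   paste(missing, collapse = ", ")))
  nms <- as.character(obj$names)
  fids <- sapply(nms, function(nm) decode_doubles(obj$fids[[nm]], complex = TRUE))
  new_basis(fids, as.numeric(obj$spectral_width), as.numeric(obj$f0),
            as.numeric(obj$ppm_ref),
            group = unlist(obj$group)[nms],
            meta = if (is.null(obj$meta)) list() else obj$meta)
}
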
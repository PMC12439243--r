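#' Per-transient coil/average parameters
#'
#' Describes how one noiseless FID is expanded into `C` transients —
#' individual receive-coil elements or signal averages. Unset per-transient
#' vectors are sampled from the defaults: sensitivities from the clamped
#' normal of [sample_coil_weights()]; SNR scaling factors from a narrow
#' normal `N(1, snr_sd^2)` clamped positive (maintaining the mean target
#' SNR); frequency drifts from `N(0, df_sd^2)` Hz; zero-order phase drifts
#' from `N(0, dphi_sd^2)` degrees. Coil-type artifacts (sensitivity, SNR)
#' and average-type artifacts (drifts) can be disabled independently by
#' passing fixed vectors.
#'
#' @param C Number of transients (>= 1).
#' @param sens,snr_scale,df,dphi Optional fixed per-transient vectors
#'   (length `C`): sensitivity weights, SNR scale factors, frequency drifts
#'   (Hz), phase drifts (degrees).
#' @param sens_mean,sens_sd Parameters of the sensitivity sampler.
#' @param snr_sd Spread of the per-transient SNR scaling factors.
#' @param df_sd,dphi_sd Spreads of the frequency (Hz) and phase (degrees)
#'   drift samplers.
#' @param seed Optional RNG seed for the sampling.
#' @return An object of class `coil_params`.
#' @export
coil_params <- function(C, sens = NULL, snr_scale = NULL, df = NULL,
                        dphi = NULL, sens_mean = 1, sens_sd = 0.5,
                        snr_sd = 0.05, df_sd = 2, dphi_sd = 5, seed = NULL) {
  abort_if(C < 1 || C != round(C), "`C` must be an integer >= 1")
  C <- as.integer(C)
  out <- with_seed(seed, {
    if (is.null(sens)) sens <- sample_coil_weights(C, mean = sens_mean,
                                                   sd = sens_sd)
    if (is.null(snr_scale)) snr_scale <- pmax(stats::rnorm(C, 1, snr_sd), 1e-3)
    if (is.null(df)) df <- stats::rnorm(C, 0, df_sd)
    if (is.null(dphi)) dphi <- stats::rnorm(C, 0, dphi_sd)
    list(sens = sens, snr_scale = snr_scale, df = df, dphi = dphi)
  })
  for (fld in names(out)) {
    abort_if(length(out[[fld]]) != C,
             sprintf("`%s` must have length C = %d", fld, C))
  }
  structure(c(list(C = C, seed = seed), out), class = "coil_params")
}

#' @export
print.coil_params <- function(x, ...) {
  cat(sprintf("<coil_params> C = %d, sens [%.2f, %.2f], df sd %.2g Hz\n",
              x$C, min(x$sens), max(x$sens), stats::sd(x$df)))
  invisible(x)
}

#' Sample coil sensitivity weights
#'
#' Default sensitivity sampler: draws from a Gaussian with mean 1.0 and
#' standard deviation 0.5, then clamps to the range \[0, 2\]. The clamping is
#' symmetric about the centre, so the expected weight remains 1.0.
#'
#' @param C Number of weights.
#' @param mean,sd Parameters of the Gaussian (`sd = 0` yields all-`mean`).
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `C` in `[0, 2]`.
#' @export
sample_coil_weights <- function(C, mean = 1, sd = 0.5, seed = NULL) {
  abort_if(C < 1, "`C` must be >= 1")
  abort_if(sd < 0, "`sd` must be >= 0")
  with_seed(seed, pmin(pmax(stats::rnorm(C, mean, sd), 0), 2))
}

#' Expand a clean FID into noisy coil/average transients
#'
#' Implements the coil-artifact stage of the model:
#' \deqn{transient_c(t) = sens_c\, fid(t)\, e^{-2i\pi\,\Delta f_c t}\,
#'   e^{-i\,\Delta\phi_c \pi/180} + noise_c(t)}
#' Each transient's noise targets an SNR of `(snr / sqrt(C)) * snr_scale_c`
#' — the target linear SNR scaled down by the square root of the number of
#' transients — so that averaging the `C` transients recovers `snr`. Noise
#' vectors are independent across transients by default; `correlated = TRUE`
#' applies the single-vector channel correlation of [add_noise()] within
#' each transient.
#'
#' @param clean_fid Pre-noise complex FID (noise is deferred from
#'   [simulate_spectrum()] at the transient stage).
#' @param snr Target linear SNR of the combined spectrum; `NULL` disables
#'   noise.
#' @param ref_peak_height Clean reference peak height defining the SNR.
#' @param cp A [coil_params()].
#' @param axes The FID's `mrs_axes`.
#' @param correlated Correlate real/imaginary noise channels.
#' @return Complex matrix with `C` rows (one transient per row).
#' @export
make_transients <- function(clean_fid, snr, ref_peak_height, cp, axes,
                            correlated = FALSE) {
  check_signal(clean_fid, axes)
  abort_if(!inherits(cp, "coil_params"), "`cp` must be a `coil_params`")
  out <- matrix(0i, nrow = cp$C, ncol = axes$n_points)
  for (cc in seq_len(cp$C)) {
    tr <- cp$sens[cc] * clean_fid *
      exp(-2i * pi * cp$df[cc] * axes$t) *
      exp(-1i * cp$dphi[cc] * pi / 180)
    if (!is.null(snr)) {
      snr_c <- (snr / sqrt(cp$C)) * cp$snr_scale[cc]
      tr <- add_noise(tr, snr_c, ref_peak_height, axes,
                      correlated = correlated)$fid
    }
    out[cc, ] <- tr
  }
  out
}

#' Combine transients into a single FID
#'
#' `"average"` forms the weighted mean `sum(w_c x_c) / sum(w_c)` (the
#' recommended combination); `"sum"` forms the weighted sum after
#' normalizing the weights by their total, preserving the overall amplitude
#' — numerically the same contract: combining `C` identical noiseless
#' transients with equal weights returns the input in both modes.
#'
#' @param transients Complex matrix, `C` rows.
#' @param weights Numeric weights, length `C` (default equal).
#' @param mode `"average"` or `"sum"`.
#' @return Combined complex FID.
#' @export
combine_transients <- function(transients, weights = NULL,
                               mode = c("average", "sum")) {
  mode <- match.arg(mode)
  abort_if(!is.matrix(transients), "`transients` must be a matrix (C x n)")
  C <- nrow(transients)
  if (is.null(weights)) weights <- rep(1, C)
  abort_if(length(weights) != C, "`weights` must have one entry per transient")
  total <- sum(weights)
  abort_if(total == 0, "`weights` must not sum to zero")
  as.vector((weights / total) %*% transients)
}

#' Remove known drifts from transients
#'
#' Applies the exact inverse of the frequency and phase drifts recorded in
#' the coil parameters — ground-truth removal, not estimation. With noise
#' off, aligned transients differ only by their sensitivity scaling.
#'
#' @param transients Complex matrix, `C` rows.
#' @param cp The [coil_params()] used to generate them.
#' @param axes The matching `mrs_axes`.
#' @return Aligned complex matrix.
#' @export
remove_known_drifts <- function(transients, cp, axes) {
  abort_if(!is.matrix(transients) || nrow(transients) != cp$C,
           "`transients` must be a C x n matrix matching `cp`")
  abort_if(ncol(transients) != axes$n_points, "transient length mismatch")
  out <- transients
  for (cc in seq_len(cp$C)) {
    out[cc, ] <- transients[cc, ] *
      exp(+2i * pi * cp$df[cc] * axes$t) *
      exp(+1i * cp$dphi[cc] * pi / 180)
  }
  out
}
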
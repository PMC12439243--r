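#' Time and chemical-shift axes for an acquisition grid
#'
#' Builds the paired time/frequency axes that every other operation consumes.
#' Time runs `t[k] = (k-1) / spectral_width` seconds. The frequency axis is the
#' fftshifted DFT grid in Hz; the chemical-shift axis is
#' `ppm = ppm_ref + f / f0`, so the zero-frequency bin maps exactly to
#' `ppm_ref` (the water reference, 4.65 ppm by default). The ppm vector is
#' stored ascending; display functions reverse it, following the convention
#' that spectra are drawn with ppm decreasing left to right.
#'
#' @param spectral_width Spectral width (sampling rate) in Hz.
#' @param n_points Number of complex time-domain points (>= 2).
#' @param f0 Spectrometer frequency in MHz.
#' @param ppm_ref Chemical-shift reference in ppm mapped to 0 Hz offset.
#' @return An object of class `mrs_axes`: a list with `t` (s), `f` (Hz),
#'   `ppm`, and the four acquisition scalars.
#' @examples
#' ax <- make_axes(2000, 4096, 127.7)
#' ax$t[2]                      # dwell time, 5e-4 s
#' diff(range(ax$ppm))          # ppm span = spectral_width / f0
#' @export
make_axes <- function(spectral_width, n_points, f0, ppm_ref = 4.65) {
  abort_if(!is.numeric(spectral_width) || spectral_width <= 0,
           "`spectral_width` must be a positive number (Hz)")
  abort_if(!is.numeric(n_points) || n_points < 2 || n_points != round(n_points),
           "`n_points` must be an integer >= 2")
  abort_if(!is.numeric(f0) || f0 <= 0, "`f0` must be positive (MHz)")
  abort_if(!is.numeric(ppm_ref) || ppm_ref <= 0, "`ppm_ref` must be positive")
  n <- as.integer(n_points)
  df <- spectral_width / n
  f <- (seq_len(n) - 1 - floor(n / 2)) * df
  structure(
    list(t = (seq_len(n) - 1) / spectral_width,
         f = f,
         ppm = ppm_ref + f / f0,
         spectral_width = spectral_width,
         n_points = n,
         f0 = f0,
         ppm_ref = ppm_ref),
    class = "mrs_axes")
}

#' @export
print.mrs_axes <- function(x, ...) {
  cat(sprintf(
    "<mrs_axes> %d points, sw %.6g Hz, f0 %.6g MHz, ppm [%.3f, %.3f] (ref %.3f)\n",
    x$n_points, x$spectral_width, x$f0, min(x$ppm), max(x$ppm), x$ppm_ref))
  invisible(x)
}

#' Fourier transforms between FID and spectrum
#'
#' `to_spectrum()` maps a complex FID to the complex spectrum on the
#' fftshifted frequency grid of its axes; `from_spectrum()` inverts it
#' (round-trip is exact to rounding). The convention is chosen so that a
#' resonance evolving as `exp(-2i * pi * f * t)` — the rotating-frame sign
#' used throughout the physics model — appears at `+f` Hz on the frequency
#' axis, i.e. higher ppm for downfield resonances.
#'
#' @param fid,spectrum Complex vector matching `axes$n_points`.
#' @param axes An `mrs_axes` object (used for length validation only).
#' @return A complex vector of the same length.
#' @examples
#' ax <- make_axes(1000, 256, 127.7)
#' fid <- exp(-2i * pi * 100 * ax$t)
#' ax$f[which.max(Mod(to_spectrum(fid, ax)))]  # 100 Hz
#' @export
to_spectrum <- function(fid, axes) {
  check_signal(fid, axes)
  fftshift_vec(stats::fft(fid, inverse = TRUE))
}

#' @rdname to_spectrum
#' @export
from_spectrum <- function(spectrum, axes) {
  check_signal(spectrum, axes)
  stats::fft(ifftshift_vec(spectrum)) / length(spectrum)
}

#' @noRd
check_signal <- function(x, axes) {
  abort_if(!inherits(axes, "mrs_axes"), "`axes` must be an `mrs_axes` object")
  abort_if(length(x) != axes$n_points,
           sprintf("signal length %d does not match axes n_points %d",
                   length(x), axes$n_points))
  invisible(x)
}
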
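#' Apodize an FID
#'
#' Multiplies the FID pointwise by `exp(-t * TL)` with `TL` the apodization
#' frequency in s^-1 (Hz-equivalent, as conventionally quoted). This trades
#' resolution for SNR and adds Lorentzian broadening of `TL/pi` Hz to every
#' line.
#'
#' @param fid Complex FID.
#' @param tl Apodization frequency `TL` (>= 0); 0 is the identity.
#' @param axes The FID's `mrs_axes`.
#' @return Apodized complex FID.
#' @export
apodize <- function(fid, tl, axes) {
  check_signal(fid, axes)
  abort_if(tl < 0, "`tl` must be >= 0")
  fid * exp(-axes$t * tl)
}

#' Zero-fill an FID
#'
#' Appends zeros up to `len` points, interpolating the spectrum onto a
#' denser grid without adding information (total spectral power is
#' conserved).
#'
#' @param fid Complex FID.
#' @param len Target length (>= current length).
#' @param axes The FID's `mrs_axes`.
#' @return A list with the padded `fid` and the new `axes` (same spectral
#'   width, `len` points).
#' @export
zero_fill <- function(fid, len, axes) {
  check_signal(fid, axes)
  abort_if(len < axes$n_points,
           "`len` must be >= the current number of points")
  abort_if(len != round(len), "`len` must be an integer")
  list(fid = c(fid, complex(real = numeric(len - axes$n_points))),
       axes = make_axes(axes$spectral_width, len, axes$f0, axes$ppm_ref))
}

#' Crop and resample a spectrum onto a new ppm grid
#'
#' Interpolates the real and imaginary channels separately with the
#' modified-Akima piecewise cubic ([interp_makima()]) — exact at the
#' original nodes, reproduces straight lines, and tempers overshoot — onto
#' `out_points` evenly spaced ppm values spanning `ppm_window`.
#'
#' @param spectrum Complex spectrum on the axes' ppm grid.
#' @param axes The spectrum's `mrs_axes`.
#' @param ppm_window Two increasing ppm values inside the axes span.
#' @param out_points Output length (>= 2).
#' @return A list with `spectrum` (complex, length `out_points`) and `ppm`
#'   (the new grid).
#' @export
crop_resample <- function(spectrum, axes, ppm_window, out_points) {
  check_signal(spectrum, axes)
  abort_if(length(ppm_window) != 2 || ppm_window[2] <= ppm_window[1],
           "`ppm_window` must be two increasing ppm values")
  abort_if(ppm_window[1] < min(axes$ppm) || ppm_window[2] > max(axes$ppm),
           "`ppm_window` must lie inside the axes ppm span")
  abort_if(out_points < 2, "`out_points` must be >= 2")
  grid <- seq(ppm_window[1], ppm_window[2], length.out = out_points)
  re <- interp_makima(axes$ppm, Re(spectrum), grid)
  im <- interp_makima(axes$ppm, Im(spectrum), grid)
  list(spectrum = complex(real = re, imaginary = im), ppm = grid)
}

#' Post-process a simulated record
#'
#' Convenience wrapper for the processing chain: optional apodization,
#' optional zero-fill, Fourier transform, optional crop/resample. Operates
#' on the record's combined FID (transient records must be combined first).
#'
#' @param record A `sim_record`.
#' @param tl Apodization frequency, Hz-equivalent (0 skips).
#' @param len Zero-fill length (`NULL` skips).
#' @param ppm_window,out_points Crop/resample request (`NULL` skips).
#' @return A list with `spectrum`, `ppm`, `fid` and `axes` after processing.
#' @export
process_record <- function(record, tl = 0, len = NULL, ppm_window = NULL,
                           out_points = NULL) {
  abort_if(!inherits(record, "sim_record"), "`record` must be a `sim_record`")
  fid <- record$fid
  axes <- record$axes
  if (tl > 0) fid <- apodize(fid, tl, axes)
  if (!is.null(len)) {
    zf <- zero_fill(fid, len, axes)
    fid <- zf$fid
    axes <- zf$axes
  }
  spec <- to_spectrum(fid, axes)
  ppm <- axes$ppm
  if (!is.null(ppm_window)) {
    cr <- crop_resample(spec, axes,  ppm_window,
                        if (is.null(out_points)) axes$n_points else out_points)
    spec <- cr$spectrum
    ppm <- cr$ppm
  }
  list(spectrum = spec, ppm = ppm, fid = fid, axes = axes)
}
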
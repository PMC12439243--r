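#' Parameters of the spectral physics model
#'
#' One object holds every scalar of the single-record physics model:
#' per-metabolite amplitudes (mM-equivalent, since each basis FID represents
#' 1.0 mM), per-metabolite Lorentzian decays, one Gaussian decay per group
#' (metabolites vs macromolecules/lipids — together the Voigt lineshape),
#' per-metabolite plus global frequency shifts, zero-/first-order phases,
#' eddy-current amplitude and time constant, the target spectral SNR and its
#' reference metabolite, and the optional B0 map and nuisance profiles.
#'
#' @param amplitude Named numeric vector of scaling factors `M_n` (>= 0), one
#'   per basis function; a single unnamed value is recycled.
#' @param lorentz_d Named numeric vector of Lorentzian decays `d_n`, s^-1
#'   (>= 0); a single value is recycled. A pure-Gaussian lineshape is
#'   obtained with `lorentz_d = 0`, a pure-Lorentzian with the Gaussian
#'   decays at 0.
#' @param gauss_met,gauss_mm Gaussian decay `g`, s^-2, applied to the
#'   metabolite group and to the macromolecule/lipid group respectively.
#' @param fshift Named numeric vector of per-metabolite frequency shifts, Hz
#'   (recycled); `fshift_global_met` is added to every metabolite,
#'   `fshift_global_nuis` applies only to the nuisance signals.
#' @param phi0 Zero-order phase, degrees.
#' @param phi1 First-order phase, degrees per ppm, pivoting at the axes'
#'   `ppm_ref`.
#' @param eddy_a0,eddy_tc Eddy-current amplitude (Hz) and time constant (s);
#'   `eddy_tc` must be positive whenever `eddy_a0 != 0`.
#' @param snr Target linear spectral SNR (> 0), or `NULL` for noise-free.
#' @param snr_ref Name of the basis function whose clean real-spectrum peak
#'   defines the SNR; `NULL` uses the full clean metabolite sum.
#' @param noise_correlated If `TRUE`, real/imaginary noise derive from a
#'   single sampled vector via [complexify()] instead of independent draws.
#' @param b0 Optional [make_b0_map()] result.
#' @param baseline_cfg,water_cfg Optional [walk_config()] profiles for the
#'   baseline and residual-water generators.
#' @return An object of class `model_params`.
#' @export
model_params <- function(amplitude = 1, lorentz_d = 0, gauss_met = 0,
                         gauss_mm = 0, fshift = 0,
                         fshift_global_met = 0, fshift_global_nuis = 0,
                         phi0 = 0, phi1 = 0,
                         eddy_a0 = 0, eddy_tc = 0.15,
                         snr = NULL, snr_ref = NULL,
                         noise_correlated = FALSE,
                         b0 = NULL, baseline_cfg = NULL, water_cfg = NULL) {
  abort_if(any(amplitude < 0), "`amplitude` entries must be >= 0")
  abort_if(any(lorentz_d < 0), "`lorentz_d` entries must be >= 0")
  abort_if(gauss_met < 0 || gauss_mm < 0, "Gaussian decays must be >= 0")
  abort_if(eddy_a0 != 0 && eddy_tc <= 0,
           "`eddy_tc` must be > 0 when `eddy_a0` is nonzero")
  abort_if(!is.null(snr) && snr <= 0, "`snr` must be > 0")
  abort_if(!is.null(b0) && !inherits(b0, "b0_map"), "`b0` must be a `b0_map`")
  structure(list(amplitude = amplitude, lorentz_d = lorentz_d,
                 gauss_met = gauss_met, gauss_mm = gauss_mm,
                 fshift = fshift,
                 fshift_global_met = fshift_global_met,
                 fshift_global_nuis = fshift_global_nuis,
                 phi0 = phi0, phi1 = phi1,
                 eddy_a0 = eddy_a0, eddy_tc = eddy_tc,
                 snr = snr, snr_ref = snr_ref,
                 noise_correlated = noise_correlated,
                 b0 = b0, baseline_cfg = baseline_cfg, water_cfg = water_cfg),
            class = "model_params")
}

# Resolve a possibly-scalar, possibly-partially-named per-metabolite
# parameter vector against the basis names.
#' @noRd
per_name <- function(value, nms, what) {
  if (is.null(names(value))) {
    abort_if(length(value) != 1 && length(value) != length(nms),
             sprintf("`%s` must be scalar or one value per basis function", what))
    out <- rep_len(value, length(nms))
    names(out) <- nms
    return(out)
  }
  missing <- setdiff(nms, names(value))
  abort_if(length(missing) > 0,
           sprintf("`%s` is missing entries for: %s", what,
                   paste(missing, collapse = ", ")))
  value[nms]
}

#' Scale, broaden and shift each basis function
#'
#' Applies the amplitude and lineshape terms of the physics model to every
#' basis FID:
#' \deqn{out_n(t) = M_n\, fid_n(t)\, e^{-(d_n t + g\,t^2)}\,
#'   e^{-2i\pi\,\Delta f_n t}}
#' with `g` resolved per group (`gauss_met` or `gauss_mm`) and
#' \eqn{\Delta f_n} the per-metabolite shift plus the global metabolite
#' shift. A Lorentzian decay `d` alone gives a lineshape of FWHM `d/pi` Hz.
#'
#' @param basis An `mrs_basis`.
#' @param p A [model_params()].
#' @param axes The basis axes.
#' @return Complex matrix, one shaped FID per column.
#' @export
scale_and_shape <- function(basis, p, axes) {
  abort_if(!inherits(basis, "mrs_basis"), "`basis` must be an `mrs_basis`")
  abort_if(!inherits(p, "model_params"), "`p` must be a `model_params`")
  m <- per_name(p$amplitude, basis$names, "amplitude")
  d <- per_name(p$lorentz_d, basis$names, "lorentz_d")
  df <- per_name(p$fshift, basis$names, "fshift") + p$fshift_global_met
  g <- ifelse(basis$group[basis$names] == "mm_lipid", p$gauss_mm, p$gauss_met)
  t <- axes$t
  out <- sapply(basis$names, function(nm) {
    m[nm] * basis$fids[, nm] *
      exp(-(d[nm] * t + g[nm] * t^2)) *
      exp(-2i * pi * df[nm] * t)
  })
  out
}

#' Sum per-metabolite FIDs into one FID
#'
#' Plain linear summation over the basis-function axis.
#'
#' @param fids Complex matrix of per-name FIDs (columns).
#' @return Complex vector.
#' @export
sum_components <- function(fids) {
  abort_if(!is.matrix(fids), "`fids` must be a matrix")
  rowSums(fids)
}

#' Add Gaussian noise calibrated to a target spectral SNR
#'
#' Spectral SNR is defined as the maximum peak height of the real spectrum
#' component divided by one standard deviation of the noise, so the noise
#' level is `sigma = ref_peak_height / snr`, defined per frequency-domain
#' bin. Real and imaginary channels are independent `N(0, sigma^2)` draws
#' unless `correlated`, in which case a single real vector is sampled and
#' its imaginary partner built with [complexify()]. The noise is generated
#' in the frequency domain (where the SNR definition lives) and injected
#' into the FID via the inverse transform; with the package's unnormalized
#' conventions the equivalent time-domain noise standard deviation is
#' `sigma / sqrt(n_points)`.
#'
#' @param fid Complex FID to perturb.
#' @param snr Target linear SNR (> 0).
#' @param ref_peak_height Clean real-spectrum maximum of the reference
#'   metabolite (or metabolite sum).
#' @param correlated Sample one vector for both channels.
#' @param seed Optional RNG seed.
#' @param axes The FID's `mrs_axes`.
#' @return A list with `fid` (noisy), `noise_fid` and `noise_spectrum` (the
#'   exact realization added, in both domains) and `sigma`.
#' @export
add_noise <- function(fid, snr, ref_peak_height, axes, correlated = FALSE,
                      seed = NULL) {
  check_signal(fid, axes)
  abort_if(!is.numeric(snr) || snr <= 0, "`snr` must be > 0")
  abort_if(ref_peak_height <= 0, "`ref_peak_height` must be > 0")
  sigma <- ref_peak_height / snr
  n <- axes$n_points
  noise_spec <- with_seed(seed, {
    if (correlated) {
      complexify(stats::rnorm(n, 0, sigma))
    } else {
      complex(real = stats::rnorm(n, 0, sigma),
              imaginary = stats::rnorm(n, 0, sigma))
    }
  })
  noise_fid <- from_spectrum(noise_spec, axes)
  list(fid = fid + noise_fid, noise_fid = noise_fid,
       noise_spectrum = noise_spec, sigma = sigma)
}

#' Zero-order phase
#'
#' Global complex rotation `f(t) * exp(-i * phi0 * pi/180)`; magnitudes are
#' unchanged everywhere.
#'
#' @param fid Complex FID (or spectrum; the operator is domain-agnostic).
#' @param phi0_deg Phase in degrees.
#' @return Rotated complex vector.
#' @export
apply_phi0 <- function(fid, phi0_deg) {
  fid * exp(-1i * phi0_deg * pi / 180)
}

#' First-order (linear) phase
#'
#' Frequency-dependent rotation applied in the spectral domain:
#' `F(w) * exp(-i * phi1 * pi/180 * (ppm - ppm_ref))`. The bin at `ppm_ref`
#' (the water reference, fixed at 4.65 ppm by default) is the pivot and is
#' left unchanged for any `phi1`; magnitudes are unchanged everywhere.
#'
#' @param spectrum Complex spectrum on the axes' ppm grid.
#' @param phi1_deg_per_ppm Linear phase slope, degrees per ppm.
#' @param axes The spectrum's `mrs_axes`.
#' @param ppm_ref Pivot, defaults to the axes' reference.
#' @return Rotated complex spectrum.
#' @export
apply_phi1 <- function(spectrum, phi1_deg_per_ppm, axes,
                       ppm_ref = axes$ppm_ref) {
  check_signal(spectrum, axes)
  spectrum * exp(-1i * phi1_deg_per_ppm * pi / 180 * (axes$ppm - ppm_ref))
}

#' First-order eddy-current distortion
#'
#' Two-parameter model of gradient-switching-induced phase errors:
#' `out(t) = fid(t) * exp(-2i * pi * A0 * exp(-t/tc) * t)`. The FID
#' magnitude is pointwise unchanged. A time constant much longer than the
#' readout degenerates to a simple global frequency shift of `+A0` Hz; short
#' time constants distort the lineshape.
#'
#' @param fid Complex FID.
#' @param a0_hz Amplitude `A0`, Hz (`0` bypasses the operator).
#' @param tc_s Time constant, s; must be positive when `a0_hz != 0`.
#' @param axes The FID's `mrs_axes`.
#' @return Distorted complex FID.
#' @export
apply_eddy <- function(fid, a0_hz, tc_s, axes) {
  check_signal(fid, axes)
  if (a0_hz == 0) return(fid)
  abort_if(tc_s <= 0, "`tc_s` must be > 0 when `a0_hz` is nonzero")
  fid * exp(-2i * pi * a0_hz * exp(-axes$t / tc_s) * axes$t)
}

#' Simulate one spectral record through the full physics model
#'
#' Pipeline (mirroring the acquisition chain): scale/lineshape/per-name
#' shifts, B0 sub-voxel ensemble, summation, addition of baseline and
#' residual water (carrying the nuisance global frequency shift), noise,
#' zero-order phase (time domain), first-order phase (frequency domain),
#' eddy currents. When `stage = "transients"` noise is deferred to
#' [make_transients()] and the returned record holds the pre-noise FID plus
#' the generated transient matrix. Every stochastic component actually used
#' is retained in `ground_truth`, so the output can be recomposed from its
#' parts (see [reconstruct_record()]).
#'
#' @param basis An `mrs_basis`.
#' @param p A [model_params()].
#' @param seed Optional seed governing noise and nuisance draws (nuisance
#'   profile seeds, when set in their configs, take precedence).
#' @param stage `"fid"` (time-domain record), `"processed"` (also stores the
#'   spectrum), or `"transients"` (expand into coil/average transients;
#'   requires `coil`).
#' @param coil A [coil_params()] when `stage = "transients"`.
#' @return An object of class `sim_record` with fields `fid`, `spectrum`,
#'   `transients`, `axes`, `stage` and `ground_truth`.
#' @export
simulate_spectrum <- function(basis, p = model_params(), seed = NULL,
                              stage = c("processed", "fid", "transients"),
                              coil = NULL) {
  stage <- match.arg(stage)
  abort_if(stage == "transients" && is.null(coil),
           "`coil` parameters are required when stage = 'transients'")
  axes <- basis_axes(basis)
  with_seed(seed, {
    shaped <- scale_and_shape(basis, p, axes)
    metab_fid <- sum_components(shaped)
    if (!is.null(p$b0)) metab_fid <- apply_b0(metab_fid, p$b0, axes)
    clean_spec <- to_spectrum(metab_fid, axes)

    ref_level <- max(Mod(clean_spec))
    baseline <- water <- NULL
    nuis_fid <- complex(real = numeric(axes$n_points))
    if (!is.null(p$baseline_cfg)) {
      baseline <- make_baseline(p$baseline_cfg, axes, ref_level = ref_level)
    }
    if (!is.null(p$water_cfg)) {
      water <- make_residual_water(p$water_cfg, axes, ref_level = ref_level)
    }
    if (!is.null(baseline) || !is.null(water)) {
      nuis_spec <- Reduce(`+`, Filter(Negate(is.null), list(baseline, water)))
      nuis_fid <- from_spectrum(nuis_spec, axes) *
        exp(-2i * pi * p$fshift_global_nuis * axes$t)
    }
    fid <- metab_fid + nuis_fid

    ref_peak <- snr_reference_height(basis, p, axes)
    noise <- NULL
    if (!is.null(p$snr) && stage != "transients") {
      noise <- add_noise(fid, p$snr, ref_peak, axes,
                         correlated = p$noise_correlated)
      fid <- noise$fid
    }

    fid <- apply_phi0(fid, p$phi0)
    spec <- apply_phi1(to_spectrum(fid, axes), p$phi1, axes)
    fid <- from_spectrum(spec, axes)
    fid <- apply_eddy(fid, p$eddy_a0, p$eddy_tc, axes)
    spec <- to_spectrum(fid, axes)

    transients <- NULL
    if (stage == "transients") {
      transients <- make_transients(fid, p$snr, ref_peak, coil, axes)
    }

    structure(
      list(fid = fid, spectrum = if (stage == "fid") NULL else spec,
           transients = transients, axes = axes, stage = stage,
           ground_truth = list(
             metab_fid = metab_fid, baseline = baseline, water = water,
             nuisance_fid = nuis_fid,
             noise_fid = if (is.null(noise)) NULL else noise$noise_fid,
             noise_sigma = if (is.null(noise)) NULL else noise$sigma,
             ref_peak_height = ref_peak, ref_level = ref_level,
             b0 = p$b0, params = p, coil = coil, seed = seed)),
      class = "sim_record")
  })
}

# Maximum real-spectrum height of the designated SNR reference metabolite
# (its clean, shaped, B0-free signal), or of the clean metabolite sum.
#' @noRd
snr_reference_height <- function(basis, p, axes) {
  shaped <- scale_and_shape(basis, p, axes)
  x <- if (is.null(p$snr_ref)) {
    sum_components(shaped)
  } else {
    abort_if(!(p$snr_ref %in% basis$names),
             sprintf("`snr_ref` '%s' is not a basis function", p$snr_ref))
    shaped[, p$snr_ref]
  }
  max(Re(to_spectrum(x, axes)))
}

#' Recompose a simulated record from its stored ground truth
#'
#' Audit utility: rebuilds the output FID from the retained ground-truth
#' components (metabolite sum, nuisance signals, noise realization) by
#' re-applying the stored phases and eddy currents. Agreement with
#' `record$fid` certifies that the stored components are exactly the ones
#' used.
#'
#' @param record A `sim_record`.
#' @return The recomposed complex FID.
#' @export
reconstruct_record <- function(record) {
  abort_if(!inherits(record, "sim_record"), "`record` must be a `sim_record`")
  gt <- record$ground_truth
  p <- gt$params
  axes <- record$axes
  fid <- gt$metab_fid + gt$nuisance_fid
  if (!is.null(gt$noise_fid)) fid <- fid + gt$noise_fid
  fid <- apply_phi0(fid, p$phi0)
  spec <- apply_phi1(to_spectrum(fid, axes), p$phi1, axes)
  fid <- from_spectrum(spec, axes)
  apply_eddy(fid, p$eddy_a0, p$eddy_tc, axes)
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> stage '%s', %d points", x$stage, x$axes$n_points))
  if (!is.null(x$transients)) {
    cat(sprintf(", %d transients", nrow(x$transients)))
  }
  p <- x$ground_truth$params
  cat(sprintf("\n  snr %s, phi0 %.3g deg, phi1 %.3g deg/ppm, eddy A0 %.3g Hz\n",
              if (is.null(p$snr)) "none" else format(p$snr), p$phi0, p$phi1,
              p$eddy_a0))
  invisible(x)
}
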
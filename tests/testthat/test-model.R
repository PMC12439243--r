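test_that("scale_and_shape is the identity at neutral parameters", {
  b <- toy_brain_basis(n_points = 512)
  ax <- basis_axes(b)
  out <- scale_and_shape(b, model_params(), ax)
  expect_equal(out, b$fids, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("zero amplitude removes a component exactly", {
  b <- toy_brain_basis(n_points = 512)
  ax <- basis_axes(b)
  m <- stats::setNames(rep(1, length(b$names)), b$names)
  m["naa"] <- 0
  out <- scale_and_shape(b, model_params(amplitude = m), ax)
  expect_true(all(out[, "naa"] == 0))
  expect_equal(out[, "cr"], b$fids[, "cr"], tolerance = 1e-14)
})

test_that("Lorentzian decay d gives FWHM d/pi Hz", {
  b <- singlet_basis(shift = 4.65, decay = 0) # constant unit FID
  ax <- basis_axes(b)
  # printed example: d = pi * 10 -> 10 Hz
  sh <- scale_and_shape(b, model_params(lorentz_d = pi * 10), ax)
  expect_equal(fwhm_hz(sh[, 1], ax), 10,
               tolerance = ax$spectral_width / ax$n_points)
  set.seed(13)
  for (d in runif(20, 5, 150)) {
    sh <- scale_and_shape(b, model_params(lorentz_d = d), ax)
    expect_equal(fwhm_hz(sh[, 1], ax), d / pi,
                 tolerance = ax$spectral_width / ax$n_points)
  }
})

test_that("group Gaussian broadening resolves by group tag", {
  b <- make_toy_basis(data.frame(
    name = c("met", "mm"), group = c("metabolite", "mm_lipid"),
    shift = c(2, 1), amp = c(1, 1)), n_points = 512)
  ax <- basis_axes(b)
  out <- scale_and_shape(b, model_params(gauss_met = 50, gauss_mm = 0), ax)
  expect_equal(out[, "mm"], b$fids[, "mm"], tolerance = 1e-14)
  expect_equal(out[, "met"], b$fids[, "met"] * exp(-50 * ax$t^2),
               tolerance = 1e-14)
})

test_that("per-name and global frequency shifts compose in Hz", {
  b <- singlet_basis(n = 2048)
  ax <- basis_axes(b)
  p <- model_params(fshift = 30, fshift_global_met = -10)
  sh <- scale_and_shape(b, p, ax)
  d <- peak_freq(sh[, 1], ax, zf = 8) - peak_freq(b$fids[, 1], ax, zf = 8)
  expect_equal(d, 20, tolerance = ax$spectral_width / ax$n_points)
})

test_that("missing per-name parameters are reported", {
  b <- toy_brain_basis(n_points = 256)
  ax <- basis_axes(b)
  p <- model_params(amplitude = c(naa = 1))
  expect_error(scale_and_shape(b, p, ax), "missing entries")
})

test_that("summation is linear and order-independent", {
  set.seed(17)
  fids <- matrix(complex(real = rnorm(640), imaginary = rnorm(640)),
                 ncol = 10)
  colnames(fids) <- paste0("m", 1:10)
  s <- sum_components(fids)
  # reassociation oracle: pairwise cascade
  acc <- fids[, 1]
  for (j in 2:10) acc <- acc + fids[, j]
  expect_equal(s, acc, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum_components(fids[, c(1, 1)]), 2 * fids[, 1],
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("noise sigma follows the SNR definition and both channels match", {
  ax <- default_axes(n = 1024)
  fid <- complex(real = numeric(1024))
  res <- add_noise(fid, snr = 10, ref_peak_height = 1, axes = ax, seed = 2)
  expect_equal(res$sigma, 0.1)
  expect_equal(stats::sd(Re(res$noise_spectrum)), 0.1, tolerance = 0.02)
  expect_equal(stats::sd(Im(res$noise_spectrum)), 0.1, tolerance = 0.02)
  # frequency-domain injection <-> time-domain sd relation
  expect_equal(stats::sd(Re(res$noise_fid)), 0.1 / sqrt(1024),
               tolerance = 0.01 / sqrt(1024) * 10)
  expect_error(add_noise(fid, snr = -1, ref_peak_height = 1, axes = ax),
               "snr")
})

test_that("correlated noise derives the imaginary channel from the real one", {
  ax <- default_axes(n = 512)
  fid <- complex(real = numeric(512))
  res <- add_noise(fid, snr = 5, ref_peak_height = 1, axes = ax,
                   correlated = TRUE, seed = 3)
  expect_identical(complexify(Re(res$noise_spectrum)), res$noise_spectrum)
})

test_that("requested SNR is recovered by measurement", {
  b <- singlet_basis()
  for (snr in c(5, 15, 50)) {
    p <- model_params(snr = snr)
    vals <- vapply(1:60, function(s) {
      rec <- simulate_spectrum(b, p, seed = s)
      measure_snr(rec$spectrum, rec$axes)
    }, numeric(1))
    expect_equal(mean(vals), snr, tolerance = 0.05 * snr)
  }
})

test_that("zero-order phase rotates globally", {
  b <- singlet_basis(n = 1024)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  expect_identical(apply_phi0(fid, 0), fid)
  expect_equal(apply_phi0(fid, 180), -fid, tolerance = 1e-12)
  expect_equal(Mod(to_spectrum(apply_phi0(fid, 37), ax)),
               Mod(to_spectrum(fid, ax)), tolerance = 1e-9)
  # quadrature: 90 degrees turns absorption into dispersion (real integral ~ 0)
  sp0 <- Re(to_spectrum(fid, ax))
  sp90 <- Re(to_spectrum(apply_phi0(fid, 90), ax))
  expect_lt(abs(sum(sp90)), 0.01 * sum(abs(sp0)))
})

test_that("first-order phase pivots at ppm_ref and preserves magnitude", {
  b <- toy_brain_basis()
  ax <- basis_axes(b)
  spec <- to_spectrum(sum_components(b$fids), ax)
  expect_identical(apply_phi1(spec, 0, ax), spec)
  out <- apply_phi1(spec, 123, ax)
  ref_bin <- which(ax$f == 0)
  expect_identical(out[ref_bin], spec[ref_bin])
  expect_equal(Mod(out), Mod(spec), tolerance = 1e-12)
  # one ppm from the pivot, phi1 = 90 rotates by exactly pi/2
  bin1 <- which.min(abs(ax$ppm - (ax$ppm_ref + 1)))
  out90 <- apply_phi1(spec, 90, ax)
  expect_equal(Arg(out90[bin1] / spec[bin1]),
               -pi / 2 * (ax$ppm[bin1] - ax$ppm_ref), tolerance = 1e-6)
})

test_that("eddy currents preserve FID magnitude and degenerate correctly", {
  b <- singlet_basis()
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  expect_identical(apply_eddy(fid, 0, 0.15, ax), fid)
  out <- apply_eddy(fid, 5, 0.15, ax)
  expect_equal(Mod(out), Mod(fid), tolerance = 1e-12)
  # very long time constant -> pure +A0 Hz frequency shift
  out_inf <- apply_eddy(fid, 5, 1e6, ax)
  shift <- peak_freq(out_inf, ax, zf = 16) - peak_freq(fid, ax, zf = 16)
  expect_equal(shift, 5, tolerance = ax$spectral_width / ax$n_points)
  # short tc distorts the lineshape (spectrum differs from any pure shift)
  expect_gt(max(Mod(to_spectrum(out, ax) - to_spectrum(fid, ax))),
            0.01 * max(Mod(to_spectrum(fid, ax))))
  expect_error(apply_eddy(fid, 5, 0, ax), "tc")
})

test_that("with all artifacts off, simulate returns the scaled basis sum", {
  b <- toy_brain_basis(n_points = 1024)
  m <- stats::setNames(c(2, 1, 0.5, 1.2, 0.8), b$names)
  rec <- simulate_spectrum(b, model_params(amplitude = m))
  expected <- sum_components(scale_and_shape(b, model_params(amplitude = m),
                                             rec$axes))
  expect_equal(rec$fid, expected, tolerance = 1e-12)
})

test_that("simulation is linear in the amplitudes with artifacts off", {
  b <- toy_brain_basis(n_points = 512)
  m1 <- stats::setNames(runif(5, 0.5, 2), b$names)
  m2 <- stats::setNames(runif(5, 0.5, 2), b$names)
  r1 <- simulate_spectrum(b, model_params(amplitude = m1))
  r2 <- simulate_spectrum(b, model_params(amplitude = m2))
  r12 <- simulate_spectrum(b, model_params(amplitude = m1 + m2))
  expect_equal(r1$fid + r2$fid, r12$fid, tolerance = 1e-9)
})

test_that("phase and eddy operators conserve spectral power", {
  b <- toy_brain_basis(n_points = 1024)
  ax <- basis_axes(b)
  fid <- sum_components(b$fids)
  p0 <- sum(Mod(to_spectrum(fid, ax))^2)
  f1 <- apply_phi0(fid, 53)
  s1 <- apply_phi1(to_spectrum(f1, ax), 71, ax)
  f2 <- apply_eddy(from_spectrum(s1, ax), 4, 0.2, ax)
  expect_equal(sum(Mod(to_spectrum(f2, ax))^2) / p0, 1, tolerance = 1e-9)
})

test_that("the full record recomposes from its stored ground truth", {
  b <- toy_brain_basis()
  p <- model_params(
    amplitude = stats::setNames(runif(5, 0.5, 2), b$names),
    lorentz_d = 8, gauss_met = 30, gauss_mm = 60,
    fshift_global_met = 3, fshift_global_nuis = -2,
    phi0 = 15, phi1 = 25, eddy_a0 = 3, eddy_tc = 0.12,
    snr = 15, b0 = make_b0_map(c(6, 6, 6), 0.5, 0.5, 0.5, mu = 4),
    baseline_cfg = baseline_config(seed = 11),
    water_cfg = residual_water_config(seed = 12))
  rec <- simulate_spectrum(b, p, seed = 99)
  err <- max(Mod(reconstruct_record(rec) - rec$fid)) / max(Mod(rec$fid))
  expect_lt(err, 1e-6)
  expect_equal(to_spectrum(rec$fid, rec$axes), rec$spectrum, tolerance = 1e-12)
})

test_that("transient stage defers noise to the transient expansion", {
  b <- singlet_basis(n = 512)
  cp <- coil_params(4, sens = rep(1, 4), snr_scale = rep(1, 4),
                    df = rep(0, 4), dphi = rep(0, 4))
  rec <- simulate_spectrum(b, model_params(snr = 20), seed = 1,
                           stage = "transients", coil = cp)
  expect_null(rec$ground_truth$noise_fid)
  expect_equal(dim(rec$transients), c(4L, 512L))
  # the pre-noise fid is clean: transients differ from it only by noise
  resid <- sweep(rec$transients, 2, rec$fid)
  expect_gt(stats::sd(Re(resid)), 0)
})
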
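test_that("coil weight sampler matches its clamped-normal definition", {
  w <- sample_coil_weights(1e5, seed = 1)
  expect_true(all(w >= 0 & w <= 2))
  expect_equal(mean(w), 1, tolerance = 0.01)
  expect_identical(sample_coil_weights(10, sd = 0), rep(1, 10))
})

test_that("C = 1 with neutral coil terms reduces to plain noise addition", {
  b <- singlet_basis(n = 512)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  cp <- coil_params(1, sens = 1, snr_scale = 1, df = 0, dphi = 0)
  set.seed(7)
  tr <- make_transients(fid, 10, 1, cp, ax)
  set.seed(7)
  ref <- add_noise(fid, 10, 1, ax)$fid
  expect_equal(as.vector(tr[1, ]), ref, tolerance = 1e-12)
})

test_that("noiseless transients are exact sensitivity-scaled drifted copies", {
  b <- singlet_basis(n = 256)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  cp <- coil_params(3, sens = c(0.5, 1, 1.5), snr_scale = rep(1, 3),
                    df = c(0, 0, 0), dphi = c(0, 0, 0))
  tr <- make_transients(fid, NULL, 1, cp, ax)
  for (cc in 1:3) {
    expect_equal(as.vector(tr[cc, ]), cp$sens[cc] * fid, tolerance = 1e-14)
  }
})

test_that("combination preserves identical noiseless transients in both modes", {
  b <- singlet_basis(n = 256)
  fid <- b$fids[, 1]
  tr <- t(sapply(1:5, function(i) fid))
  expect_equal(combine_transients(tr, mode = "average"), fid,
               tolerance = 1e-12)
  expect_equal(combine_transients(tr, mode = "sum"), fid, tolerance = 1e-12)
  w <- c(0, 0, 2, 0, 0)
  expect_equal(combine_transients(tr, w, mode = "average"), fid,
               tolerance = 1e-12)
  expect_error(combine_transients(tr, rep(0, 5)), "zero")
})

test_that("combination is permutation-invariant in (transient, weight) pairs", {
  set.seed(23)
  tr <- matrix(complex(real = rnorm(4 * 64), imaginary = rnorm(4 * 64)),
               nrow = 4)
  w <- runif(4)
  perm <- c(3, 1, 4, 2)
  expect_equal(combine_transients(tr, w),
               combine_transients(tr[perm, ], w[perm]), tolerance = 1e-12)
})

test_that("equal-weight averaging gains sqrt(C) in SNR", {
  b <- singlet_basis(n = 1024)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  snr0 <- 40
  ref <- max(Re(to_spectrum(fid, ax)))
  for (C in c(4, 16, 64)) {
    cp <- coil_params(C, sens = rep(1, C), snr_scale = rep(1, C),
                      df = rep(0, C), dphi = rep(0, C))
    ratios <- vapply(1:25, function(s) {
      set.seed(s)
      tr <- make_transients(fid, snr0, ref, cp, ax)
      snr_single <- measure_snr(to_spectrum(as.vector(tr[1, ]), ax), ax)
      snr_comb <- measure_snr(to_spectrum(combine_transients(tr), ax), ax)
      snr_comb / snr_single
    }, numeric(1))
    expect_equal(mean(ratios), sqrt(C), tolerance = 0.1 * sqrt(C))
  }
})

test_that("drift application and removal are an exact inverse pair", {
  b <- singlet_basis(n = 512)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  cp <- coil_params(6, seed = 14)
  tr <- make_transients(fid, NULL, 1, cp, ax)
  aligned <- remove_known_drifts(tr, cp, ax)
  for (cc in 1:6) {
    expect_equal(as.vector(aligned[cc, ]), cp$sens[cc] * fid,
                 tolerance = 1e-12)
  }
  cp0 <- coil_params(2, sens = c(1, 1), snr_scale = c(1, 1), df = c(0, 0),
                     dphi = c(0, 0))
  tr0 <- make_transients(fid, NULL, 1, cp0, ax)
  expect_identical(remove_known_drifts(tr0, cp0, ax), tr0)
})

test_that("aligned noisy transients agree in phase at the reference peak", {
  b <- singlet_basis(n = 1024)
  ax <- basis_axes(b)
  fid <- b$fids[, 1]
  cp <- coil_params(8, sens = rep(1, 8), snr_scale = rep(1, 8), seed = 33)
  set.seed(33)
  tr <- make_transients(fid, 200, max(Re(to_spectrum(fid, ax))), cp, ax)
  aligned <- remove_known_drifts(tr, cp, ax)
  pk <- which.max(Mod(to_spectrum(fid, ax)))
  phases <- vapply(1:8, function(cc) {
    Arg(to_spectrum(as.vector(aligned[cc, ]), ax)[pk] /
          to_spectrum(fid, ax)[pk])
  }, numeric(1))
  expect_lt(max(abs(phases)), 0.05)
})

test_that("coil parameter validation", {
  expect_error(coil_params(0), ">= 1")
  expect_error(coil_params(3, sens = c(1, 1)), "length C")
})
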
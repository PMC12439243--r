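test_that("std = 0 reduces the walk to the smoothed trend line", {
  cfg <- walk_config(start = -0.5, end = 0.5, std = 0, lower_bound = -1,
                     upper_bound = 1, length = 64, window_size = 0.1)
  w <- bounded_walk(cfg)
  trend <- seq(-0.5, 0.5, length.out = 64)
  # smoothing a straight line with reflective padding perturbs only edges
  mid <- 10:54
  expect_equal(w[mid], trend[mid], tolerance = 1e-9)
})

test_that("walks respect their bounds and are deterministic given a seed", {
  set.seed(21)
  for (rep in 1:200) {
    lb <- runif(1, -5, 0)
    ub <- lb + runif(1, 0.5, 5)
    cfg <- walk_config(start = runif(1, lb, ub), end = runif(1, lb, ub),
                       std = runif(1, 0, 3), lower_bound = lb,
                       upper_bound = ub,
                       length = sample(8:200, 1),
                       window_size = runif(1, 0.02, 0.9),
                       seed = sample.int(1e6, 1))
    w <- bounded_walk(cfg)
    expect_gte(min(w), lb - 1e-12)
    expect_lte(max(w), ub + 1e-12)
    expect_identical(w, bounded_walk(cfg))
  }
})

test_that("smoothing a bounded signal stays within the same bounds", {
  set.seed(4)
  x <- pmin(pmax(cumsum(rnorm(100)), -2), 2)
  cfg <- walk_config(std = 1, lower_bound = -2, upper_bound = 2,
                     length = 100, window_size = 0.25, seed = 1)
  w <- bounded_walk(cfg)
  expect_true(min(w) >= -2 && max(w) <= 2)
})

test_that("complexify preserves the real channel bit-exactly", {
  set.seed(31)
  for (rep in 1:100) {
    cfg <- walk_config(std = runif(1, 0.1, 2), length = sample(c(64, 65, 128), 1),
                       window_size = 0.1, seed = rep)
    w <- bounded_walk(cfg)
    z <- complexify(w)
    expect_identical(Re(z), w)
    expect_gt(max(abs(Im(z))), 0) # a genuine quadrature partner, not zeros
  }
  expect_equal(complexify(numeric(32)), complex(real = numeric(32)))
})

test_that("complexify produces a dispersion partner, not a copy", {
  x <- exp(-(seq(-6, 6, length.out = 256))^2)
  z <- complexify(x)
  # dispersion of a symmetric absorption line is antisymmetric: near-zero sum
  expect_lt(abs(sum(Im(z))) / sum(abs(Im(z))), 0.05)
  expect_gt(max(abs(Im(z) + x)), 0.1 * max(x)) # differs from -x
})

test_that("two 90-degree time-domain shifts negate a spectrum", {
  set.seed(5)
  x <- rnorm(128)
  twice <- td_phase_shift(td_phase_shift(x, 90), 90)
  expect_equal(Re(twice), -x, tolerance = 1e-10)
  expect_equal(max(abs(Im(twice))), 0, tolerance = 1e-10)
})

test_that("nuisance signals are zero outside their ppm span and scale linearly", {
  ax <- default_axes(n = 1024)
  cfg <- residual_water_config(ppm_span = c(4.2, 5.1), seed = 8)
  w <- make_residual_water(cfg, ax)
  outside <- ax$ppm < 4.2 | ax$ppm > 5.1
  expect_true(all(w[outside] == 0))
  expect_gt(max(Mod(w)), 0)
  cfg0 <- residual_water_config(ppm_span = c(4.2, 5.1), seed = 8, scale = 0)
  expect_true(all(make_residual_water(cfg0, ax) == 0))
  # scale * ref_level enters multiplicatively
  w2 <- make_residual_water(cfg, ax, ref_level = 3)
  expect_equal(w2, 3 * w, tolerance = 1e-12)
})

test_that("residual water is rougher than the baseline (total variation per ppm)", {
  ax <- default_axes(n = 2048)
  tv_b <- tv_w <- numeric(50)
  for (i in 1:50) {
    tv_b[i] <- tv_per_ppm(make_baseline(baseline_config(seed = i), ax),
                          ax, c(0.2, 4.2))
    tv_w[i] <- tv_per_ppm(make_residual_water(residual_water_config(seed = i),
                                              ax),
                          ax, c(4.2, 5.1))
  }
  expect_gt(stats::median(tv_w), stats::median(tv_b))
})

test_that("nuisance generation validates its span", {
  ax <- default_axes(n = 256)
  cfg <- baseline_config(ppm_span = c(-10, 2))
  expect_error(make_baseline(cfg, ax), "inside the axes")
})
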
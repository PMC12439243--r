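test_that("sampling schemes draw deterministically and respect bounds", {
  sch <- sampling_scheme(
    amplitude = dist_spec("uniform", min = 0.5, max = 2),
    phi0 = dist_spec("normal", mean = 0, sd = 10),
    snr = dist_spec("constant", value = 15),
    eddy_a0 = dist_spec("truncnorm", mean = 0, sd = 3, lower = -5, upper = 5))
  nms <- c("naa", "cr")
  d1 <- sample_params(sch, 50, nms, seed = 4)
  d2 <- sample_params(sch, 50, nms, seed = 4)
  expect_identical(d1, d2)
  expect_true(all(d1$amplitude.naa >= 0.5 & d1$amplitude.naa <= 2))
  expect_true(all(d1$eddy_a0 >= -5 & d1$eddy_a0 <= 5))
  expect_true(all(d1$snr == 15))
  u <- sample_params(sampling_scheme(phi0 = dist_spec("uniform", min = 0,
                                                      max = 1)),
                     1e5, "x", seed = 1)
  expect_equal(mean(u$phi0), 0.5, tolerance = 0.01)
})

test_that("invalid specs and scheme entries are rejected", {
  expect_error(dist_spec("uniform", min = 2, max = 1), "invalid")
  expect_error(dist_spec("normal", mean = 0), "invalid")
  expect_error(sampling_scheme(bogus = dist_spec("constant", value = 1)),
               "unknown")
})

test_that("draws convert to usable model parameters", {
  b <- toy_brain_basis(n_points = 128)
  sch <- sampling_scheme(amplitude = dist_spec("uniform", min = 0.5, max = 2),
                         phi0 = dist_spec("normal", mean = 0, sd = 5))
  draws <- sample_params(sch, 3, b$names, seed = 2)
  p <- params_from_draws(draws, 2, b$names)
  expect_s3_class(p, "model_params")
  expect_equal(unname(p$amplitude), as.numeric(draws[2, paste0("amplitude.",
                                                               b$names)]))
  rec <- simulate_spectrum(b, p)
  expect_s3_class(rec, "sim_record")
})

test_that("distribution fitting recovers generating parameters", {
  set.seed(71)
  x <- rnorm(1e4, 5, 2)
  fit <- fit_distributions(x, candidates = c("normal", "uniform", "gamma",
                                             "lognormal"))
  expect_identical(fit$best, "normal")
  expect_equal(unname(fit$best_params["mean"]), 5, tolerance = 0.1)
  expect_equal(unname(fit$best_params["sd"]), 2, tolerance = 0.1)

  u <- runif(1e4, 0, 1)
  fit_u <- fit_distributions(u, candidates = c("normal", "uniform"))
  expect_identical(fit_u$best, "uniform")

  g <- rgamma(1e4, shape = 3, rate = 1.5)
  fit_g <- fit_distributions(g, candidates = c("normal", "gamma", "lognormal"))
  expect_identical(fit_g$best, "gamma")
  expect_equal(unname(fit_g$best_params["shape"]), 3, tolerance = 0.15)
  expect_equal(unname(fit_g$best_params["rate"]), 1.5, tolerance = 0.075)
})

test_that("fitting output is a ranked table, reproducible for a fixed sample", {
  set.seed(72)
  x <- rnorm(500, 0, 1)
  f1 <- fit_distributions(x)
  f2 <- fit_distributions(x)
  expect_identical(f1$table$family, f2$table$family)
  expect_true(setequal(f1$table$rank, seq_len(nrow(f1$table))))
  expect_true(all(is.finite(f1$table$sse[f1$table$rank == 1])))
  expect_s3_class(as.data.frame(f1), "data.frame")
})

test_that("degenerate and tiny samples are rejected", {
  expect_error(fit_distributions(rep(1, 100)), "degenerate")
  expect_error(fit_distributions(rnorm(5)), "at least 30")
  expect_error(fit_distributions(rnorm(100), candidates = "weibull"),
               "unknown")
})

test_that("fit tables load, rename and drop incomplete rows", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("amp_NAA,phi_zero", "1.2,3", "0.9,NA", "1.1,-2"), tmp)
  expect_message(tab <- load_fit_table(tmp, rename = c(phi0 = "phi_zero")),
                 "dropped 1")
  expect_identical(names(tab), c("amp_NAA", "phi0"))
  expect_equal(nrow(tab), 2L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), tsv)
  expect_equal(load_fit_table(tsv)$b, 2)

  empty <- tempfile()
  file.create(empty)
  expect_error(load_fit_table(empty), "empty")
})
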
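#' Declarative sampling schemes for model parameters
#'
#' A sampling scheme maps model-parameter names to distribution specs. Each
#' spec is created with [dist_spec()] and supports the families `constant`,
#' `uniform`, `normal`, `truncnorm` (normal truncated to `[lower, upper]`),
#' `gamma` and `lognormal`. Per-metabolite parameters (`amplitude`,
#' `lorentz_d`, `fshift`) accept either one spec applied to every basis
#' function or a named list of specs, one per basis function.
#'
#' @param ... Named entries: `amplitude`, `lorentz_d`, `gauss_met`,
#'   `gauss_mm`, `fshift`, `fshift_global_met`, `fshift_global_nuis`,
#'   `phi0`, `phi1`, `eddy_a0`, `eddy_tc`, `snr`. Omitted entries keep the
#'   [model_params()] defaults.
#' @return An object of class `sampling_scheme`.
#' @examples
#' sch <- sampling_scheme(amplitude = dist_spec("uniform", min = 0.5, max = 2),
#'                        phi0 = dist_spec("normal", mean = 0, sd = 10),
#'                        snr = dist_spec("constant", value = 15))
#' @export
sampling_scheme <- function(...) {
  entries <- list(...)
  allowed <- c("amplitude", "lorentz_d", "gauss_met", "gauss_mm", "fshift",
               "fshift_global_met", "fshift_global_nuis", "phi0", "phi1",
               "eddy_a0", "eddy_tc", "snr")
  bad <- setdiff(names(entries), allowed)
  abort_if(length(bad) > 0,
           sprintf("unknown scheme entries: %s", paste(bad, collapse = ", ")))
  is_spec <- function(x) inherits(x, "dist_spec") ||
    (is.list(x) && all(vapply(x, inherits, logical(1), "dist_spec")))
  abort_if(!all(vapply(entries, is_spec, logical(1))),
           "scheme entries must be dist_spec objects (or named lists of them)")
  structure(entries, class = "sampling_scheme")
}

#' Distribution specification
#'
#' @param dist One of `"constant"`, `"uniform"`, `"normal"`, `"truncnorm"`,
#'   `"gamma"`, `"lognormal"`.
#' @param ... Family parameters: `value` (constant); `min`, `max` (uniform);
#'   `mean`, `sd` (normal, truncnorm); `lower`, `upper` (truncnorm bounds);
#'   `shape`, `rate` (gamma); `meanlog`, `sdlog` (lognormal).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(dist = c("constant", "uniform", "normal", "truncnorm",
                               "gamma", "lognormal"), ...) {
  dist <- match.arg(dist)
  args <- list(...)
  ok <- switch(dist,
    constant = "value" %in% names(args),
    uniform = all(c("min", "max") %in% names(args)) && args$max > args$min,
    normal = all(c("mean", "sd") %in% names(args)) && args$sd >= 0,
    truncnorm = all(c("mean", "sd", "lower", "upper") %in% names(args)) &&
      args$sd >= 0 && args$upper > args$lower,
    gamma = all(c("shape", "rate") %in% names(args)) && args$shape > 0 &&
      args$rate > 0,
    lognormal = all(c("meanlog", "sdlog") %in% names(args)) && args$sdlog >= 0)
  abort_if(!isTRUE(ok), sprintf("invalid or missing parameters for '%s'", dist))
  structure(c(list(dist = dist), args), class = "dist_spec")
}

# Draw n values from one dist_spec (uses the current RNG stream).
#' @noRd
draw_spec <- function(spec, n) {
  switch(spec$dist,
    constant = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    truncnorm = rtruncnorm_(n, spec$mean, spec$sd, spec$lower, spec$upper),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog))
}

# Inverse-CDF sampler for the truncated normal.
#' @noRd
rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Truncated-normal density (used by the fitter).
#' @noRd
dtruncnorm_ <- function(x, mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  out <- stats::dnorm(x, mean, sd) / z
  out[x < lower | x > upper] <- 0
  out
}

#' Sample model parameters from a scheme
#'
#' Draws `n` parameter sets. The result is a data frame of the sampled
#' values (per-metabolite parameters expand to one column per basis
#' function, e.g. `amplitude.naa`) with one attached [model_params()] object
#' per row retrievable via [params_from_draws()]. Draws are deterministic
#' given `seed` and respect every spec's support.
#'
#' @param scheme A [sampling_scheme()].
#' @param n Number of draws.
#' @param basis_names Character vector of basis-function names the
#'   per-metabolite entries expand over.
#' @param seed Optional RNG seed.
#' @return A data frame with `n` rows, one column per sampled scalar.
#' @export
sample_params <- function(scheme, n, basis_names, seed = NULL) {
  abort_if(!inherits(scheme, "sampling_scheme"),
           "`scheme` must be a `sampling_scheme`")
  abort_if(n < 1, "`n` must be >= 1")
  per_met <- c("amplitude", "lorentz_d", "fshift")
  with_seed(seed, {
    cols <- list()
    for (par in names(scheme)) {
      spec <- scheme[[par]]
      if (par %in% per_met) {
        specs <- if (inherits(spec, "dist_spec")) {
          stats::setNames(rep(list(spec), length(basis_names)), basis_names)
        } else {
          missing <- setdiff(basis_names, names(spec))
          abort_if(length(missing) > 0,
                   sprintf("`%s` lacks specs for: %s", par,
                           paste(missing, collapse = ", ")))
          spec[basis_names]
        }
        for (nm in basis_names) {
          cols[[paste(par, nm, sep = ".")]] <- draw_spec(specs[[nm]], n)
        }
      } else {
        cols[[par]] <- draw_spec(spec, n)
      }
    }
    if (length(cols) == 0) {
      return(as.data.frame(matrix(numeric(0), nrow = n, ncol = 0)))
    }
    as.data.frame(cols, check.names = FALSE)
  })
}

#' Build model_params from one row of sampled draws
#'
#' @param draws The data frame returned by [sample_params()].
#' @param row Row index.
#' @param basis_names Basis-function names used for the sampling.
#' @param ... Fixed fields passed through to [model_params()] (e.g. `b0`,
#'   `baseline_cfg`, `snr_ref`).
#' @return A [model_params()] object.
#' @export
params_from_draws <- function(draws, row, basis_names, ...) {
  abort_if(row < 1 || row > nrow(draws), "`row` out of range")
  args <- list(...)
  take_per_met <- function(par, default) {
    nmcols <- paste(par, basis_names, sep = ".")
    if (all(nmcols %in% names(draws))) {
      stats::setNames(as.numeric(draws[row, nmcols]), basis_names)
    } else {
      default
    }
  }
  take <- function(par, default) {
    if (par %in% names(draws)) draws[[par]][row] else default
  }
  defaults <- list(amplitude = take_per_met("amplitude", 1),
                   lorentz_d = take_per_met("lorentz_d", 0),
                   fshift = take_per_met("fshift", 0),
                   gauss_met = take("gauss_met", 0),
                   gauss_mm = take("gauss_mm", 0),
                   fshift_global_met = take("fshift_global_met", 0),
                   fshift_global_nuis = take("fshift_global_nuis", 0),
                   phi0 = take("phi0", 0), phi1 = take("phi1", 0),
                   eddy_a0 = take("eddy_a0", 0),
                   eddy_tc = take("eddy_tc", 0.15),
                   snr = if ("snr" %in% names(draws)) draws$snr[row] else NULL)
  do.call(model_params, utils::modifyList(defaults, args))
}

#' Fit candidate probability distributions to a sample
#'
#' Fits each candidate family by maximum likelihood (standard families via
#' \pkg{fitdistrplus}; uniform by its closed-form MLE, the sample range;
#' truncated normal by direct likelihood optimization) and ranks the
#' candidates by the sum of squared errors between the fitted density and a
#' fixed-binning histogram of the data, with AIC as tiebreaker. Families
#' whose support excludes the data (e.g. gamma with non-positive values)
#' are scored `Inf` and reported as failed.
#'
#' @param x Numeric sample (>= 30 non-missing, non-constant values).
#' @param candidates Subset of `"normal"`, `"uniform"`, `"gamma"`,
#'   `"lognormal"`, `"truncnorm"`.
#' @param bins Number of histogram bins for the SSE score.
#' @return An object of class `dist_fit`: a list with `table` (data frame:
#'   family, parameter estimates, sse, aic, rank), `best` (family name) and
#'   `best_params` (named numeric vector).
#' @examples
#' fit <- fit_distributions(rnorm(1000, 5, 2))
#' fit$best
#' @export
fit_distributions <- function(x, candidates = c("normal", "uniform", "gamma",
                                                "lognormal", "truncnorm"),
                              bins = 50) {
  x <- x[is.finite(x)]
  abort_if(length(x) < 30, "need at least 30 finite samples")
  abort_if(max(x) == min(x), "degenerate input: all samples identical")
  known <- c("normal", "uniform", "gamma", "lognormal", "truncnorm")
  bad <- setdiff(candidates, known)
  abort_if(length(bad) > 0,
           sprintf("unknown candidate families: %s", paste(bad, collapse = ", ")))
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                      plot = FALSE)
  mids <- h$mids
  dens <- h$density
  fits <- lapply(candidates, function(fam) fit_one_family(fam, x, mids, dens))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(family = candidates[i],
               params = I(list(f$params)),
               sse = f$sse, aic = f$aic, stringsAsFactors = FALSE)
  }))
  ord <- order(tab$sse, tab$aic)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  abort_if(!is.finite(tab$sse[1]),
           "no candidate family could be fitted to the sample")
  structure(list(table = tab, best = tab$family[1],
                 best_params = tab$params[[1]], n = length(x)),
            class = "dist_fit")
}

#' @noRd
fit_one_family <- function(fam, x, mids, dens) {
  fail <- list(params = c(), sse = Inf, aic = Inf)
  res <- tryCatch(switch(fam,
    normal = {
      f <- fitdistrplus::fitdist(x, "norm")
      list(params = f$estimate, ll = f$loglik, k = 2,
           d = stats::dnorm(mids, f$estimate["mean"], f$estimate["sd"]))
    },
    lognormal = {
      if (any(x <= 0)) stop("support")
      f <- fitdistrplus::fitdist(x, "lnorm")
      list(params = f$estimate, ll = f$loglik, k = 2,
           d = stats::dlnorm(mids, f$estimate["meanlog"], f$estimate["sdlog"]))
    },
    gamma = {
      if (any(x <= 0)) stop("support")
      f <- fitdistrplus::fitdist(x, "gamma")
      list(params = f$estimate, ll = f$loglik, k = 2,
           d = stats::dgamma(mids, shape = f$estimate["shape"],
                             rate = f$estimate["rate"]))
    },
    uniform = {
      est <- c(min = min(x), max = max(x))
      ll <- -length(x) * log(est["max"] - est["min"])
      list(params = est, ll = unname(ll), k = 2,
           d = stats::dunif(mids, est["min"], est["max"]))
    },
    truncnorm = {
      est <- fit_truncnorm(x)
      list(params = est$params, ll = est$ll, k = 4,
           d = dtruncnorm_(mids, est$params["mean"], est$params["sd"],
                           est$params["lower"], est$params["upper"]))
    }), error = function(e) NULL)
  if (is.null(res)) return(fail)
  list(params = res$params,
       sse = sum((dens - res$d)^2),
       aic = 2 * res$k - 2 * res$ll)
}

# Truncated-normal MLE: bounds at the sample range, (mean, sd) by optim.
#' @noRd
fit_truncnorm <- function(x) {
  lower <- min(x)
  upper <- max(x)
  nll <- function(par) {
    if (par[2] <= 0) return(1e12)
    -sum(log(pmax(dtruncnorm_(x, par[1], par[2], lower, upper), 1e-300)))
  }
  opt <- stats::optim(c(mean(x), stats::sd(x)), nll, method = "Nelder-Mead")
  list(params = c(mean = opt$par[1], sd = opt$par[2],
                  lower = lower, upper = upper),
       ll = -opt$value)
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit> n = %d, best family: %s\n", x$n, x$best))
  tab <- x$table
  tab$params <- vapply(tab$params, function(p) {
    paste(sprintf("%s=%.4g", names(p), p), collapse = ", ")
  }, character(1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.dist_fit <- function(x, ...) x$table

#' Load a tabular spectral-fit parameter export
#'
#' Reads a delimited text table (CSV/TSV; the separator is sniffed from the
#' header line), optionally renames columns via a mapping, and drops rows
#' containing missing values with a message stating how many were removed.
#'
#' @param path Path to the delimited file with a header row.
#' @param rename Optional named character vector `c(new = "old")` remapping
#'   column names.
#' @return A data frame of numeric columns.
#' @export
load_fit_table <- function(path, rename = NULL) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  abort_if(length(first) == 0 || !nzchar(first), "empty file")
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(nrow(tab) == 0, "table has a header but no rows")
  if (!is.null(rename)) {
    for (new in names(rename)) {
      old <- rename[[new]]
      abort_if(!(old %in% names(tab)),
               sprintf("column '%s' not found for renaming", old))
      names(tab)[names(tab) == old] <- new
    }
  }
  complete <- stats::complete.cases(tab)
  if (any(!complete)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!complete)))
    tab <- tab[complete, , drop = FALSE]
  }
  tab
}
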
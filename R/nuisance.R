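#' Configuration for the smoothed bounded pseudo-random walk
#'
#' Holds the generator inputs: trend endpoints `start`/`end`, raw step
#' standard deviation `std`, walk bounds, walk length, the smoothing-kernel
#' size as a fraction of the length, the final amplitude scale (relative to
#' the spectrum it will be added to), the ppm interval the walk is resampled
#' onto, and an optional seed.
#'
#' @param start,end Trend-line endpoints, arbitrary amplitude units.
#' @param std Standard deviation of the raw Gaussian steps (>= 0).
#' @param lower_bound,upper_bound Bounds of the walk (`upper > lower`).
#' @param length Number of walk samples (>= 8).
#' @param window_size Smoothing-kernel size as a fraction of `length`,
#'   strictly between 0 and 1.
#' @param scale Dimensionless amplitude multiplier applied after matching
#'   the walk's order of magnitude to the spectrum.
#' @param ppm_span Two ppm values; the interval the walk occupies on the
#'   spectral axis (zero outside).
#' @param seed Optional RNG seed for reproducible walks.
#' @return An object of class `walk_config`.
#' @seealso [bounded_walk()], [baseline_config()], [residual_water_config()]
#' @export
walk_config <- function(start = 0, end = 0, std = 1,
                        lower_bound = -1, upper_bound = 1,
                        length = 256, window_size = 0.15,
                        scale = 1, ppm_span = c(0.2, 4.2), seed = NULL) {
  abort_if(upper_bound <= lower_bound, "`upper_bound` must exceed `lower_bound`")
  abort_if(length < 8 || length != round(length), "`length` must be an integer >= 8")
  abort_if(window_size <= 0 || window_size >= 1,
           "`window_size` must lie strictly between 0 and 1")
  abort_if(std < 0, "`std` must be >= 0")
  abort_if(!is.numeric(ppm_span) || base::length(ppm_span) != 2 ||
             ppm_span[2] <= ppm_span[1],
           "`ppm_span` must be two increasing ppm values")
  structure(list(start = start, end = end, std = std,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 length = as.integer(length), window_size = window_size,
                 scale = scale, ppm_span = ppm_span, seed = seed),
            class = "walk_config")
}

#' Default nuisance profiles
#'
#' `baseline_config()` yields broad, smooth walks (small step noise, large
#' smoothing window, full metabolite ppm region) emulating the slowly
#' undulating non-macromolecule spectral background. `residual_water_config()`
#' yields highly irregular, localized walks (large step noise, small window,
#' narrow span around the water reference at 4.65 ppm) emulating imperfectly
#' suppressed water. The numeric profiles are package defaults — the
#' literature characterizes these signals only qualitatively — and every
#' field can be overridden.
#'
#' @param ... Overrides passed to [walk_config()].
#' @return A `walk_config`.
#' @export
baseline_config <- function(...) {
  defaults <- list(start = 0, end = 0, std = 0.05, lower_bound = -1,
                   upper_bound = 1, length = 256, window_size = 0.3,
                   scale = 0.1, ppm_span = c(0.2, 4.2))
  do.call(walk_config, utils::modifyList(defaults, list(...)))
}

#' @rdname baseline_config
#' @export
residual_water_config <- function(...) {
  defaults <- list(start = 0, end = 0, std = 1, lower_bound = -1,
                   upper_bound = 1, length = 1024, window_size = 0.02,
                   scale = 0.5, ppm_span = c(4.2, 5.1))
  do.call(walk_config, utils::modifyList(defaults, list(...)))
}

#' Smoothed bounded pseudo-random walk
#'
#' Generates a real-valued signal by (1) cumulatively summing Gaussian steps
#' of standard deviation `std`, (2) subtracting a linear trend from `start`
#' to `end`, (3) rescaling the residual deltas so their range equals
#' `upper_bound - lower_bound`, (4) clipping `trend + deltas` into the
#' bounds (the conditional adjustment), and (5) smoothing with a uniform
#' moving-average kernel of size `window_size * length` using reflective
#' padding (a convex combination, so the bounds are preserved and the output
#' length equals `length`). With `std = 0` the deltas are identically zero
#' and the output is the smoothed trend line.
#'
#' @param cfg A [walk_config()].
#' @return Numeric vector of length `cfg$length`, guaranteed inside
#'   `[lower_bound, upper_bound]` provided the trend itself is.
#' @export
bounded_walk <- function(cfg) {
  abort_if(!inherits(cfg, "walk_config"), "`cfg` must be a `walk_config`")
  with_seed(cfg$seed, {
    n <- cfg$length
    trend <- seq(cfg$start, cfg$end, length.out = n)
    if (cfg$std == 0) {
      deltas <- numeric(n)
    } else {
      walk <- cumsum(stats::rnorm(n, 0, cfg$std))
      deltas <- walk - trend
      rng <- max(deltas) - min(deltas)
      delta_range <- if (rng == 0) 0 else
        (cfg$upper_bound - cfg$lower_bound) / rng
      deltas <- deltas * delta_range
    }
    out <- pmin(pmax(trend + deltas, cfg$lower_bound), cfg$upper_bound)
    smooth_uniform(out, max(1L, as.integer(round(cfg$window_size * n))))
  })
}

# Uniform moving average with reflective padding; output length = input.
# The kernel is forced to the nearest odd size so the window is centered
# (an even window would shift every feature by half a sample).
#' @noRd
smooth_uniform <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  k <- min(k, n)
  if (k %% 2 == 0) k <- k - 1
  if (k <= 1) return(x)
  pad <- k %/% 2
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  cs <- c(0, cumsum(xp))
  # centered window of size k (k even: window [i-pad, i+pad-1])
  i <- seq_len(n) + pad
  (cs[i + (k - pad)] - cs[i - pad]) / k
}

#' Create the complex partner of a real spectrum
#'
#' Real-valued generated signals (baseline, residual water) must be
#' complexified before addition to complex spectra. The real spectrum is
#' inverse-transformed to the time domain, restricted to its forward-time
#' (causal, analytic one-sided) half, rotated by a 90 degree phase shift
#' (`exp(-i*pi/2)`), and transformed back; the real channel of that result —
#' the discrete Hilbert (dispersion) partner — becomes the imaginary
#' channel, while the original real channel is restored exactly.
#'
#' @param real_spectrum Real numeric vector (a spectrum-domain signal).
#' @return Complex vector with `Re(out)` identical to the input.
#' @examples
#' x <- exp(-(seq(-5, 5, length.out = 64))^2)
#' z <- complexify(x)
#' identical(Re(z), x)
#' @export
complexify <- function(real_spectrum) {
  abort_if(!all(is.finite(real_spectrum)), "input must be finite")
  x <- as.numeric(real_spectrum)
  n <- length(x)
  s <- stats::fft(ifftshift_vec(x + 0i)) / n # time-domain partner
  mask <- numeric(n)
  mask[1] <- 1
  if (n %% 2 == 0) {
    mask[2:(n / 2)] <- 2
    mask[n / 2 + 1] <- 1
  } else {
    mask[2:((n + 1) / 2)] <- 2
  }
  rotated <- s * mask * exp(-1i * pi / 2)
  disp <- Re(fftshift_vec(stats::fft(rotated, inverse = TRUE)))
  complex(real = x, imaginary = disp)
}

#' Time-domain phase rotation of a spectrum
#'
#' Transforms a spectrum to the time domain, applies a global phase
#' `exp(-i * deg * pi/180)`, and transforms back. Two successive 90 degree
#' shifts negate the spectrum (`exp(-i*pi) = -1`).
#'
#' @param spectrum Complex (or real) spectrum-domain vector.
#' @param deg Phase shift in degrees.
#' @return Complex vector.
#' @keywords internal
#' @export
td_phase_shift <- function(spectrum, deg) {
  n <- length(spectrum)
  s <- stats::fft(ifftshift_vec(as.complex(spectrum))) / n
  fftshift_vec(stats::fft(s * exp(-1i * deg * pi / 180), inverse = TRUE))
}

# Shared generator: walk -> complexify -> resample onto the axes ppm grid
# (zero outside ppm_span) -> scale by cfg$scale * ref_level.
#' @noRd
make_nuisance <- function(cfg, axes, ref_level = 1) {
  abort_if(!inherits(cfg, "walk_config"), "`cfg` must be a `walk_config`")
  abort_if(!inherits(axes, "mrs_axes"), "`axes` must be an `mrs_axes`")
  abort_if(cfg$ppm_span[1] < min(axes$ppm) || cfg$ppm_span[2] > max(axes$ppm),
           "`ppm_span` must lie inside the axes ppm span")
  w <- bounded_walk(cfg)
  z <- complexify(w)
  grid <- seq(cfg$ppm_span[1], cfg$ppm_span[2], length.out = cfg$length)
  re <- interp_makima(grid, Re(z), axes$ppm, rule_value = 0)
  im <- interp_makima(grid, Im(z), axes$ppm, rule_value = 0)
  complex(real = re, imaginary = im) * cfg$scale * ref_level
}

#' Generate baseline / residual-water nuisance spectra
#'
#' Runs [bounded_walk()] under the given profile, complexifies the result,
#' resamples it onto the acquisition ppm grid (exactly zero outside
#' `cfg$ppm_span`), and scales it by `cfg$scale * ref_level`. `ref_level`
#' should be the maximum magnitude of the clean metabolite spectrum so that
#' `scale` is a dimensionless, interpretable knob ("order of magnitude
#' matched to the spectra"); [simulate_spectrum()] passes it automatically.
#'
#' @param cfg A [walk_config()]; see [baseline_config()] and
#'   [residual_water_config()] for the default profiles.
#' @param axes Target `mrs_axes`.
#' @param ref_level Amplitude reference the scale multiplies (default 1).
#' @return Complex vector on the full spectral grid.
#' @export
make_baseline <- function(cfg = baseline_config(), axes, ref_level = 1) {
  make_nuisance(cfg, axes, ref_level)
}

#' @rdname make_baseline
#' @export
make_residual_water <- function(cfg = residual_water_config(), axes,
                                ref_level = 1) {
  make_nuisance(cfg, axes, ref_level)
}
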
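# Modified-Akima (makima) interpolation: cubic Hermite evaluation with
# Akima-style slope weights w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]|/2, which
# tempers overshoot near flat regions while staying exact at the nodes and
# reproducing straight lines. Used for spectral crop/resample and for
# mapping nuisance walks onto acquisition ppm grids.

#' Modified-Akima piecewise-cubic interpolation
#'
#' @param x Strictly increasing node positions.
#' @param y Node values (real).
#' @param xi Query positions; values outside `range(x)` return `rule_value`.
#' @param rule_value Value used outside the node range (default 0).
#' @return Interpolated values at `xi`.
#' @keywords internal
#' @export
interp_makima <- function(x, y, xi, rule_value = 0) {
  n <- length(x)
  abort_if(n != length(y) || n < 2, "`x` and `y` must have equal length >= 2")
  abort_if(is.unsorted(x, strictly = TRUE), "`x` must be strictly increasing")
  if (n == 2) {
    out <- y[1] + (xi - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    out[xi < x[1] | xi > x[n]] <- rule_value
    return(out)
  }
  h <- diff(x)
  delta <- diff(y) / h
  # Akima's quadratic end extension of the secant slopes
  d0 <- 2 * delta[1] - delta[2]
  dm1 <- 2 * d0 - delta[1]
  dn <- 2 * delta[n - 1] - delta[n - 2]
  dn1 <- 2 * dn - delta[n - 1]
  m <- c(dm1, d0, delta, dn, dn1) # m[j] = secant slope delta_(j-2)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mi <- m[i:(i + 3)] # m(i-2), m(i-1), m(i), m(i+1) around node i
    w1 <- abs(mi[4] - mi[3]) + abs(mi[4] + mi[3]) / 2
    w2 <- abs(mi[2] - mi[1]) + abs(mi[2] + mi[1]) / 2
    s[i] <- if (w1 + w2 == 0) (mi[2] + mi[3]) / 2 else
      (w1 * mi[2] + w2 * mi[3]) / (w1 + w2)
  }
  idx <- findInterval(xi, x, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= n - 1 & xi >= x[1] & xi <= x[n]
  out <- rep(rule_value, length(xi))
  if (any(inside)) {
    i <- idx[inside]
    u <- (xi[inside] - x[i]) / h[i]
    h00 <- (1 + 2 * u) * (1 - u)^2
    h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u)
    h11 <- u^2 * (u - 1)
    out[inside] <- h00 * y[i] + h10 * h[i] * s[i] +
      h01 * y[i + 1] + h11 * h[i] * s[i + 1]
  }
  out
}
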
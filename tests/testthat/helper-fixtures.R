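# Shared fixtures and oracles for the test suite.

default_axes <- function(n = 4096, sw = 2000, f0 = 127.7, ref = 4.65) {
  make_axes(sw, n, f0, ref)
}

# Chemical shift whose resonance frequency falls exactly on FFT bin k.
on_grid_shift <- function(k, ax) {
  ax$ppm_ref + k * (ax$spectral_width / ax$n_points) / ax$f0
}

# Single-resonance toy basis; shift defaults to an NAA-like 2.01 ppm.
singlet_basis <- function(shift = 2.01, decay = 2, n = 4096, sw = 2000,
                          f0 = 127.7, group = "metabolite") {
  make_toy_basis(data.frame(name = "s", group = group,
                            shift = shift, amp = 1),
                 spectral_width = sw, n_points = n, f0 = f0, decay = decay)
}

# Peak frequency (Hz) of a signal's magnitude spectrum, optionally measured
# on a zero-filled grid for sub-bin resolution.
peak_freq <- function(fid, ax, zf = 1) {
  if (zf > 1) {
    z <- zero_fill(fid, zf * ax$n_points, ax)
    fid <- z$fid
    ax <- z$axes
  }
  ax$f[which.max(Mod(to_spectrum(fid, ax)))]
}

# Numerical FWHM (Hz) of the real spectrum by linear interpolation of the
# half-maximum crossings around the tallest peak.
fwhm_hz <- function(fid, ax) {
  sp <- Re(to_spectrum(fid, ax))
  pk <- which.max(sp)
  half <- sp[pk] / 2
  cross <- function(idx_range) {
    for (i in idx_range) {
      if (sp[i] < half) {
        lo <- sp[i]; hi <- sp[i + sign(pk - i)]
        frac <- (half - lo) / (hi - lo)
        return(ax$f[i] + frac * (ax$f[i + sign(pk - i)] - ax$f[i]))
      }
    }
    stop("no half-maximum crossing found")
  }
  right <- cross(seq(pk, length(sp)))
  left <- cross(seq(pk, 1))
  abs(right - left)
}

# Spectral SNR estimate: max real peak over noise sd from a signal-free
# ppm window.
measure_snr <- function(spec, ax, noise_window = c(7.5, 11)) {
  idx <- ax$ppm >= noise_window[1] & ax$ppm <= noise_window[2]
  max(Re(spec)) / stats::sd(Re(spec[idx]))
}

# Total variation per ppm of the real channel inside a ppm window.
tv_per_ppm <- function(x, ax, window) {
  idx <- which(ax$ppm >= window[1] & ax$ppm <= window[2])
  sum(abs(diff(Re(x[idx])))) / diff(window)
}
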
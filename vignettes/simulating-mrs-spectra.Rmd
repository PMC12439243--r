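---
title: "Simulating in vivo-like proton MR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating in vivo-like proton MR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsim)
```

## The signal model

Single-voxel proton MRS data are modelled as a weighted sum of metabolite
basis functions — noiseless complex time-domain signals (FIDs), one per
metabolite, macromolecule or lipid, each representing the signal from
1.0 mM of its compound — passed through a chain of physically motivated
operators that mirror the acquisition:

1. **Amplitude scaling.** Each basis FID is multiplied by `M_n` (mM-equivalent
   concentration).
2. **Voigt lineshape.** Multiplication by `exp(-(d_n t + g t^2))`: a
   per-metabolite Lorentzian decay `d_n` (s^-1; FWHM contribution `d_n/pi`
   Hz) and a single Gaussian decay `g` (s^-2) per group — one value for the
   metabolites, a second for the macromolecules/lipids. Setting either term
   to zero gives a purely Gaussian or purely Lorentzian line.
3. **Frequency shifts.** `exp(-2i*pi*df_n*t)` with `df_n` the per-metabolite
   shift plus a global metabolite shift; nuisance signals receive their own,
   separate global shift.
4. **B0 inhomogeneity.** A sub-voxel phase ensemble (below).
5. **Nuisance signals.** Semi-parametric baseline and residual-water
   contributions from a smoothed bounded pseudo-random walk (below).
6. **Noise.** Complex Gaussian noise calibrated to a target spectral SNR
   (below).
7. **Phases.** Zero-order phase `exp(-i*phi0*pi/180)` applied in the time
   domain; first-order phase `exp(-i*phi1*pi/180*(ppm - ppm_ref))` applied
   in the frequency domain, pivoting at the water reference `ppm_ref`
   (default 4.65 ppm, hence invariant there).
8. **Eddy currents.** The two-parameter first-order model
   `exp(-2i*pi*A0*exp(-t/tc)*t)`; the FID magnitude is pointwise unchanged.
   When `tc` greatly exceeds the readout the term degenerates to a global
   `+A0` Hz shift, so amplitude/time-constant combinations must be chosen
   jointly.

`simulate_spectrum()` composes the chain in that order and stores every
stochastic component it used (metabolite sum, baseline, residual water,
noise realization, B0 map, parameters) in the returned record;
`reconstruct_record()` re-derives the output from those parts, and the test
suite holds that audit to 1e-6 relative.

Two orderings in the chain were genuinely open. First, the equations define
phases as operating on the signal *including* noise, while one could argue
noise should be injected after phase rotations; we apply noise before the
phases, matching the model equation read left to right (a complex Gaussian
is rotation-invariant in distribution, so only the stored realization — not
the statistics — depends on this choice). Second, eddy currents are applied
after both phase terms, again following the equation's composition order
rather than the looser prose ordering.

### Conventions

* **Fourier transform.** The spectrum is the fftshifted unnormalized inverse
  DFT of the FID, so a resonance evolving as `exp(-2i*pi*f*t)` — the
  rotating-frame sign used by every operator above — appears at `+f` Hz.
  This makes the signs literal: a `+10` Hz voxel-mean B0 offset, a `+5` Hz
  frequency shift, or a long-`tc` eddy term of amplitude `+5` Hz each move
  peaks by exactly that amount along the frequency axis. The convention is
  pinned by a single-complex-exponential oracle test.
* **Hz means Hz.** All frequency-valued parameters carry an explicit `2*pi`
  inside the exponents.
* **ppm axis.** `ppm = ppm_ref + f/f0`, stored ascending; display functions
  reverse the axis, following the convention of plotting chemical shift
  decreasing to the right. The zero-frequency bin maps exactly to `ppm_ref`.

## B0 inhomogeneity as a sub-voxel ensemble

Within a spectroscopy voxel, the static field varies spatially; treating the
voxel as a point misses the resulting line broadening and damping.
`make_b0_map()` builds a 3D grid of per-subvoxel frequency offsets (Hz)
described by four quantities: half-ranges `dx, dy, dz` of the linear change
along each axis and the voxel mean `mu`. The grid resolution represents the
spectroscopy voxel divided by an anatomical imaging voxel; the endpoints are
placed at `(i-1)/(n-1) - 1/2` so the stated half-ranges are met exactly at
the voxel faces. The isotropic total spread is `Delta = 2*dx = 2*dy = 2*dz`.
The linear profile is an extension point; other gradient shapes can be added
without touching the application step.

`apply_b0()` multiplies the FID by the *mean* of the per-offset phase ramps.
The mean (rather than the bare sum) is a deliberate normalization: grid
resolution is a numerical choice, not physics, so refining the grid must not
rescale the signal. Consequences, all tested: the zero map is an exact
identity; a constant map is a pure `+mu` Hz shift with unchanged peak
height; growing spread monotonically damps the peak; and the result depends
only on the multiset of offsets, not their arrangement.

## Baseline and residual water

No physics-based model exists for the smooth spectral background or for the
imperfectly suppressed water region, so both are generated by a smoothed
bounded pseudo-random walk with profile presets rather than by claiming a
true physical shape:

1. cumulative sum of Gaussian steps with standard deviation `std`;
2. subtraction of the linear trend between `start` and `end`;
3. rescaling of the residual deltas so their range spans the bounds;
4. clipping of `trend + deltas` into `[lower_bound, upper_bound]` (the
   conditional-adjustment step; clipping preserves boundedness without
   distorting interior structure, and the subsequent smoothing removes clip
   plateaus);
5. a uniform moving average of size `window_size * length`, with reflective
   padding so the output keeps its length and, being a convex combination,
   its bounds. The kernel is forced to the nearest odd size so features are
   not shifted by half a sample. With `std = 0` the deltas are defined as
   identically zero and the walk reduces to the smoothed trend.

The walk is then complexified: the real spectrum is inverse-transformed,
restricted to its causal (forward-time, analytic one-sided) half, rotated by
90 degrees in the time domain, and transformed back; the real channel of
that result is the discrete Hilbert (dispersion) partner and becomes the
imaginary channel, while the original real channel is restored bit-exactly.
Finally the signal is resampled onto the acquisition ppm grid (zero outside
its `ppm_span`) and scaled by `scale` times the maximum magnitude of the
clean metabolite spectrum, making `scale` a dimensionless knob.

The two presets differ only in configuration: `baseline_config()` uses small
step noise (`std = 0.05`), a wide window (30% of the walk) and the full
metabolite region (0.2–4.2 ppm), giving broad smooth undulations;
`residual_water_config()` uses large step noise (`std = 1`), a narrow window
(2%) and a narrow span around the water reference (4.2–5.1 ppm), giving
irregular localized structure. The literature characterizes these signals
only qualitatively, so the numeric presets are package defaults chosen to
reproduce that qualitative contrast — the test suite checks it via total
variation per ppm — and every field is user-configurable.

## Noise and SNR

Spectral SNR is defined as the maximum real-channel peak height divided by
one standard deviation of the noise. Given a target `snr` and the clean
reference peak height (of a chosen metabolite, or of the metabolite sum),
the per-bin frequency-domain noise standard deviation is
`sigma = ref_peak_height / snr`. Real and imaginary channels are independent
draws by default; optionally a single vector is drawn and its quadrature
partner built with `complexify()`. Noise is generated in the frequency
domain — where the definition lives — and injected into the FID by the
inverse transform; under the package's conventions the equivalent
time-domain standard deviation is `sigma / sqrt(n_points)`, a relation the
tests verify. Requested SNR is recovered by measurement (peak over the noise
standard deviation estimated in a signal-free window) to within 5% averaged
over 200 seeds.

## Transients

One noiseless FID can be expanded into `C` transients — coil elements or
signal averages — each scaled by a sensitivity weight, rotated by
per-transient frequency and phase drifts, and given its own noise. The
default sensitivity sampler is a Gaussian with mean 1.0 and standard
deviation 0.5 clamped to [0, 2] (symmetric, so the expected weight stays 1).
Per-transient noise targets `(snr / sqrt(C)) * snr_scale_c`, the target SNR
scaled down by the square root of the transient count, with `snr_scale_c`
drawn from a narrow normal (`N(1, 0.05^2)`, clamped positive) to vary SNR
across transients while maintaining the mean; equal-weight averaging then
recovers the target, and the sqrt(C) combination gain is verified at
C = 4, 16 and 64. Drift samplers default to `N(0, 2^2)` Hz and `N(0, 5^2)`
degrees and are fully configurable, so coil-type artifacts (sensitivity,
SNR) and average-type artifacts (drifts) can be enabled independently.
`combine_transients()` implements the weighted mean (recommended) and the
amplitude-preserving normalized sum — algebraically the same operation —
and `remove_known_drifts()` applies the exact inverse rotations
(ground-truth removal, not estimation).

## Post-processing and formats

`apodize()` multiplies by `exp(-t*TL)` (adds `TL/pi` Hz of Lorentzian
width), `zero_fill()` pads to a denser spectral grid, and `crop_resample()`
interpolates the real and imaginary channels separately onto a requested ppm
window with a hand-implemented modified-Akima piecewise cubic — exact at the
nodes, reproduces straight lines, and tempers the overshoot of ordinary
splines near sharp features.

Records are exported in two forms. The keyed JSON container stores every
array as base64-encoded IEEE-754 doubles, so round-trips are bit-exact and
the complete ground truth travels with the data. NIfTI-MRS export writes
NIfTI-2 files with complex-double time-domain data in dimension 4, the dwell
time in `pixdim[5]`, the JSON header extension (ecode 44) carrying the
spectrometer frequency, nucleus and — for transient records — the `DIM_COIL`
tag for dimension 5. Because the NIfTI header stores `pixdim` in single
precision, the exact dwell time is also carried in the JSON sidecar and
preferred on import.

## Parameter sampling and distribution analysis

`sampling_scheme()` + `sample_params()` draw per-record parameters from
declarative specs (constant, uniform, normal, truncated normal, gamma,
lognormal), deterministic under a seed. For the inverse problem —
choosing realistic ranges from in vivo fitting results — `load_fit_table()`
reads delimited exports of spectral-fit parameters and `fit_distributions()`
fits candidate families by maximum likelihood (closed form for the uniform;
direct likelihood optimization for the truncated normal; `fitdistrplus` for
the rest), ranking them by the sum of squared errors against a fixed-binning
histogram with AIC as tiebreaker. Parameter recovery is tested to within 5%
at n = 10^4 for the normal, uniform and gamma families.

## Batch runs

`run_config()`/`run_simulation()` (or the `inst/cli/mrsim` wrapper) generate
N records in batches. Each record's seed derives deterministically from the
master seed and the record index, so outputs are invariant to the batch size
and reruns are byte-identical; the manifest logs every file, seed and
sampled parameter — the sampled parameters *are* the ground truth.

## What the toy basis does and does not show

`make_toy_basis()` builds basis FIDs as sums of damped complex exponentials
at requested chemical shifts, with a mild fixed Lorentzian decay (2 s^-1 by
default) so spectra are integrable. This is a deliberately simple stand-in
for externally simulated basis sets: real basis functions carry J-coupled
multiplet structure, sequence- and TE-dependent phase evolution, and
spatially resolved excitation profiles that singlets cannot express. Tests
passing on toy bases therefore validate the *operators* — scaling, line
shapes, shifts, B0 ensembles, noise calibration, transients, processing, IO
— not the biochemical realism of any particular spectrum. For realistic
work, load a density-matrix-simulated basis via `load_basis()`.

## Problem sizes and numerical choices

The test and acceptance workloads use 2000 Hz spectral width with 4096
points (0.488 Hz per bin) for calibration checks, and 128–2048 points for
structural checks; SNR calibration averages 200 seeds, combination gain 20–25
seeds per coil count, walk boundedness 10^4 random configurations, and
distribution recovery 10^4 samples — sizes chosen so the full suite runs in
under a minute while keeping Monte-Carlo error well below the asserted
tolerances. Peak positions measured from discrete spectra are accurate to
one frequency bin; where sub-bin accuracy matters (B0 shift, long-`tc` eddy
shift) the measurement zero-fills by 16x first. Degenerate inputs are
defined explicitly: `eddy_a0 = 0` bypasses the eddy term regardless of `tc`;
`std = 0` walks reduce to the smoothed trend; a zero B0 map and zero-valued
phases are exact identities.

## Known limitations

* No quantum-mechanical (density-matrix) basis simulation, pulse-sequence or
  vendor-specific modelling; basis sets come from external simulators or the
  toy generator.
* No susceptibility-derived or acquired B0 maps; only parametric gradient
  profiles.
* No spectral fitting, quantification, or artifact-correction algorithms
  (e.g. eddy-current correction), and no estimation-based coil combination
  (water-SNR weighting, noise-whitening PCA) — drift removal uses the known
  ground truth.
* Baselines and residual water are explicitly semi-parametric
  approximations; no claim is made that any generated profile is a true in
  vivo baseline.
* No vendor raw formats (Twix/P-file) or DICOM-MRS.
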
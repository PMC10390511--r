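---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuroload)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

# The analysis problem

Stimulus-free tasks that vary only internal workload — resting with eyes
open, counting backward by ones, counting backward by sevens — change
ongoing EEG dynamics in several ways at once: canonical band amplitudes
shift, the broadband 1/f ("scale-free") trend of the spectrum rotates, and
the coupling between low-frequency phase and gamma-band amplitude
strengthens. The package implements one coherent pipeline for all of these
facets so they can be estimated from the same preprocessed data and
compared on the same effect-size scale.

# Spectral estimation

Amplitude spectra use Bartlett's method: each recording is cut into
non-overlapping 1-s epochs (60 epochs for a 60-s task), the magnitude
spectrum of each epoch is taken with a rectangular window, and the epoch
spectra are averaged. Scaling is one-sided `2/L`, so a unit-amplitude
sinusoid at an integer frequency reads 1.0 at its bin; the convention is
internal — every downstream statistic is scale-invariant — but it is fixed
and tested. Spectra span 1–100 Hz at 1-Hz resolution. The 50-Hz mains bin
is replaced by the mean of the 49- and 51-Hz bins, exactly.

Two canonical band-edge presets ship, because two sets are in circulation
in the literature this pipeline follows: the default `"statistics"` preset
(theta 4–7, alpha 8–12 Hz) used for every reported test, and a
`"spectrum"` preset (theta 4–8, alpha 9–12 Hz). Beta is 13–30 and gamma
31–90 Hz in both. Delta is excluded: a 1-Hz high-pass and 1-s epochs leave
nothing trustworthy below 2 Hz.

# Split-band aperiodic model

Within a frequency segment the aperiodic component is linear in log–log
coordinates,

$$\log_{10} A(f) \;=\; \mathrm{offset} - \chi \,\log_{10} f ,$$

with up to `max_peaks` Gaussian humps added in (log-amplitude vs linear
frequency). Empirical EEG spectra are not a single power law: there is a
visible break of the log–log slope in the low-beta range, so the model is
fitted separately on 1–25 Hz (allowing 2 peaks — alpha and beta humps) and
26–90 Hz (0 peaks). The split frequency is a configuration scalar; setting
it to 30 reproduces the usual robustness check. No knee parameter is
fitted inside a segment — the two-segment split is the knee.

Numerics: the fit is deterministic two-stage least squares. A robust line
is seeded from the median log-amplitudes of the first and last decile of
bins and refined by iterated OLS with the most positive residuals (peak
candidates) masked; peaks are then seeded greedily at the largest positive
residuals and all parameters refined jointly with `L-BFGS-B` (objective
tolerance 1e-8, at most 500 iterations, exponent bounded at 0, peak width
bounded to 1–12 Hz, centres confined to the segment). Peaks refined below
0.05 log10 units are dropped. Fits are reported with R² on the
log-spectrum. Fitting is done on *amplitude* spectra; users fitting power
spectra should note the exponent doubles, and exponents are only
comparable within one convention.

The "1/f-free" spectrum subtracts the fitted aperiodic curve bin-wise in
linear amplitude units; negative residual amplitudes are expected and
preserved. Because the residual is not positive, it cannot be refitted
through the log-domain model; the self-consistency check divides the raw
spectrum by the fitted curve (log-domain flattening) and verifies the
refitted exponent is near zero.

Split-half reliability cuts each participant's epochs into halves, fits
each half, and reports the across-participant Pearson correlation per
electrode and parameter. It is a *between-participant* statistic: it needs
real between-participant spread to be meaningful, which is why the
generator's effect specification accepts a `baseline_sd`.

# Phase-amplitude coupling

The modulation index follows the standard Kullback–Leibler recipe: filter
the signal in a low (phase) and a high (amplitude) band with zero-phase
windowed-sinc FIR filters (length = 3 cycles of each band's low edge),
take Hilbert phase and amplitude, discard one filter length at each end,
average the amplitude within `N = 18` equal phase bins on `[-π, π)`
(left-closed, first bin at −π; empty bins contribute `0·log 0 = 0`),
normalize to a distribution `P`, and report

$$\mathrm{MI} = \frac{\log N - H(P)}{\log N} \in [0, 1].$$

The phase-frequency sweep runs 1–20 Hz in 0.1-Hz steps with a ±1-Hz
pass-band clipped below at 0.5 Hz, on the whole continuous signal (not per
epoch). Two cautions, both visible in the tests: below roughly 4 Hz a 60-s
signal contains too few phase cycles for a stable MI, so null sweeps are
heavy-tailed at the low end; and on a 1/f background the single-recording
argmax of the sweep is biased upward by a few tenths of a Hz (bands just
above the rhythm contain less background noise), so peak location should
be read from an averaged sweep curve, as cohort-average PAC profiles are.

The qualitative PAC view uses the generalized Morse wavelet (symmetry
γ = 3, time–bandwidth product γβ = 60, peak-normalized so a unit sinusoid
has ridge modulus 1). Epoch TFRs are averaged after circularly shifting
each epoch by `phase/(2π f_low)` seconds, where the phase is read from the
wavelet coefficient at `f_low` at the epoch midpoint. This delay zeroes
the midpoint phase: epochs whose oscillation peaks earlier in time carry a
larger midpoint phase and are shifted rightward. Folding cuts the averaged
TFR into one-period segments of `f_low`, averages them and the 31–90-Hz
rows, and yields the amplitude-vs-phase profile. The fold's time origin is
the aligned zero-phase point at the epoch midpoint; mapping fold position
to phase therefore subtracts `2π f_low t_mid`.

# Preprocessing

The deterministic chain is: integer-factor downsampling behind a
zero-phase anti-alias low-pass; zero-phase Hamming windowed-sinc high-pass
with the −6 dB point at half the passband edge (1-Hz edge → −6 dB at
0.5 Hz) and the conventional order heuristic (3.3 × fs / transition width,
rounded up to even, plus one: 827 taps at 250 Hz); bad channels flagged
when their variance exceeds the median channel variance plus 4 scaled
median absolute deviations (MAD constant 1.4826 — note MATLAB's `mad`
default is unscaled) — computed after downsampling, before filtering;
inverse-distance-weighted interpolation over the adjacency graph (a
deliberate, documented simplification of spherical splines); common
average reference; 1-s epoching with the remainder dropped. ICA-based
artifact removal is not re-implemented; `preprocess()` exposes a `cleaner`
hook that accepts and returns a recording between re-referencing and
epoching.

# Electrode geometry and the cluster test

The built-in 32-channel 10–20 montage stores idealized 2-D
azimuthal-equidistant positions on rings (vertex, r = 0.20, 0.38, 0.52,
0.65 of the head radius scale). The default adjacency connects electrodes
closer than 1.3 × the median nearest-neighbour distance; the graph is
overridable from a two-column TSV edge list, so an exact published map can
be supplied.

The cluster-based permutation test thresholds per-electrode paired t-maps
at p < 0.01, forms sign-separated connected components of at least 4
electrodes, scores each by its summed t, and builds the null by reversing
the condition labels of a fresh random ⌊n/2⌋-participant subset per
permutation (2000 by default). The null records the *maximum* |t_sum| over
clusters found in each permutation — the max-statistic completion that
gives family-wise control — and cluster p-values use the add-one rule, so
p ≥ 1/(n_perm + 1).

One calibration subtlety the tests make explicit: the family-wise rate of
this procedure is bounded above by the probability that any cluster forms
at all under the null. With spatially *independent* electrode features
that probability is essentially zero (the test is extremely conservative),
so calibration is informative only in the spatially smooth regime real
EEG topographies occupy. The calibration suite therefore draws null
feature maps from a Gaussian spatial process over the montage (length
scale 0.5 in montage units, unit marginals). Even in the most favourable
smooth regime the attainable family-wise rate tops out near 0.04 under
these settings.

Outlier exclusion uses the 2 × IQR rule (note: 2, not the common 1.5),
with quartiles by linear interpolation of order statistics (R type 7;
borderline exclusions can differ from tools using midpoint quartiles).
For paired tests it is applied to the paired differences, which is what
makes per-comparison degrees of freedom vary. Cohen's d is `t/√n` with
`n` the retained pair count, exactly.

# The synthetic generator: a stated world

`generate_recording()` synthesizes each channel by spectral shaping of
white Gaussian noise: a target amplitude profile — the two-segment power
law joined at 25/26 Hz with no smoothing, times Gaussian humps in
log-amplitude — is imposed in the frequency domain with random phases.
Shaping is done **independently per 1-s block on the 1-Hz analysis
grid**, calibrated so the expected Bartlett amplitude equals the profile
exactly at every bin. This choice is deliberate: shaping the whole 60-s
signal at dense frequency resolution and then analysing it with
rectangular 1-s epochs leaks the steep low-frequency power into the high
band through the window's sidelobes and biases the recovered high-band
exponent upward by several tenths — defeating the generator's purpose of
exact slope control. The price of blockwise shaping is an amplitude
discontinuity at block boundaries; Bartlett epochs never straddle a
boundary, and the PAC filters see 59 step artifacts spread uniformly over
phase, which the binned means average out.

PAC is generated by multiplying the channel's own gamma-band (31–90 Hz)
noise content — plus an optional extra broadband carrier at the coupling
site — by the envelope `1 + m g_ch cos φ(t)`, where `φ(t)` is the Hilbert
phase of a narrowband noise rhythm at the phase frequency (default 9 Hz,
Gaussian spectral width 0.5 Hz, peak amplitude 3 µV), synthesized
continuously so its phase evolves smoothly. Two design points matter:

- modulating the band content *in place* leaves the log–log slope
  independent of the coupling depth up to O(m²) sidebands, so the PAC and
  aperiodic ground truths do not contaminate each other (an additive flat
  carrier strong enough for MI detectability demonstrably flattens the
  high-band fit at the coupling site, and — once smeared across the scalp
  by the common average reference — everywhere else);
- a narrowband *noise* rhythm rather than a pure sinusoid is what makes
  the phase-frequency sweep localize: a sinusoid keeps every overlapping
  band phase-locked and the sweep plateaus.

Default magnitudes were chosen once, for identifiability and realism, and
are not revisited: aperiodic offsets 1.0 (low) and 1.7 (high) in log10 µV
with exponents 1.0 / 1.5 give ~1 µV at 10 Hz and ~0.06 µV at 90 Hz;
sensor noise 0.05 µV per sample keeps the flat noise floor below the 1/f
background across the whole 1–90-Hz analysis range, as in cleaned EEG —
when a flat floor reaches the high-band background it compresses the
steeper condition's fitted exponent more and can invert recovered
between-condition differences. Spatial structure uses fixed Gaussian gain
templates (frontal theta, posterior alpha, Oz-centred PAC with a tight
σ = 0.18 field so the modulated gamma does not reach the electrodes used
to read the aperiodic effect).

Cohorts draw per-participant baseline variation (`baseline_sd`) and a
personal between-condition shift `N(mean, sd)` per named parameter;
condition order is counterbalanced at random; every random draw descends
from one cohort seed through a splittable integer-hash scheme, so cohorts
are bit-reproducible.

What the generator does *not* emulate — and hence what a green test does
not establish: ocular/muscle artifacts and their gamma contamination,
volume conduction and reference-dependent spatial correlation of the
background (channels are independent except the PAC rhythm), non-Gaussian
and non-stationary dynamics within a block, and any relation between the
behavioural reports and neural features beyond the one the demo plants
(hard-task performance declining with stronger exponent change).

# Degenerate inputs and tie-breaks

Zero signals produce zero spectra and zero TFRs; a constant vector
survives outlier exclusion untouched (IQR = 0 keeps equal values); paired
t on identical vectors returns t = 0 and d = 0, and a zero-variance,
nonzero-mean difference returns signed infinity rather than NaN; phase
exactly +π lands in the last bin; `0·log 0 = 0` throughout the entropy
arithmetic; epoching drops a trailing partial epoch; the notch and fold
operations are idempotent where the contract says they are.

# Known limitations

The 1/f fit assumes strictly positive amplitudes on the segment, so it
refuses 1/f-removed spectra rather than guessing. The high-band exponent
at a strongly coupled site is biased low by O(m²) sideband smoothing of
the modulated gamma — a real-world entanglement of broadband gamma with
the scale-free component, localized here by the tight PAC gain. The
behavioural correctness criterion is a divisibility proxy: a compensating
pair of counting errors can pass it. The CLI covers the documented
subcommands but is a thin wrapper; programmatic use is the primary
interface.
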
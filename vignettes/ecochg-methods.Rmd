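---
title: "Separating hair-cell and neural components of the ongoing ECochG response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating hair-cell and neural components of the ongoing ECochG response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecochg)
```

## The problem

The ongoing portion of an ECochG response to a low-frequency tone — the
steady-state region between the compound action potential at onset and the
stimulus offset — mixes two sources with completely overlapping time courses
and the same fundamental frequency. The cochlear microphonic (CM) follows
hair-cell transducer currents; the auditory nerve neurophonic (ANN) is the
far-field signature of phase-locked auditory-nerve firing. Both distort the
recorded waveform away from the stimulus sinusoid, but through different
mechanisms: the CM through saturation of the transducer nonlinearity, the
ANN through the half-wave rectification inherent in spike-rate modulation.
Because the ANN's energy lies mostly at the stimulus fundamental, where it
mixes with the CM, second-harmonic magnitude alone cannot quantify the
neural contribution; a generative model of both sources, fit jointly, can.

## The forward model

One stimulus cycle is modeled as `ECochG(t) = CM(t) + ANN(t)` on a grid of
`round(fs / f)` samples (`time_grid()`), where `fs` is the sampling rate and
`f` the stimulus frequency.

**CM.** A sinusoid `A_CM sin(2π(f t − φ_CM))` clipped pointwise to
`[LowerCutoff, UpperCutoff]`. The two cutoffs represent independent peak and
trough saturation, which captures both asymmetric saturation (operating
point away from the midpoint of the transducer function) and symmetric
saturation at high intensity, without committing to a particular Boltzmann
shape or operating point.

**ANN.** The circular convolution of a population cycle histogram (CH) with
a unit potential (UP), scaled by `A_ANN` and circularly shifted by `φ_ANN`.
The UP is a single cycle of a sinusoid at 1,100 Hz with unit peak; the CH is
a lognormal-shaped density over the stimulus cycle whose width is the spread
of excitation (SOE). Half-wave rectification of phase locking is reflected
in the CH being effectively zero over part of the cycle.

### Parameterization choices

Several details of this construction are genuinely underdetermined and were
fixed as follows.

* **Cycle-histogram time scale.** The lognormal density is evaluated with
  time expressed in units of UP periods (`x = t · f_UP`), `meanlog = 0` and
  `sdlog = SOE`, then renormalized to unit peak. Time zero maps to a small
  positive epsilon (1e−6) to avoid the lognormal singularity. This reading
  keeps the density's mode early in the cycle (at `exp(−SOE²)` UP periods)
  and makes its width grow monotonically with SOE over the allowed range
  0.35–0.65; alternative scalings shift the mode but are absorbed by the
  fitted ANN phase.
* **Kernel normalization.** `CH ⊛ UP` is normalized to unit peak magnitude
  before `A_ANN` scaling, so the fitted `A_ANN` is in µV and directly
  comparable with `A_CM`.
* **Phase anchoring.** The raw convolved kernel has an arbitrary intrinsic
  phase that varies with SOE. The kernel is therefore advanced — by a
  fractional circular shift computed in the frequency domain, so it remains
  smooth in SOE — until its fundamental aligns with an unshifted sine. With
  this convention `φ_ANN = φ_CM` means the two components' fundamentals are
  in phase and interfere constructively (maximum peak-to-peak), and the
  fitted phase difference is directly interpretable. This is a labeling
  convention only: it relabels which `φ_ANN` corresponds to which waveform.
* **UP polarity.** The unit potential begins with its negative-going half
  cycle (N1-first, as a spike appears at the round window). The sign is
  absorbed by the ±2-cycle phase range, so this too is only a convention.
* **Phase resolution.** `φ_ANN` is applied as an integer-sample circular
  shift (the discrete-shift semantics of the original implementation), so
  its resolution is `1/n` cycles — 1/32 at the default 500 Hz / 16 kHz
  grid. `φ_CM` enters the sinusoid analytically and is continuous.

## Fitting

`fit_decomposition()` minimizes the sum of squared residuals between the
model and the observed average cycle, subject to bounds taken from the
model's published constraints: amplitudes in `[0, 5 × max(input)]`, phases
in `[−2, 2]` cycles, SOE in `[0.35, 0.65]`, and cutoffs between 50% of the
input extremum and the amplitude bound (at the outer bound the clipping
branch never activates). The solver for the six smooth parameters is
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, first-order
optimality tolerance 1e−6 by default).

The ANN phase shift is discrete, so its objective is piecewise constant and
gradient-free; it is handled by profiling rather than descent:

1. **Screen.** Every candidate shift (all `n`) gets two quick optimizations
   of the smooth parameters from standard starts.
2. **Polish.** The best `multistart_phases` shifts (default 8, plus the
   initial-guess shift) are re-optimized from a full grid of starts: four
   `(A_CM, cutoffs)` regimes × three SOE values.
3. **Hill-climb.** The incumbent is refined over neighboring shifts,
   warm-started, until no improvement. Ties keep the earliest start.

The four start regimes exist because the cutoff parameters have exactly
zero gradient whenever no sample is clipped: a fit started with inactive
cutoffs can never discover saturation. The regimes start the cutoffs
inactive, at the observed extrema, marginally active at the first-harmonic
amplitude, and — for deeply saturated responses — with the sinusoid
amplitude inflated to 1.3× the first harmonic so that clipping is engaged
from the outset. The SOE starts (both bounds and the midpoint) address the
multimodality introduced by the kernel's envelope moving with SOE. With this
strategy every noise-free self-generated test case in the suite is refit to
machine-precision residuals; a single-start fit (`multistart_phases = 1`)
remains available for speed.

The initial guess is deterministic: `A_CM` and `φ_CM` from the first
harmonic of the cycle, `A_ANN = 0.2 A_CM`, `SOE = 0.5`, `φ_ANN = φ_CM`,
cutoffs at their no-clipping bounds. The returned solution is never worse
than this guess, since the guess itself is among the polished starts.

Goodness of fit follows the dual convention: `r` is the maximum normalized
cross-correlation over circular lags (insensitive to pure time shifts),
while `r²` is the zero-lag coefficient of determination — so a shifted but
otherwise perfect model scores `r = 1`, `r² < 1`. The objective uses one
cycle; for a circular model, fitting two concatenated cycles would yield the
identical optimum at double the cost.

## Preprocessing and spectra

`extract_average_cycle()` folds the ongoing window into one cycle by a
pointwise mean over whole cycles only (a trailing partial cycle is
discarded to avoid phase smearing). The default window skips the stimulus
rise ramp plus two cycles at onset — clearing the CAP, which can be delayed
— and the fall ramp plus one cycle at offset. The default analysis uses a
single polarity's average cycle; `combine_polarities()` offers the
half-difference and half-sum combinations for alternating-polarity
protocols.

`harmonic_spectrum()` reports single-sided amplitude spectra in µV. An
average cycle is analyzed on eight concatenated copies so every harmonic
falls exactly on an FFT bin with no window function, avoiding leakage
arbitrariness. A harmonic is significant when it exceeds the local noise
floor — mean of the 3 bins on either side of the peak, pooled (6 bins, peak
excluded) — by more than 3 standard deviations. Two numerical details: bins
within double-precision roundoff of zero (relative to the largest spectral
line) are treated as exactly zero, so noise-free periodic signals give
deterministic significance calls; and the DC bin is never used as a noise
bin. `total_response()` sums significant harmonics 1–3 across stimulus
frequencies.

## Metrics

`decomposition_metrics()` reports component magnitudes on one of two bases:
the raw fitted amplitude parameters, or (default) the first-harmonic
magnitudes of the separated component waveforms, which is the spectral
reading used when components are compared on a common scale — saturation
moves CM energy out of the fundamental, so the bases differ exactly when
clipping is active. Derived quantities are the ANN/CM ratio, the ANN/CM
index `(ANN − CM)/(ANN + CM)`, and the dB difference `20 log10(ANN/CM)`.
`apply_small_ratio_cutoff()` implements the no-response rule: fitted ANN
magnitudes below 5% of the CM (strict `<`) are zeroed and flagged, because
the fit rarely returns much less than that even for purely hair-cell
responses; the cutoff is never applied to the index, and the ratio/index/dB
fields keep their pre-cutoff values for reporting.

## The simulated-signal harness

`generate_simulated_cycle()` evaluates the same forward model used in
fitting and adds i.i.d. Gaussian noise of chosen standard deviation —
additive Gaussian noise is an assumption; the noise of real recordings is
not characterized here. `sweep_preset()` encodes the five published
validation sweeps (100 noise-free signals each, 500 Hz at 16 kHz): ANN
amplitude 0.01–2 µV; CM–ANN phase difference −0.5–0.5 cycles; trough
saturation 0–15% of the CM amplitude; peak saturation 0–10% with trough
saturation fixed at 15% and ANN 0.43 µV; and SOE 0.35–0.65 cycles. The
remaining parameters in each sweep are CM 1 µV, ANN 0.3 µV, SOE 0.65 and
zero phase difference unless the sweep itself sets them.

What passing these sweeps shows — and does not show. The harness emulates
only the average cycle of the ongoing response: no onset CAP, no stimulus
ramps, no summating-potential offset, no cycle-by-cycle CM adaptation, and
a noise model that is white and Gaussian. Recovery on these signals
demonstrates that the fitter inverts its own generative model reliably
(identifiability and optimizer coverage), not that real responses obey the
model. In particular, real high-intensity responses can show a declining
peak within each cycle that the saturating-sinusoid CM cannot represent;
the fit then attributes that distortion to the ANN, which is the model's
known overestimation regime. The converse regime — a very large CM masking
a small ANN — motivates the 5% cutoff above.

## Sizes, tolerances and degenerate inputs

The test suite and validation scripts use the 32-sample cycle (500 Hz at
16 kHz) that mirrors the human recording configuration, with short sweeps
(5–7 points) for routine testing and the full 100-point sweeps available
through `sweep_preset()`. Degenerate inputs fail fast with classed
conditions: zero-energy cycles and cycles that do not cross zero are
rejected before fitting; a constant observed series makes `r`/`r²`
undefined and errors; both-zero magnitudes make the index undefined.
Individual fit failures inside a sweep are recorded per signal rather than
raised. JSON reports are written at full (17-digit) precision so they
round-trip exactly.

## Known limitations

* ANN estimates below ~5% of the CM are not trustworthy (hence the cutoff),
  and very large CM responses inflate the apparent ANN.
* The CM model omits cycle-by-cycle adaptation and separate inner/outer
  hair-cell contributions; the ANN model omits dendritic potentials and
  uses a fixed-shape UP.
* `φ_ANN` resolution is one grid sample; at coarse grids (low sampling
  rate relative to the stimulus) phase-difference recovery is limited
  accordingly.
* The lognormal cycle-histogram parameterization is one defensible reading
  of an underdetermined construction; its tail wraps into the next cycle at
  large SOE, which is physiologically interpretable as overlapping spread
  but is still a modeling choice.
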
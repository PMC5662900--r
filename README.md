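# ecochg

Decomposition of the ongoing electrocochleography (ECochG) response to
low-frequency tone bursts into its two underlying sources: the **cochlear
microphonic** (CM), generated by hair-cell transducer currents, and the
**auditory nerve neurophonic** (ANN), the evoked-potential correlate of
phase-locked auditory-nerve firing. The two components overlap completely in
time and share the stimulus frequency, so they cannot be separated by
filtering or spectral analysis alone; `ecochg` separates them by fitting a
parametric model of each source to the response's average cycle. The package
is aimed at auditory electrophysiologists working with round-window or
intracochlear recordings — for example ECochG obtained during cochlear
implantation — who need an objective estimate of how much of a response is
neural.

## The model

One stimulus cycle of the ongoing response is modeled as the sum of the two
components,

    ECochG(t) = CM(t) + ANN(t)

**CM** — a sinusoid at the stimulus frequency *f* that can saturate
independently at its peak and trough (hair-cell transduction is a saturating
nonlinearity whose operating point sets the asymmetry):

    CMsine(t) = A_CM · sin(2π(f·t − φ_CM))
    CM(t)     = clip(CMsine(t); LowerCutoff, UpperCutoff)

**ANN** — the circular convolution of a population *cycle histogram* (CH)
with a *unit potential* (UP), scaled and phase-shifted:

    ANN(t) = A_ANN · shift(CH(t) ⊛ UP(t); φ_ANN)

The CH is a lognormal-shaped, half-wave-rectified firing-probability density
whose width is the spread of excitation (SOE, 0.35–0.65 stimulus cycles);
the UP is a single sine cycle at 1,100 Hz. The convolved kernel is
normalized to unit peak so that `A_ANN` is in µV, and its fundamental is
phase-anchored so that `φ_ANN = φ_CM` means the components interfere
constructively.

The seven free parameters (`A_CM`, `φ_CM`, upper/lower cutoff, `A_ANN`,
`φ_ANN`, `SOE`) are estimated by bounded nonlinear least squares against the
average cycle, with a multistart/profile strategy over the discrete ANN
phase shift. Goodness of fit is reported as the maximum circular-lag
cross-correlation *r* and the zero-lag coefficient of determination *r²*.
Summary metrics include the ANN/CM ratio, the ANN/CM index
`(ANN − CM)/(ANN + CM)` (−1 all CM, 0 equal, +1 all ANN), dB differences,
and the <5% small-ratio cutoff used to suppress implausibly small ANN
estimates.

## Worked example

Simulate a response whose ground truth is known — a 1 µV CM with 15% trough
saturation plus a 0.43 µV ANN — add a little noise, and refit it:

```r
library(ecochg)

grid  <- time_grid(500, 16000)            # one 500 Hz cycle at 16 kHz: 32 samples
truth <- model_params(
  saturating_cm(1, trough_saturation_pct = 15),
  ann_params(0.43, phi_ann = 0.1, soe = 0.65)
)
cycle <- generate_simulated_cycle(truth, grid, noise_sd = 0.02, seed = 7)
fit   <- fit_decomposition(cycle)
fit
#> ECochG decomposition fit
#>   32 samples at 16000 Hz (stimulus 500 Hz)
#>   r = 0.9997, r^2 = 0.9994, SSE = 0.0136 uV^2
#>   CM:  A = 1.017 uV, phase = 0.002403 cy, cutoffs [-0.8452, 1.009] uV
#>   ANN: A = 0.4176 uV, phase = 0.09375 cy, SOE = 0.65 cy
```

Despite the noise, the fit recovers the CM amplitude within 2%, the ANN
amplitude within 3%, the trough cutoff (−0.845 vs. the true −0.85 µV), and
the ANN phase to the grid's resolution (1/32 cycle). Summary metrics read:

```r
as.data.frame(apply_small_ratio_cutoff(decomposition_metrics(fit)))
#>   cm_magnitude ann_magnitude ann_cm_ratio ann_cm_index ann_re_cm_db
#> 1        0.976         0.254        0.261       -0.587        -11.7
#>            basis cutoff_applied
#> 1 first_harmonic          FALSE
```

Here the magnitudes are the first-harmonic amplitudes of the separated
component waveforms; the ANN is about a quarter of the CM (index −0.59,
−11.7 dB), well above the 5% no-response cutoff. `tidy(fit)`, `glance(fit)`
and `autoplot(fit)` give the broom/ggplot2 views; `extract_average_cycle()`
and `read_recording()` produce average cycles from recorded waveforms;
`sweep_preset()` and `run_parameter_sweep()` reproduce the
parameter-recovery validation sweeps.

A thin command-line front end with `fit`, `simulate`, `sweep` and `metrics`
subcommands is installed at `inst/cli/ecochg.R`:

```sh
Rscript inst/cli/ecochg.R fit --input recording.csv --out report.json
```

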
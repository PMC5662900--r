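#' One-cycle time grid for the ongoing-response model
#'
#' The CM/ANN model is evaluated on exactly one period of the stimulus tone,
#' sampled at the recording rate. The number of samples is
#' `round(sampling_rate / stimulus_frequency)`, matching the length of an
#' average cycle folded from the same recording.
#'
#' @param stimulus_frequency Tone frequency in Hz.
#' @param sampling_rate Recording sampling rate in Hz.
#' @return A tibble of class `eco_grid` with column `time` (seconds, starting
#'   at 0, spaced `1/sampling_rate`) and attributes `stimulus_frequency`,
#'   `sampling_rate`, `n_samples`.
#' @examples
#' time_grid(500, 16000) # 32 samples covering one 2-ms cycle
#' @export
time_grid <- function(stimulus_frequency, sampling_rate) {
  if (!is.numeric(stimulus_frequency) || stimulus_frequency <= 0) {
    abort_config("`stimulus_frequency` must be a positive number (Hz).")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort_config("`sampling_rate` must be a positive number (Hz).")
  }
  n <- round(sampling_rate / stimulus_frequency)
  if (n < 8) {
    abort_config(paste0(
      "Grid too coarse: round(sampling_rate / stimulus_frequency) = ", n,
      " samples per cycle; at least 8 are required."
    ))
  }
  out <- tibble(time = (seq_len(n) - 1) / sampling_rate)
  structure(out,
    stimulus_frequency = stimulus_frequency,
    sampling_rate = sampling_rate,
    n_samples = n,
    class = c("eco_grid", class(out))
  )
}

grid_info <- function(grid) {
  if (!inherits(grid, "eco_grid")) {
    abort_config("`grid` must be created with time_grid().")
  }
  list(
    f = attr(grid, "stimulus_frequency"),
    fs = attr(grid, "sampling_rate"),
    n = attr(grid, "n_samples"),
    time = grid$time
  )
}

#' Cochlear microphonic (CM) parameters
#'
#' The CM is a sinusoid at the stimulus frequency whose peak and trough can
#' saturate independently: the sinusoid is clipped at `upper_cutoff` and
#' `lower_cutoff` (uV). Cutoffs at or beyond +/- `a_cm` leave the sinusoid
#' untouched (no saturation).
#'
#' @param a_cm CM amplitude in uV (>= 0).
#' @param phi_cm CM starting phase in cycles.
#' @param upper_cutoff Peak saturation level in uV (>= 0).
#' @param lower_cutoff Trough saturation level in uV (<= 0).
#' @return A list of class `cm_params`.
#' @export
cm_params <- function(a_cm, phi_cm = 0, upper_cutoff = Inf, lower_cutoff = -Inf) {
  if (a_cm < 0) abort_config("`a_cm` must be nonnegative.")
  if (!(lower_cutoff < upper_cutoff)) {
    abort_config("`lower_cutoff` must be strictly below `upper_cutoff`.")
  }
  if (lower_cutoff > 0 || upper_cutoff < 0) {
    abort_config("Cutoffs must bracket zero: lower_cutoff <= 0 <= upper_cutoff.")
  }
  structure(
    list(a_cm = a_cm, phi_cm = phi_cm,
         upper_cutoff = upper_cutoff, lower_cutoff = lower_cutoff),
    class = "cm_params"
  )
}

#' Auditory nerve neurophonic (ANN) parameters
#'
#' The ANN is the circular convolution of a population cycle histogram (a
#' lognormal-shaped, half-wave-rectified firing-probability density whose
#' width is set by the spread of excitation, SOE) with a unit potential (one
#' sine cycle at `up_frequency`), scaled by `a_ann` and circularly shifted by
#' `phi_ann`.
#'
#' @param a_ann ANN amplitude in uV (>= 0).
#' @param phi_ann ANN phase in cycles; applied as an integer-sample circular
#'   shift, so effective resolution is one grid sample.
#' @param soe Spread of excitation, in stimulus cycles; must lie in
#'   \[0.35, 0.65\].
#' @param up_frequency Unit-potential frequency in Hz (default 1100).
#' @return A list of class `ann_params`.
#' @export
ann_params <- function(a_ann, phi_ann = 0, soe = 0.5, up_frequency = 1100) {
  if (a_ann < 0) abort_config("`a_ann` must be nonnegative.")
  if (soe < 0.35 || soe > 0.65) {
    abort_config("`soe` must lie in [0.35, 0.65] stimulus cycles.")
  }
  if (up_frequency <= 0) abort_config("`up_frequency` must be positive (Hz).")
  structure(
    list(a_ann = a_ann, phi_ann = phi_ann, soe = soe,
         up_frequency = up_frequency),
    class = "ann_params"
  )
}

#' Combined model parameters
#'
#' @param cm A [cm_params()] record.
#' @param ann An [ann_params()] record.
#' @return A list of class `model_params` with elements `cm` and `ann`.
#' @export
model_params <- function(cm, ann) {
  if (!inherits(cm, "cm_params")) abort_config("`cm` must be a cm_params record.")
  if (!inherits(ann, "ann_params")) abort_config("`ann` must be an ann_params record.")
  structure(list(cm = cm, ann = ann), class = "model_params")
}

# ---- internal vector kernels (fast path used by the fitter) -----------------

clip_series <- function(x, lower, upper) pmin(pmax(x, lower), upper)

cm_eval <- function(time, f, a_cm, phi_cm, upper_cutoff, lower_cutoff) {
  clip_series(a_cm * sin(2 * pi * (f * time - phi_cm)), lower_cutoff, upper_cutoff)
}

# circshift semantics: positive k delays the series (moves samples to higher
# indices, wrapping at the end).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((round(k) %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# circular convolution of equal-length series via the DFT
circ_conv <- function(a, b) {
  Re(fft(fft(a) * fft(b), inverse = TRUE)) / length(a)
}

# circular delay by a possibly fractional number of samples, via an FFT
# phase ramp; the Nyquist bin is weighted cos(pi * s) so the output is real
frac_circ_shift <- function(x, s) {
  n <- length(x)
  k <- 0:(n - 1)
  kk <- ifelse(k <= n / 2, k, k - n)
  ramp <- exp(-2i * pi * kk * s / n)
  if (n %% 2 == 0) ramp[n / 2 + 1] <- cos(pi * s)
  Re(fft(fft(x) * ramp, inverse = TRUE)) / n
}

up_kernel <- function(up_frequency, sampling_rate) {
  if (sampling_rate < 4 * up_frequency) {
    abort_config(paste0(
      "Sampling rate ", sampling_rate, " Hz cannot resolve a ",
      up_frequency, " Hz unit potential (need >= 4x)."
    ))
  }
  n_up <- round(sampling_rate / up_frequency)
  # one full cycle, negative-going half first (N1-like), unit peak magnitude
  k <- -sin(2 * pi * (seq_len(n_up) - 1) / n_up)
  k / max(abs(k))
}

# Lognormal cycle histogram over one stimulus cycle, unit peak. Time enters
# in units of unit-potential periods; the density is zero for the
# hyperpolarizing phase by construction (it vanishes as t -> 0 and decays in
# the tail), mirroring half-wave-rectified phase locking.
cycle_histogram_eval <- function(time, soe, up_frequency) {
  x <- time * up_frequency
  x[x <= 0] <- 1e-6
  h <- dlnorm(x, meanlog = 0, sdlog = soe)
  h / max(h)
}

# CH (*) UP, normalized to unit peak magnitude so a_ann is in uV
ann_kernel <- function(gi, soe, up_frequency) {
  ch <- cycle_histogram_eval(gi$time, soe, up_frequency)
  up <- up_kernel(up_frequency, gi$fs)
  if (length(up) > gi$n) {
    abort_config("Unit potential is longer than one stimulus cycle.")
  }
  k <- circ_conv(ch, c(up, rep(0, gi$n - length(up))))
  # anchor the kernel's intrinsic phase: advance it (fractionally, so the
  # kernel stays smooth in soe) until its fundamental aligns with an
  # unshifted sine, so phi_ann = phi_cm means the CM and ANN are in phase
  # (constructive interference). A labeling convention absorbed by the
  # phase parameter.
  ph <- ((-Arg(fft(k)[2]) - pi / 2) / (2 * pi)) %% 1
  k <- frac_circ_shift(k, -ph * gi$n)
  k / max(abs(k))
}

ann_eval <- function(gi, a_ann, phi_ann, soe, up_frequency) {
  if (a_ann == 0) return(rep(0, gi$n))
  a_ann * circ_shift(ann_kernel(gi, soe, up_frequency), round(phi_ann * gi$n))
}

model_eval <- function(gi, p) {
  cm_eval(gi$time, gi$f, p$cm$a_cm, p$cm$phi_cm,
          p$cm$upper_cutoff, p$cm$lower_cutoff) +
    ann_eval(gi, p$ann$a_ann, p$ann$phi_ann, p$ann$soe, p$ann$up_frequency)
}

# ---- exported forward-model surface -----------------------------------------

#' Evaluate the saturating-sinusoid CM over one cycle
#'
#' Computes `a_cm * sin(2 * pi * (f * t - phi_cm))` and clips it pointwise to
#' `[lower_cutoff, upper_cutoff]`.
#'
#' @param grid A [time_grid()].
#' @param cm A [cm_params()] record.
#' @return The grid tibble with an added `amplitude` column (uV).
#' @export
cm_waveform <- function(grid, cm) {
  gi <- grid_info(grid)
  if (!inherits(cm, "cm_params")) abort_config("`cm` must be a cm_params record.")
  dplyr::mutate(grid, amplitude = cm_eval(
    gi$time, gi$f, cm$a_cm, cm$phi_cm, cm$upper_cutoff, cm$lower_cutoff
  ))
}

#' Unit potential: a single sine cycle
#'
#' The waveform contributed by one nerve fiber's action potential at the
#' recording site, modeled as exactly one cycle of a sinusoid at
#' `up_frequency` with unit peak magnitude, negative-going half first.
#'
#' @param up_frequency Unit-potential frequency in Hz (default 1100).
#' @param sampling_rate Sampling rate in Hz; must be at least 4x
#'   `up_frequency`.
#' @return A tibble with columns `time` (s) and `amplitude` (unit peak),
#'   `round(sampling_rate / up_frequency)` rows.
#' @export
unit_potential <- function(up_frequency = 1100, sampling_rate) {
  k <- up_kernel(up_frequency, sampling_rate)
  tibble(time = (seq_along(k) - 1) / sampling_rate, amplitude = k)
}

#' Population cycle histogram over one stimulus cycle
#'
#' Lognormal-shaped firing-probability density (unit peak) whose width is the
#' spread of excitation; the density is effectively zero over the
#' hyperpolarizing part of the cycle, reflecting half-wave-rectified phase
#' locking.
#'
#' @inheritParams cm_waveform
#' @param ann An [ann_params()] record (only `soe` and `up_frequency` are
#'   used).
#' @return The grid tibble with an added `density` column in \[0, 1\].
#' @export
cycle_histogram <- function(grid, ann) {
  gi <- grid_info(grid)
  if (!inherits(ann, "ann_params")) abort_config("`ann` must be an ann_params record.")
  dplyr::mutate(grid, density = cycle_histogram_eval(gi$time, ann$soe, ann$up_frequency))
}

#' Evaluate the ANN component over one cycle
#'
#' Circularly convolves the cycle histogram with the unit potential,
#' normalizes the convolved kernel to unit peak magnitude (so `a_ann` is in
#' uV), scales by `a_ann`, and applies `phi_ann` as an integer-sample
#' circular shift.
#'
#' @inheritParams cycle_histogram
#' @return The grid tibble with an added `amplitude` column (uV).
#' @export
ann_waveform <- function(grid, ann) {
  gi <- grid_info(grid)
  if (!inherits(ann, "ann_params")) abort_config("`ann` must be an ann_params record.")
  dplyr::mutate(grid, amplitude = ann_eval(gi, ann$a_ann, ann$phi_ann, ann$soe, ann$up_frequency))
}

#' Evaluate the full ongoing-response model over one cycle
#'
#' The modeled ongoing ECochG is the pointwise sum of the CM and ANN
#' components.
#'
#' @inheritParams cm_waveform
#' @param params A [model_params()] record.
#' @return The grid tibble with an added `amplitude` column (uV).
#' @export
ecochg_model <- function(grid, params) {
  gi <- grid_info(grid)
  if (!inherits(params, "model_params")) {
    abort_config("`params` must be a model_params record.")
  }
  dplyr::mutate(grid, amplitude = model_eval(gi, params))
}
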
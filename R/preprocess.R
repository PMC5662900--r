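#' Construct a recorded-waveform object
#'
#' Wraps a sampled evoked-potential trace (uV) with the stimulus metadata
#' needed to fold it into an average cycle.
#'
#' @param samples Numeric vector of voltages in uV.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the stimulus
#'   frequency.
#' @param stimulus_frequency Tone frequency in Hz.
#' @param stimulus_polarity One of "condensation", "rarefaction", "unknown".
#' @param rise_time_ms,fall_time_ms Stimulus ramp durations in ms (used to
#'   locate the ongoing window).
#' @return A tibble of class `eco_waveform` with columns `time` (s) and
#'   `amplitude` (uV) and the metadata stored as attributes.
#' @export
eco_waveform <- function(samples, sampling_rate, stimulus_frequency,
                         stimulus_polarity = c("unknown", "condensation", "rarefaction"),
                         rise_time_ms = 0, fall_time_ms = 0) {
  stimulus_polarity <- match.arg(stimulus_polarity)
  if (!all(is.finite(samples))) abort_data("Waveform samples must be finite.")
  if (sampling_rate <= 2 * stimulus_frequency) {
    abort_config("`sampling_rate` must exceed twice `stimulus_frequency`.")
  }
  out <- tibble(
    time = (seq_along(samples) - 1) / sampling_rate,
    amplitude = as.numeric(samples)
  )
  structure(out,
    sampling_rate = sampling_rate,
    stimulus_frequency = stimulus_frequency,
    stimulus_polarity = stimulus_polarity,
    rise_time_ms = rise_time_ms,
    fall_time_ms = fall_time_ms,
    class = c("eco_waveform", class(out))
  )
}

waveform_info <- function(w) {
  if (!inherits(w, "eco_waveform")) {
    abort_config("Input must be an eco_waveform (see eco_waveform() or read_recording()).")
  }
  list(
    fs = attr(w, "sampling_rate"),
    f = attr(w, "stimulus_frequency"),
    rise_ms = attr(w, "rise_time_ms"),
    fall_ms = attr(w, "fall_time_ms"),
    x = w$amplitude
  )
}

#' Fold the ongoing response into an average cycle
#'
#' Drops an onset window (the stimulus rise ramp plus `skip_onset_cycles`
#' whole cycles, clearing the compound action potential) and an offset window
#' (the fall ramp plus `skip_offset_cycles` cycles), then averages the
#' remaining whole stimulus cycles pointwise. Only whole cycles are folded; a
#' trailing partial cycle is discarded so no phase smearing occurs.
#'
#' @param w An [eco_waveform()].
#' @param skip_onset_cycles Whole cycles discarded after the rise ramp
#'   (default 2).
#' @param skip_offset_cycles Whole cycles discarded before the fall ramp
#'   (default 1).
#' @return A tibble of class `eco_cycle` with columns `time`, `amplitude`
#'   (one stimulus period) and attributes `sampling_rate`,
#'   `stimulus_frequency`, `n_cycles_folded`.
#' @export
extract_average_cycle <- function(w, skip_onset_cycles = 2, skip_offset_cycles = 1) {
  wi <- waveform_info(w)
  period <- round(wi$fs / wi$f)
  n <- length(wi$x)
  onset <- round(wi$rise_ms / 1000 * wi$fs) + skip_onset_cycles * period
  offset <- round(wi$fall_ms / 1000 * wi$fs) + skip_offset_cycles * period
  k <- (n - onset - offset) %/% period
  if (k < 1) {
    abort_data(paste0(
      "Too few cycles: ", n, " samples leave ", max(n - onset - offset, 0),
      " for folding but one cycle needs ", period, "."
    ))
  }
  seg <- wi$x[(onset + 1):(onset + k * period)]
  avg <- rowMeans(matrix(seg, nrow = period, ncol = k))
  new_eco_cycle(avg, wi$fs, wi$f, n_cycles_folded = k)
}

new_eco_cycle <- function(samples, sampling_rate, stimulus_frequency,
                          n_cycles_folded = 1L) {
  out <- tibble(
    time = (seq_along(samples) - 1) / sampling_rate,
    amplitude = as.numeric(samples)
  )
  structure(out,
    sampling_rate = sampling_rate,
    stimulus_frequency = stimulus_frequency,
    n_cycles_folded = n_cycles_folded,
    class = c("eco_cycle", class(out))
  )
}

cycle_info <- function(cycle) {
  if (!inherits(cycle, "eco_cycle")) {
    abort_config("Input must be an eco_cycle (see extract_average_cycle()).")
  }
  list(
    fs = attr(cycle, "sampling_rate"),
    f = attr(cycle, "stimulus_frequency"),
    n = nrow(cycle),
    x = cycle$amplitude,
    time = cycle$time
  )
}

cycle_grid <- function(cycle) {
  ci <- cycle_info(cycle)
  time_grid(ci$f, ci$fs)
}

#' Combine condensation and rarefaction responses
#'
#' Alternating-polarity averaging: the half-difference emphasizes components
#' that invert with stimulus polarity (CM-like), the half-sum emphasizes
#' polarity-invariant components. The default passes the condensation trace
#' through untouched, matching single-polarity analysis.
#'
#' @param cond,rare [eco_waveform()] objects with matching length, rate and
#'   stimulus frequency.
#' @param mode "single" (passthrough of `cond`), "difference_half"
#'   (`(cond - rare)/2`) or "sum_half" (`(cond + rare)/2`).
#' @return An `eco_waveform`.
#' @export
combine_polarities <- function(cond, rare,
                               mode = c("single", "difference_half", "sum_half")) {
  mode <- match.arg(mode)
  ci <- waveform_info(cond)
  ri <- waveform_info(rare)
  if (length(ci$x) != length(ri$x) || ci$fs != ri$fs || ci$f != ri$f) {
    abort_data("Polarity pair must match in length, sampling rate and stimulus frequency.")
  }
  x <- switch(mode,
    single = ci$x,
    difference_half = (ci$x - ri$x) / 2,
    sum_half = (ci$x + ri$x) / 2
  )
  eco_waveform(x, ci$fs, ci$f,
    stimulus_polarity = if (mode == "single") attr(cond, "stimulus_polarity") else "unknown",
    rise_time_ms = ci$rise_ms, fall_time_ms = ci$fall_ms
  )
}
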
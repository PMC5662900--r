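#' Magnitudes of the separated CM and ANN components
#'
#' Either the raw fitted amplitude parameters, or (default) the
#' first-harmonic magnitudes of the separated component waveforms — the
#' spectral reading used when comparing components on a common uV scale. For
#' an unclipped CM the two bases agree; saturation moves fundamental energy
#' into higher harmonics, so the first-harmonic CM magnitude then falls
#' below the amplitude parameter.
#'
#' @param fit An `ecochg_fit`.
#' @param basis "first_harmonic" (default) or "parameter".
#' @return Named numeric vector with elements `cm_magnitude` and
#'   `ann_magnitude` (uV).
#' @export
component_magnitudes <- function(fit, basis = c("first_harmonic", "parameter")) {
  basis <- match.arg(basis)
  if (!inherits(fit, "ecochg_fit")) abort_config("`fit` must be an ecochg_fit.")
  if (basis == "parameter") {
    c(cm_magnitude = fit$params$cm$a_cm, ann_magnitude = fit$params$ann$a_ann)
  } else {
    c(
      cm_magnitude = first_harmonic(fit$cm_component)$magnitude,
      ann_magnitude = first_harmonic(fit$ann_component)$magnitude
    )
  }
}

#' ANN/CM index
#'
#' `(ANN - CM) / (ANN + CM)`: -1 is all CM, 0 equal amounts, +1 all ANN.
#' Scale-invariant and antisymmetric in its arguments.
#'
#' @param ann_magnitude,cm_magnitude Component magnitudes in uV (nonnegative,
#'   not both zero).
#' @return Index in \[-1, 1\].
#' @export
ann_cm_index <- function(ann_magnitude, cm_magnitude) {
  if (ann_magnitude < 0 || cm_magnitude < 0) {
    abort_config("Magnitudes must be nonnegative.")
  }
  if (ann_magnitude + cm_magnitude == 0) {
    abort_data("Index undefined: both magnitudes are zero.")
  }
  (ann_magnitude - cm_magnitude) / (ann_magnitude + cm_magnitude)
}

#' Summary metrics for a fitted decomposition
#'
#' @param fit An `ecochg_fit`.
#' @inheritParams component_magnitudes
#' @return A one-row tibble of class `eco_metrics`: `cm_magnitude`,
#'   `ann_magnitude` (uV), `ann_cm_ratio`, `ann_cm_index`, `ann_re_cm_db`
#'   (20 log10 of the ratio), `basis`, `cutoff_applied` (FALSE until
#'   [apply_small_ratio_cutoff()] is used).
#' @export
decomposition_metrics <- function(fit, basis = c("first_harmonic", "parameter")) {
  basis <- match.arg(basis)
  mags <- component_magnitudes(fit, basis)
  cm <- unname(mags["cm_magnitude"])
  ann <- unname(mags["ann_magnitude"])
  ratio <- if (cm > 0) ann / cm else Inf
  out <- tibble(
    cm_magnitude = cm,
    ann_magnitude = ann,
    ann_cm_ratio = ratio,
    ann_cm_index = ann_cm_index(ann, cm),
    ann_re_cm_db = if (ann > 0 && cm > 0) amplitude_to_db(ann, cm) else -Inf,
    basis = basis,
    cutoff_applied = FALSE
  )
  structure(out, class = c("eco_metrics", class(out)))
}

#' Zero out implausibly small ANN estimates
#'
#' The model rarely reports an ANN much below 5% of the CM even when no
#' neural response is present, so fitted ANN magnitudes with
#' `ann_cm_ratio < threshold` are treated as no response: `ann_magnitude` is
#' set to 0 and `cutoff_applied` flagged. The ratio, index and dB fields keep
#' their pre-cutoff values for reporting — in particular the cutoff is never
#' applied to the ANN/CM index.
#'
#' @param m An `eco_metrics` row from [decomposition_metrics()].
#' @param threshold Ratio below which the ANN is zeroed (strict `<`,
#'   default 0.05).
#' @return The metrics row, possibly with `ann_magnitude = 0` and
#'   `cutoff_applied = TRUE`.
#' @export
apply_small_ratio_cutoff <- function(m, threshold = 0.05) {
  if (!inherits(m, "eco_metrics")) abort_config("`m` must come from decomposition_metrics().")
  if (m$ann_cm_ratio < threshold) {
    m$ann_magnitude <- 0
    m$cutoff_applied <- TRUE
  }
  m
}

#' Amplitude ratio in decibels
#'
#' @param value,reference Positive amplitudes in the same units (uV).
#' @return `20 * log10(value / reference)` in dB.
#' @export
amplitude_to_db <- function(value, reference = 1) {
  if (any(value <= 0) || any(reference <= 0)) {
    abort_data("dB conversion requires positive amplitudes.")
  }
  20 * log10(value / reference)
}
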
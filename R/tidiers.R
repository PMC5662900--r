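#' Tidy the fitted parameters of a decomposition
#'
#' @param x An `ecochg_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter: `term`, `estimate`,
#'   `unit`, and `wrapped` (phases wrapped to \[0, 1), `NA` otherwise).
#' @export
tidy.ecochg_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("a_cm", "phi_cm", "upper_cutoff", "lower_cutoff",
             "a_ann", "phi_ann", "soe"),
    estimate = c(p$cm$a_cm, p$cm$phi_cm, p$cm$upper_cutoff, p$cm$lower_cutoff,
                 p$ann$a_ann, p$ann$phi_ann, p$ann$soe),
    unit = c("uV", "cycles", "uV", "uV", "uV", "cycles", "cycles"),
    wrapped = c(NA, unname(x$phases_wrapped["phi_cm"]), NA, NA,
                NA, unname(x$phases_wrapped["phi_ann"]), NA)
  )
}

#' One-row fit summary
#'
#' @param x An `ecochg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r`, `r_squared`, `sse`, `ann_cm_ratio`
#'   (first-harmonic basis), `converged`, `n_evaluations`, `n_samples`,
#'   `stimulus_frequency`.
#' @export
glance.ecochg_fit <- function(x, ...) {
  mags <- component_magnitudes(x, "first_harmonic")
  tibble(
    r = x$r,
    r_squared = x$r_squared,
    sse = x$sse,
    ann_cm_ratio = unname(mags["ann_magnitude"] / mags["cm_magnitude"]),
    converged = x$converged,
    n_evaluations = x$n_evaluations,
    n_samples = length(x$observed),
    stimulus_frequency = x$stimulus_frequency
  )
}

#' @export
print.ecochg_fit <- function(x, ...) {
  cat("ECochG decomposition fit\n")
  cat(sprintf("  %d samples at %g Hz (stimulus %g Hz)\n",
              length(x$observed), x$sampling_rate, x$stimulus_frequency))
  cat(sprintf("  r = %.4f, r^2 = %.4f, SSE = %.3g uV^2%s\n",
              x$r, x$r_squared, x$sse,
              if (x$converged) "" else " [not converged]"))
  p <- x$params
  cat(sprintf("  CM:  A = %.4g uV, phase = %.4g cy, cutoffs [%.4g, %.4g] uV\n",
              p$cm$a_cm, p$cm$phi_cm, p$cm$lower_cutoff, p$cm$upper_cutoff))
  cat(sprintf("  ANN: A = %.4g uV, phase = %.4g cy, SOE = %.3g cy\n",
              p$ann$a_ann, p$ann$phi_ann, p$ann$soe))
  invisible(x)
}

fit_series <- function(x, n_cycles = 2) {
  n <- length(x$observed)
  idx <- rep(seq_len(n), n_cycles)
  time <- (seq_len(n * n_cycles) - 1) / x$sampling_rate
  tibble(
    time = rep(time, 4),
    amplitude = c(x$observed[idx], x$modeled[idx],
                  x$cm_component[idx], x$ann_component[idx]),
    series = rep(c("observed", "modeled", "CM", "ANN"), each = n * n_cycles)
  )
}

#' Plot a fitted decomposition
#'
#' Shows two concatenated cycles of the observed average cycle, the modeled
#' fit, and the separated CM and ANN components.
#'
#' @param object An `ecochg_fit`.
#' @param n_cycles Cycles to display (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecochg_fit <- function(object, n_cycles = 2, ...) {
  dat <- fit_series(object, n_cycles)
  dat$series <- factor(dat$series, levels = c("observed", "modeled", "CM", "ANN"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time * 1000, y = .data$amplitude,
                                    color = .data$series, linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c("solid", "dashed", "solid", "solid")) +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)",
                  color = NULL, linetype = NULL,
                  title = sprintf("ECochG decomposition (r² = %.3f)", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a harmonic spectrum
#'
#' @param object An `eco_spectrum`.
#' @param ... Unused.
#' @return A ggplot of harmonic magnitudes with the noise floor and
#'   significance marked.
#' @export
autoplot.eco_spectrum <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frequency, y = .data$magnitude,
                                    fill = .data$significant)) +
    ggplot2::geom_col(width = diff(range(dat$frequency)) / (3 * nrow(dat) + 1e-9) + 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$noise_mean,
                                        ymax = .data$noise_mean + 3 * .data$noise_sd),
                           width = 0, linewidth = 0.3, color = "grey30") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude (µV)",
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery sweep
#'
#' True (line) versus recovered (points) values of the swept parameter.
#'
#' @param object An `eco_sweep` from [run_parameter_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_sweep <- function(object, ...) {
  par <- attr(object, "swept_parameter")
  dat <- as_tibble(object)
  dat$true <- dat[[paste0("true_", par)]]
  dat$fitted <- dat[[paste0("fitted_", par)]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sweep_value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true), color = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fitted), color = "red", size = 0.8) +
    ggplot2::labs(x = paste("input", par), y = paste("recovered", par),
                  title = sprintf("Parameter recovery: %s", par)) +
    ggplot2::theme_minimal()
}

#' Plot a waveform or average cycle
#'
#' @param object An `eco_waveform` or `eco_cycle`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_waveform <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time * 1000, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eco_waveform
#' @export
autoplot.eco_cycle <- autoplot.eco_waveform
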
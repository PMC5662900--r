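#' CM parameters from saturation percentages
#'
#' Convenience constructor expressing the saturation cutoffs as a percentage
#' of the CM amplitude: a peak saturation of 15% clips the sinusoid at
#' `0.85 * a_cm`. Zero percent places the cutoff safely outside the sinusoid
#' (no clipping).
#'
#' @param a_cm CM amplitude in uV.
#' @param phi_cm CM phase in cycles.
#' @param peak_saturation_pct,trough_saturation_pct Saturation depth as a
#'   percent of `a_cm` (0 = none).
#' @return A [cm_params()] record.
#' @export
saturating_cm <- function(a_cm, phi_cm = 0,
                          peak_saturation_pct = 0, trough_saturation_pct = 0) {
  no_clip <- 5 * a_cm
  cm_params(
    a_cm = a_cm, phi_cm = phi_cm,
    upper_cutoff = if (peak_saturation_pct > 0) (1 - peak_saturation_pct / 100) * a_cm else no_clip,
    lower_cutoff = if (trough_saturation_pct > 0) -(1 - trough_saturation_pct / 100) * a_cm else -no_clip
  )
}

#' Recovered saturation depths from a fit
#'
#' Converts the fitted cutoffs back to percent of the fitted CM amplitude; a
#' cutoff at or beyond the sinusoid's extreme reads as 0% (no saturation).
#'
#' @param fit An `ecochg_fit`.
#' @return Named vector `c(peak_saturation_pct, trough_saturation_pct)`.
#' @export
saturation_pct <- function(fit) {
  if (!inherits(fit, "ecochg_fit")) abort_config("`fit` must be an ecochg_fit.")
  a <- fit$params$cm$a_cm
  c(
    peak_saturation_pct = max(0, (1 - fit$params$cm$upper_cutoff / a) * 100),
    trough_saturation_pct = max(0, (1 + fit$params$cm$lower_cutoff / a) * 100)
  )
}

#' Generate a simulated average cycle
#'
#' Evaluates the forward model on the grid and adds i.i.d. Gaussian noise of
#' standard deviation `noise_sd` (uV). With `noise_sd = 0` the output equals
#' the model exactly. Reproducible given `seed`.
#'
#' @param params A [model_params()] record.
#' @param grid A [time_grid()].
#' @param noise_sd Additive noise standard deviation in uV (default 0).
#' @param seed Optional integer seed for the noise.
#' @return An `eco_cycle`.
#' @export
generate_simulated_cycle <- function(params, grid, noise_sd = 0, seed = NULL) {
  gi <- grid_info(grid)
  if (!inherits(params, "model_params")) {
    abort_config("`params` must be a model_params record.")
  }
  x <- model_eval(gi, params)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      rnorm(gi$n, sd = noise_sd)
    } else {
      withr::with_seed(seed, rnorm(gi$n, sd = noise_sd))
    }
    x <- x + noise
  }
  new_eco_cycle(x, gi$fs, gi$f, n_cycles_folded = 1L)
}

sweep_parameters <- c(
  "a_cm", "phi_cm", "upper_cutoff", "lower_cutoff",
  "a_ann", "phi_ann", "soe",
  "phase_difference", "peak_saturation_pct", "trough_saturation_pct"
)

apply_sweep_value <- function(base, name, v) {
  cm <- base$cm
  ann <- base$ann
  switch(name,
    a_cm = cm$a_cm <- v,
    phi_cm = cm$phi_cm <- v,
    upper_cutoff = cm$upper_cutoff <- v,
    lower_cutoff = cm$lower_cutoff <- v,
    a_ann = ann$a_ann <- v,
    phi_ann = ann$phi_ann <- v,
    soe = ann$soe <- v,
    phase_difference = ann$phi_ann <- cm$phi_cm + v,
    peak_saturation_pct = cm$upper_cutoff <-
      if (v > 0) (1 - v / 100) * cm$a_cm else 5 * cm$a_cm,
    trough_saturation_pct = cm$lower_cutoff <-
      if (v > 0) -(1 - v / 100) * cm$a_cm else -5 * cm$a_cm
  )
  model_params(do.call(cm_params, unclass(cm)), do.call(ann_params, unclass(ann)))
}

#' Define a parameter sweep of simulated signals
#'
#' @param swept_parameter One of `a_cm`, `phi_cm`, `upper_cutoff`,
#'   `lower_cutoff`, `a_ann`, `phi_ann`, `soe`, `phase_difference`,
#'   `peak_saturation_pct`, `trough_saturation_pct`.
#' @param sweep_values Numeric values the parameter takes, one signal each.
#' @param base A [model_params()] record holding every other parameter.
#' @param grid A [time_grid()] (default 500 Hz at 16 kHz: 32 samples).
#' @param noise_sd Additive noise sd in uV (default 0, as in the validation
#'   sweeps).
#' @param seed Optional integer; signal i uses `seed + i` for its noise.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(swept_parameter, sweep_values, base,
                            grid = time_grid(500, 16000),
                            noise_sd = 0, seed = NULL) {
  swept_parameter <- match.arg(swept_parameter, sweep_parameters)
  if (length(sweep_values) < 1) abort_config("`sweep_values` must be non-empty.")
  if (!inherits(base, "model_params")) abort_config("`base` must be a model_params record.")
  structure(
    list(
      swept_parameter = swept_parameter,
      sweep_values = as.numeric(sweep_values),
      base = base, grid = grid, noise_sd = noise_sd, seed = seed
    ),
    class = "simulation_spec"
  )
}

#' Published validation sweeps
#'
#' The five parametric sweeps used to validate parameter recovery, each 100
#' noise-free signals on a 500 Hz / 16 kHz grid:
#' \describe{
#'   \item{ann_amplitude}{ANN amplitude 0.01 to 2 uV; CM 1 uV, no
#'     saturation, SOE 0.65, zero phase difference.}
#'   \item{phase_difference}{CM-ANN phase difference -0.5 to 0.5 cycles; CM
#'     1 uV, ANN 0.3 uV, SOE 0.65, no saturation.}
#'   \item{trough_saturation}{Trough saturation 0 to 15% of the CM
#'     amplitude; no peak saturation, ANN 0.3 uV, SOE 0.65, zero phase
#'     difference.}
#'   \item{peak_saturation}{Peak saturation 0 to 10% of the 1 uV CM with
#'     trough saturation fixed at 15%; ANN 0.43 uV, SOE 0.65, zero phase
#'     difference.}
#'   \item{soe}{SOE 0.35 to 0.65 cycles; CM 1 uV, ANN 0.3 uV, no
#'     saturation, zero phase difference.}
#' }
#'
#' @param name Which sweep to build.
#' @param n_signals Number of equally spaced sweep values (default 100).
#' @param grid A [time_grid()].
#' @return A [simulation_spec()].
#' @export
sweep_preset <- function(name = c("ann_amplitude", "phase_difference",
                                  "trough_saturation", "peak_saturation", "soe"),
                         n_signals = 100, grid = time_grid(500, 16000)) {
  name <- match.arg(name)
  up <- 1100
  base_ann <- function(a) ann_params(a_ann = a, phi_ann = 0, soe = 0.65, up_frequency = up)
  switch(name,
    ann_amplitude = simulation_spec(
      "a_ann", seq(0.01, 2, length.out = n_signals),
      model_params(saturating_cm(1), base_ann(0.3)), grid
    ),
    phase_difference = simulation_spec(
      "phase_difference", seq(-0.5, 0.5, length.out = n_signals),
      model_params(saturating_cm(1), base_ann(0.3)), grid
    ),
    trough_saturation = simulation_spec(
      "trough_saturation_pct", seq(0, 15, length.out = n_signals),
      model_params(saturating_cm(1), base_ann(0.3)), grid
    ),
    peak_saturation = simulation_spec(
      "peak_saturation_pct", seq(0, 10, length.out = n_signals),
      model_params(saturating_cm(1, trough_saturation_pct = 15), base_ann(0.43)), grid
    ),
    soe = simulation_spec(
      "soe", seq(0.35, 0.65, length.out = n_signals),
      model_params(saturating_cm(1), base_ann(0.3)), grid
    )
  )
}

wrap_half <- function(x) ((x + 0.5) %% 1) - 0.5

#' Run a generate-and-refit parameter sweep
#'
#' For each sweep value, generates a simulated cycle, fits the decomposition,
#' and records true versus recovered parameters. Individual fit failures are
#' recorded per signal (`converged = FALSE`), never raised.
#'
#' @param spec A [simulation_spec()] (see also [sweep_preset()]).
#' @param opts A [fit_options()].
#' @return A tibble of class `eco_sweep`, one row per signal: the swept
#'   value, true and fitted values of all seven parameters, the true and
#'   fitted CM-ANN phase difference (wrapped to \[-0.5, 0.5)) and saturation
#'   percentages, `r_squared`, `sse`, `converged`. Summarize with
#'   [recovery_summary()].
#' @export
run_parameter_sweep <- function(spec, opts = fit_options()) {
  if (!inherits(spec, "simulation_spec")) {
    abort_config("`spec` must come from simulation_spec() or sweep_preset().")
  }
  rows <- purrr::imap_dfr(spec$sweep_values, function(v, i) {
    p <- apply_sweep_value(spec$base, spec$swept_parameter, v)
    seed_i <- if (is.null(spec$seed)) NULL else spec$seed + i
    cyc <- generate_simulated_cycle(p, spec$grid, spec$noise_sd, seed_i)
    fit <- tryCatch(fit_decomposition(cyc, opts), error = function(e) NULL)
    true_sat_peak <- max(0, (1 - p$cm$upper_cutoff / p$cm$a_cm) * 100)
    true_sat_trough <- max(0, (1 + p$cm$lower_cutoff / p$cm$a_cm) * 100)
    base_row <- tibble(
      signal = i, sweep_value = v,
      true_a_cm = p$cm$a_cm, true_phi_cm = p$cm$phi_cm,
      true_upper_cutoff = p$cm$upper_cutoff, true_lower_cutoff = p$cm$lower_cutoff,
      true_a_ann = p$ann$a_ann, true_phi_ann = p$ann$phi_ann, true_soe = p$ann$soe,
      true_phase_difference = wrap_half(p$ann$phi_ann - p$cm$phi_cm),
      true_peak_saturation_pct = true_sat_peak,
      true_trough_saturation_pct = true_sat_trough
    )
    if (is.null(fit)) {
      return(dplyr::mutate(base_row,
        fitted_a_cm = NA_real_, fitted_phi_cm = NA_real_,
        fitted_upper_cutoff = NA_real_, fitted_lower_cutoff = NA_real_,
        fitted_a_ann = NA_real_, fitted_phi_ann = NA_real_, fitted_soe = NA_real_,
        fitted_phase_difference = NA_real_,
        fitted_peak_saturation_pct = NA_real_, fitted_trough_saturation_pct = NA_real_,
        r_squared = NA_real_, sse = NA_real_, converged = FALSE
      ))
    }
    sat <- saturation_pct(fit)
    dplyr::mutate(base_row,
      fitted_a_cm = fit$params$cm$a_cm,
      fitted_phi_cm = fit$params$cm$phi_cm,
      fitted_upper_cutoff = fit$params$cm$upper_cutoff,
      fitted_lower_cutoff = fit$params$cm$lower_cutoff,
      fitted_a_ann = fit$params$ann$a_ann,
      fitted_phi_ann = fit$params$ann$phi_ann,
      fitted_soe = fit$params$ann$soe,
      fitted_phase_difference = wrap_half(fit$params$ann$phi_ann - fit$params$cm$phi_cm),
      fitted_peak_saturation_pct = unname(sat["peak_saturation_pct"]),
      fitted_trough_saturation_pct = unname(sat["trough_saturation_pct"]),
      r_squared = fit$r_squared, sse = fit$sse, converged = fit$converged
    )
  })
  structure(rows,
    swept_parameter = spec$swept_parameter,
    noise_sd = spec$noise_sd,
    class = c("eco_sweep", class(rows))
  )
}

#' Per-parameter recovery errors for a sweep
#'
#' @param report An `eco_sweep` from [run_parameter_sweep()].
#' @return A tibble, one row per parameter, with `bias` (mean fitted - true),
#'   `mae` (median absolute error) and `rmse`, over converged signals. Phase
#'   errors are computed on the wrapped phase difference.
#' @export
recovery_summary <- function(report) {
  if (!inherits(report, "eco_sweep")) abort_config("`report` must come from run_parameter_sweep().")
  pars <- c("a_cm", "a_ann", "soe", "phase_difference",
            "peak_saturation_pct", "trough_saturation_pct")
  ok <- report[report$converged %in% TRUE, ]
  purrr::map_dfr(pars, function(p) {
    err <- ok[[paste0("fitted_", p)]] - ok[[paste0("true_", p)]]
    if (p == "phase_difference") err <- wrap_half(err)
    tibble(
      parameter = p,
      n = length(err),
      bias = mean(err),
      mae = median(abs(err)),
      rmse = sqrt(mean(err^2))
    )
  })
}
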
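#' Read a recorded waveform from delimited text
#'
#' Supports two dialects: a single voltage column, or a time column followed
#' by a voltage column. Header lines starting with `#` carry metadata as
#' `key: value` pairs (`sampling_rate`, `stimulus_frequency`, `units`,
#' `stimulus_polarity`, `rise_time_ms`, `fall_time_ms`). Arguments override
#' header values. Voltages are coerced to uV (`units` may be `nV`, `uV`,
#' `mV` or `V`). A time column must be uniformly spaced; its spacing must
#' agree with the resolved sampling rate.
#'
#' @param path Path to a CSV/TSV/whitespace-delimited file.
#' @param sampling_rate,stimulus_frequency,units,stimulus_polarity,rise_time_ms,fall_time_ms
#'   Optional overrides for the header metadata.
#' @return An [eco_waveform()].
#' @export
read_recording <- function(path, sampling_rate = NULL, stimulus_frequency = NULL,
                           units = NULL, stimulus_polarity = NULL,
                           rise_time_ms = NULL, fall_time_ms = NULL) {
  if (!file.exists(path)) abort_data(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  header <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) abort_data("No data rows in file.")

  meta <- list()
  for (h in header) {
    kv <- sub("^\\s*#\\s*", "", h)
    m <- regmatches(kv, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+?)\\s*$", kv))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  pick <- function(arg, key, as_num = TRUE) {
    if (!is.null(arg)) return(arg)
    v <- meta[[key]]
    if (is.null(v)) return(NULL)
    if (as_num) as.numeric(v) else v
  }
  fs <- pick(sampling_rate, "sampling_rate")
  f0 <- pick(stimulus_frequency, "stimulus_frequency")
  unit <- pick(units, "units", as_num = FALSE)
  pol <- pick(stimulus_polarity, "stimulus_polarity", as_num = FALSE)
  rise <- pick(rise_time_ms, "rise_time_ms")
  fall <- pick(fall_time_ms, "fall_time_ms")

  sep <- if (grepl(",", body[1])) "," else ""
  dat <- utils::read.table(text = body, sep = sep, header = FALSE)
  dat <- dat[vapply(dat, is.numeric, logical(1))]
  if (ncol(dat) == 0) abort_data("No numeric columns found in file.")

  if (ncol(dat) >= 2) {
    tcol <- dat[[1]]
    x <- dat[[2]]
    dt <- diff(tcol)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      abort_data("Time column is not uniformly increasing.")
    }
    fs_time <- 1 / stats::median(dt)
    if (is.null(fs)) fs <- fs_time
    else if (abs(fs - fs_time) > 1e-3 * fs) {
      abort_config(paste0("sampling_rate ", fs, " Hz disagrees with the time column (",
                          signif(fs_time, 8), " Hz)."))
    }
  } else {
    x <- dat[[1]]
  }
  if (is.null(fs)) abort_config("Missing metadata: sampling_rate (header `# sampling_rate:` or argument).")
  if (is.null(f0)) abort_config("Missing metadata: stimulus_frequency (header `# stimulus_frequency:` or argument).")

  scale <- switch(tolower(unit %||% "uv"),
    "nv" = 1e-3, "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
    abort_config(paste0("Unknown units: ", unit))
  )
  eco_waveform(x * scale, fs, f0,
    stimulus_polarity = pol %||% "unknown",
    rise_time_ms = rise %||% 0, fall_time_ms = fall %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a decomposition report as JSON
#'
#' Serializes the fitted parameters (raw and wrapped phases), goodness of
#' fit, summary metrics, the per-harmonic spectral table, tool version, the
#' fit configuration and seed. Numeric fields are written at full precision
#' so a report round-trips exactly. Optionally writes the observed, modeled,
#' CM and ANN series as CSV.
#'
#' @param fit An `ecochg_fit`.
#' @param metrics Optional `eco_metrics` row.
#' @param spectra Optional `eco_spectrum` table.
#' @param path Output JSON path.
#' @param series_path Optional CSV path for the component series.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, metrics = NULL, spectra = NULL, path,
                         series_path = NULL) {
  if (!inherits(fit, "ecochg_fit")) abort_config("`fit` must be an ecochg_fit.")
  opts <- fit$options
  report <- list(
    tool = "ecochg",
    version = as.character(utils::packageVersion("ecochg")),
    seed = opts$seed,
    config = list(
      amplitude_bound_factor = opts$amplitude_bound_factor,
      phase_bounds = opts$phase_bounds,
      soe_bounds = opts$soe_bounds,
      cutoff_bound_fraction = opts$cutoff_bound_fraction,
      optimality_tolerance = opts$optimality_tolerance,
      up_frequency = opts$up_frequency,
      multistart_phases = opts$multistart_phases
    ),
    input = list(
      stimulus_frequency = fit$stimulus_frequency,
      sampling_rate = fit$sampling_rate,
      n_samples = length(fit$observed)
    ),
    parameters = list(
      a_cm = fit$params$cm$a_cm,
      phi_cm = fit$params$cm$phi_cm,
      upper_cutoff = fit$params$cm$upper_cutoff,
      lower_cutoff = fit$params$cm$lower_cutoff,
      a_ann = fit$params$ann$a_ann,
      phi_ann = fit$params$ann$phi_ann,
      soe = fit$params$ann$soe
    ),
    phases_wrapped = as.list(fit$phases_wrapped),
    fit = list(
      r = fit$r, r_squared = fit$r_squared, sse = fit$sse,
      converged = fit$converged, n_evaluations = fit$n_evaluations
    )
  )
  if (!is.null(metrics)) report$metrics <- as.list(as_tibble(metrics)[1, ])
  if (!is.null(spectra)) report$harmonics <- as_tibble(spectra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE, dataframe = "rows")
  if (!is.null(series_path)) {
    readr::write_csv(tibble(
      time = fit$time, observed = fit$observed, modeled = fit$modeled,
      cm = fit$cm_component, ann = fit$ann_component
    ), series_path)
  }
  invisible(path)
}

#' Read a decomposition report written by [write_report()]
#'
#' @param path JSON report path.
#' @return A nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
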
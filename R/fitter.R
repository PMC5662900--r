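#' Options controlling the decomposition fit
#'
#' Bounds follow the model's published constraints: amplitudes may vary
#' between 0 and `amplitude_bound_factor` times the maximum of the input
#' signal; phases between -2 and 2 cycles; SOE between 0.35 and 0.65 cycles;
#' the saturation cutoffs between `cutoff_bound_fraction` of the input
#' extremum and the amplitude bound (at the outer bound the clipping branch
#' never activates).
#'
#' @param amplitude_bound_factor Upper amplitude bound as a multiple of
#'   `max(input)` (default 5).
#' @param phase_bounds Length-2 phase bounds in cycles (default `c(-2, 2)`).
#' @param soe_bounds Length-2 SOE bounds in cycles (default `c(0.35, 0.65)`).
#' @param cutoff_bound_fraction Inner cutoff bound as a fraction of the input
#'   maximum/minimum (default 0.5).
#' @param optimality_tolerance First-order optimality tolerance passed to the
#'   least-squares solver (default 1e-6).
#' @param up_frequency Unit-potential frequency in Hz (default 1100).
#' @param multistart_phases Number of equally spaced ANN-phase starts
#'   (default 8); 1 gives a single-start fit.
#' @param seed Optional integer recorded with results for provenance.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(amplitude_bound_factor = 5,
                        phase_bounds = c(-2, 2),
                        soe_bounds = c(0.35, 0.65),
                        cutoff_bound_fraction = 0.5,
                        optimality_tolerance = 1e-6,
                        up_frequency = 1100,
                        multistart_phases = 8,
                        seed = NULL) {
  if (optimality_tolerance <= 0) abort_config("`optimality_tolerance` must be positive.")
  if (diff(phase_bounds) <= 0 || diff(soe_bounds) <= 0) {
    abort_config("Bound pairs must be increasing.")
  }
  if (cutoff_bound_fraction <= 0 || cutoff_bound_fraction >= amplitude_bound_factor) {
    abort_config("`cutoff_bound_fraction` must lie in (0, amplitude_bound_factor).")
  }
  if (multistart_phases < 1) abort_config("`multistart_phases` must be >= 1.")
  structure(
    list(
      amplitude_bound_factor = amplitude_bound_factor,
      phase_bounds = phase_bounds,
      soe_bounds = soe_bounds,
      cutoff_bound_fraction = cutoff_bound_fraction,
      optimality_tolerance = optimality_tolerance,
      up_frequency = up_frequency,
      multistart_phases = multistart_phases,
      seed = seed
    ),
    class = "fit_options"
  )
}

first_harmonic <- function(x) {
  n <- length(x)
  X <- fft(x)[2]
  list(
    magnitude = 2 * Mod(X) / n,
    # x ~ A sin(2*pi*(f t - phi)): bin-1 coefficient is (n A / 2) e^{-i(2*pi*phi + pi/2)}
    phase_cycles = ((-Arg(X) - pi / 2) / (2 * pi)) %% 1
  )
}

#' Deterministic starting parameters for the fit
#'
#' The CM amplitude and phase are seeded from the first harmonic of the
#' average cycle; the saturation cutoffs start at their no-clipping outer
#' bounds; the ANN starts at 20% of the CM amplitude, in phase with it, with
#' SOE at mid-range.
#'
#' @param cycle An `eco_cycle`.
#' @param opts A [fit_options()].
#' @return A [model_params()] record.
#' @export
initial_guess <- function(cycle, opts = fit_options()) {
  ci <- cycle_info(cycle)
  if (sum(ci$x^2) == 0) abort_data("Degenerate input: the cycle has zero energy.")
  h1 <- first_harmonic(ci$x)
  bf <- opts$amplitude_bound_factor
  model_params(
    cm = cm_params(
      a_cm = h1$magnitude, phi_cm = h1$phase_cycles,
      upper_cutoff = bf * max(ci$x), lower_cutoff = bf * min(ci$x)
    ),
    ann = ann_params(
      a_ann = 0.2 * h1$magnitude, phi_ann = h1$phase_cycles,
      soe = 0.5, up_frequency = opts$up_frequency
    )
  )
}

# Bounded least squares over the six smooth parameters
# (a_cm, phi_cm, upper, lower, a_ann, soe) at a fixed integer ANN shift.
# The ANN kernel depends only on soe, so it is rebuilt inside the residual.
fit_at_shift <- function(x, gi, shift, par0, lower, upper, opts, counter) {
  kern_cache <- new.env(parent = emptyenv())
  resid_fn <- function(p) {
    counter$n <- counter$n + 1L
    key <- format(p[6], digits = 17)
    k <- kern_cache[[key]]
    if (is.null(k)) {
      k <- ann_kernel(gi, p[6], opts$up_frequency)
      kern_cache[[key]] <- k
    }
    cm_eval(gi$time, gi$f, p[1], p[2], p[3], p[4]) +
      p[5] * circ_shift(k, shift) - x
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-12, ptol = 1e-12, gtol = opts$optimality_tolerance,
      maxiter = 300
    )
  )
  list(par = fit$par, sse = fit$deviance, info = fit$info, shift = shift)
}

#' Fit the CM + ANN decomposition to an average cycle
#'
#' Minimizes the sum of squared residuals between the modeled ongoing
#' response and the observed average cycle, subject to the bounds in
#' [fit_options()]. The six smooth parameters (CM amplitude and phase, the
#' two saturation cutoffs, ANN amplitude, SOE) are optimized by bounded
#' nonlinear least squares; the ANN phase, which acts as an integer-sample
#' circular shift, is profiled: every candidate shift is screened with quick
#' optimizations, the best `multistart_phases` shifts (plus the
#' initial-guess shift) are polished from a grid of amplitude/cutoff and SOE
#' starts, and the best solution is refined by a hill-climb over neighboring
#' shifts. Ties are broken by the first start.
#'
#' @param cycle An `eco_cycle` (see [extract_average_cycle()] or
#'   [generate_simulated_cycle()]).
#' @param opts A [fit_options()].
#' @return An object of class `ecochg_fit`: fitted [model_params()] (with
#'   phases reported both raw and wrapped to \[0, 1)), the modeled cycle and
#'   separated CM/ANN component series, `r` (maximum circular-lag
#'   cross-correlation), `r_squared`, `sse`, `converged`, `n_evaluations`,
#'   and per-start diagnostics. Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_decomposition <- function(cycle, opts = fit_options()) {
  ci <- cycle_info(cycle)
  x <- ci$x
  if (sum(x^2) == 0) abort_data("Degenerate input: the cycle has zero energy.")
  if (max(x) <= 0 || min(x) >= 0) {
    abort_data("Degenerate input: the average cycle must oscillate about zero.")
  }
  gi <- grid_info(cycle_grid(cycle))
  n <- gi$n
  guess <- initial_guess(cycle, opts)
  bf <- opts$amplitude_bound_factor
  cf <- opts$cutoff_bound_fraction
  lower <- c(0, opts$phase_bounds[1], cf * max(x), bf * min(x), 0, opts$soe_bounds[1])
  upper <- c(bf * max(x), opts$phase_bounds[2], bf * max(x), cf * min(x),
             bf * max(x), opts$soe_bounds[2])

  base_par <- c(guess$cm$a_cm, guess$cm$phi_cm, NA, NA, guess$ann$a_ann, guess$ann$soe)
  # four start regimes for (a_cm, upper, lower): cutoffs inactive (no
  # saturation), clipping at the observed extrema, marginally active at the
  # first-harmonic amplitude (keeps the cutoff gradient alive so mild
  # saturation can be found), and a deeply saturated regime where the
  # sinusoid amplitude starts above the observed maximum
  h1_amp <- guess$cm$a_cm
  regime_inits <- list(
    no_clip = c(h1_amp, bf * max(x), bf * min(x)),
    extrema = c(h1_amp, max(x), min(x)),
    marginal = c(h1_amp, h1_amp, -h1_amp),
    saturated = c(1.3 * h1_amp, max(x), min(x))
  )
  # the residual surface is multimodal in both the ANN shift and the SOE
  # (the anchored kernel's envelope moves with soe), so the smooth optimizer
  # is started from a small grid of soe values as well
  soe_inits <- unique(c(opts$soe_bounds, mean(opts$soe_bounds)))

  counter <- new.env(parent = emptyenv())
  counter$n <- 0L

  start_par <- function(regime, soe0) {
    p0 <- base_par
    p0[c(1, 3, 4)] <- regime
    p0[6] <- soe0
    pmin(pmax(p0, lower), upper)
  }

  # stage 1 — screen: two quick optimizations per candidate shift (the
  # marginal and deeply saturated regimes) at mid-range soe
  soe_mid <- mean(opts$soe_bounds)
  screen <- unlist(lapply(seq_len(n) - 1L, function(s) {
    lapply(regime_inits[c("marginal", "saturated")], function(rg) {
      fit_at_shift(x, gi, s, start_par(rg, soe_mid), lower, upper, opts, counter)
    })
  }), recursive = FALSE)
  screen_shift <- vapply(screen, `[[`, numeric(1), "shift")
  screen_sse <- vapply(screen, `[[`, numeric(1), "sse")
  shift_sse <- vapply(seq_len(n) - 1L, function(s) {
    min(screen_sse[screen_shift == s])
  }, numeric(1))

  # stage 2 — polish the most promising shifts (plus the initial-guess
  # shift, so the solution can never be worse than the starting guess) with
  # the full grid of cutoff and soe starts
  m <- min(opts$multistart_phases, n)
  polish_shifts <- union(
    (seq_len(n) - 1L)[order(shift_sse)][seq_len(m)],
    round(guess$ann$phi_ann * n) %% n
  )
  runs <- screen
  for (s in polish_shifts) {
    for (rg in regime_inits) {
      for (soe0 in soe_inits) {
        runs[[length(runs) + 1]] <-
          fit_at_shift(x, gi, s, start_par(rg, soe0), lower, upper, opts, counter)
      }
    }
  }
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best <- runs[[which.min(sses)]]

  # refine the discrete ANN shift by hill-climbing, warm-starting from the
  # incumbent solution
  visited <- c(best$shift)
  repeat {
    cand_shifts <- setdiff(((best$shift + c(-1, 1)) %% n), visited)
    if (length(cand_shifts) == 0) break
    cands <- lapply(cand_shifts, function(s) {
      fit_at_shift(x, gi, s, best$par, lower, upper, opts, counter)
    })
    visited <- c(visited, cand_shifts)
    csse <- vapply(cands, `[[`, numeric(1), "sse")
    if (min(csse) < best$sse) best <- cands[[which.min(csse)]] else break
  }

  p <- best$par
  params <- model_params(
    cm = cm_params(a_cm = p[1], phi_cm = p[2],
                   upper_cutoff = p[3], lower_cutoff = p[4]),
    ann = ann_params(a_ann = p[5], phi_ann = best$shift / n,
                     soe = p[6], up_frequency = opts$up_frequency)
  )
  cm_comp <- cm_eval(gi$time, gi$f, p[1], p[2], p[3], p[4])
  ann_comp <- ann_eval(gi, p[5], best$shift / n, p[6], opts$up_frequency)
  modeled <- cm_comp + ann_comp
  gof <- goodness_of_fit(x, modeled)

  structure(
    list(
      params = params,
      phases_wrapped = c(phi_cm = p[2] %% 1, phi_ann = (best$shift / n) %% 1),
      observed = x,
      modeled = modeled,
      cm_component = cm_comp,
      ann_component = ann_comp,
      time = gi$time,
      stimulus_frequency = gi$f,
      sampling_rate = gi$fs,
      r = gof$r,
      r_squared = gof$r_squared,
      sse = best$sse,
      converged = best$info %in% 1:4,
      n_evaluations = counter$n,
      n_starts = length(runs),
      options = opts
    ),
    class = "ecochg_fit"
  )
}

#' Goodness of fit between observed and modeled cycles
#'
#' `r` is the maximum normalized cross-correlation between the two series
#' over all circular lags (so a pure time shift still scores 1); `r_squared`
#' is the zero-lag coefficient of determination
#' `1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,modeled Equal-length numeric series (or tibbles with an
#'   `amplitude` column).
#' @return A list with elements `r` and `r_squared`.
#' @export
goodness_of_fit <- function(observed, modeled) {
  if (is.data.frame(observed)) observed <- observed$amplitude
  if (is.data.frame(modeled)) modeled <- modeled$amplitude
  if (length(observed) != length(modeled)) {
    abort_data("`observed` and `modeled` must have equal length.")
  }
  if (sd(observed) == 0) {
    abort_data("`observed` is constant: correlation and r-squared are undefined.")
  }
  r <- if (sd(modeled) == 0) {
    NA_real_
  } else {
    max(vapply(seq_along(modeled) - 1, function(lag) {
      cor(observed, circ_shift(modeled, lag))
    }, numeric(1)))
  }
  r2 <- 1 - sum((observed - modeled)^2) / sum((observed - mean(observed))^2)
  list(r = r, r_squared = r2)
}
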
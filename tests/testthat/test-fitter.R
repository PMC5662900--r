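test_that("the initial guess reads the first harmonic and is deterministic", {
  cyc <- make_cycle(sine_cycle(1, phase = 0.15))
  g1 <- initial_guess(cyc)
  expect_equal(g1$cm$a_cm, 1, tolerance = 1e-9)
  expect_equal(g1$cm$phi_cm, 0.15, tolerance = 1e-9)
  expect_equal(g1$ann$a_ann, 0.2 * g1$cm$a_cm)
  expect_equal(g1$ann$soe, 0.5)

  g2 <- initial_guess(cyc)
  expect_identical(g1, g2)

  expect_error(initial_guess(make_cycle(rep(0, 32))), class = "ecochg_data_error")
})

test_that("goodness of fit separates lag-max correlation from zero-lag determination", {
  x <- sine_cycle(1) + 0.2 * sin(4 * pi * (0:31) / 32)

  same <- goodness_of_fit(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$r_squared, 1)

  shifted <- goodness_of_fit(x, ecochg:::circ_shift(x, 5))
  expect_equal(shifted$r, 1, tolerance = 1e-12)
  expect_lt(shifted$r_squared, 1)

  zero_model <- goodness_of_fit(x - mean(x), rep(0, 32))
  expect_equal(zero_model$r_squared, 0)

  expect_error(goodness_of_fit(rep(1, 32), x), class = "ecochg_data_error")
})

test_that("a pure sinusoid is fit as essentially all CM", {
  fit <- fit_decomposition(make_cycle(sine_cycle(0.9, phase = 0.3)))
  expect_gte(fit$r_squared, 0.99)
  mags <- component_magnitudes(fit, "first_harmonic")
  expect_lte(mags["ann_magnitude"] / mags["cm_magnitude"], 0.05)
  expect_equal(fit$params$cm$a_cm, 0.9, tolerance = 0.05)
})

test_that("noise-free model outputs are refit essentially exactly", {
  g <- default_grid()
  cases <- list(
    model_params(saturating_cm(1), ann_params(0.3, 0, 0.65)),
    model_params(saturating_cm(1, trough_saturation_pct = 15), ann_params(0.43, 0, 0.65)),
    model_params(saturating_cm(0.8, phi_cm = 0.2), ann_params(0.5, 0.45, 0.45)),
    model_params(
      cm_params(1.2, phi_cm = -0.1, upper_cutoff = 1.0, lower_cutoff = -1.1),
      ann_params(0.2, -0.25, 0.35)
    )
  )
  for (p in cases) {
    cyc <- generate_simulated_cycle(p, g)
    fit <- fit_decomposition(cyc)
    expect_gte(fit$r_squared, 0.99)
    # round-trip residual energy is negligible relative to signal energy
    expect_lte(fit$sse, 1e-4 * sum(cyc$amplitude^2))
    expect_equal(fit$params$cm$a_cm, p$cm$a_cm, tolerance = 0.05 * p$cm$a_cm)
    expect_equal(fit$params$ann$a_ann, p$ann$a_ann, tolerance = 0.05 * p$ann$a_ann)
  }
})

test_that("the returned solution is never worse than the initial guess", {
  set.seed(21)
  g <- default_grid()
  p <- model_params(saturating_cm(1, trough_saturation_pct = 10), ann_params(0.4, 0.3, 0.5))
  cyc <- generate_simulated_cycle(p, g, noise_sd = 0.1, seed = 99)
  fit <- fit_decomposition(cyc)
  guess <- initial_guess(cyc)
  sse_guess <- sum((ecochg_model(default_grid(), guess)$amplitude - cyc$amplitude)^2)
  expect_lte(fit$sse, sse_guess)
})

test_that("fitted amplitudes and cutoffs scale with the input", {
  g <- default_grid()
  p <- model_params(
    cm_params(1, phi_cm = 0.05, upper_cutoff = 0.9, lower_cutoff = -0.95),
    ann_params(0.3, 0.1, 0.55)
  )
  cyc1 <- generate_simulated_cycle(p, g)
  k <- 7.5
  cyc2 <- make_cycle(k * cyc1$amplitude)
  f1 <- fit_decomposition(cyc1)
  f2 <- fit_decomposition(cyc2)
  expect_equal(f2$params$cm$a_cm, k * f1$params$cm$a_cm, tolerance = 1e-3)
  expect_equal(f2$params$ann$a_ann, k * f1$params$ann$a_ann, tolerance = 1e-3)
  expect_equal(f2$params$cm$upper_cutoff, k * f1$params$cm$upper_cutoff, tolerance = 1e-3)
  expect_equal(f2$params$cm$lower_cutoff, k * f1$params$cm$lower_cutoff, tolerance = 1e-3)
})

test_that("phases differing by whole cycles give identical model output", {
  g <- default_grid()
  for (d in c(-2, -1, 1, 2)) {
    expect_equal(
      ecochg_model(g, model_params(cm_params(1, phi_cm = 0.2 + d), ann_params(0.4, 0.3 + d, 0.5)))$amplitude,
      ecochg_model(g, model_params(cm_params(1, phi_cm = 0.2), ann_params(0.4, 0.3, 0.5)))$amplitude
    )
  }
})

test_that("degenerate inputs are rejected with a data error", {
  expect_error(fit_decomposition(make_cycle(rep(0, 32))), class = "ecochg_data_error")
  # a strictly positive cycle never crosses zero: not an ongoing response
  expect_error(fit_decomposition(make_cycle(rep(1, 32))), class = "ecochg_data_error")
})
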
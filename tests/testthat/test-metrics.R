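make_metrics <- function(ann, cm) {
  m <- tibble::tibble(
    cm_magnitude = cm, ann_magnitude = ann,
    ann_cm_ratio = ann / cm,
    ann_cm_index = ann_cm_index(ann, cm),
    ann_re_cm_db = if (ann > 0) amplitude_to_db(ann, cm) else -Inf,
    basis = "first_harmonic", cutoff_applied = FALSE
  )
  structure(m, class = c("eco_metrics", class(m)))
}

test_that("the ANN/CM index hits its endpoints and inverts to the fold ratio", {
  expect_equal(ann_cm_index(0, 1), -1)
  expect_equal(ann_cm_index(0.7, 0.7), 0)
  expect_equal(ann_cm_index(1, 0), 1)

  # an index of -0.56 corresponds to a CM about 3.5 times the ANN
  idx <- -0.56
  cm_over_ann <- (1 - idx) / (1 + idx)
  expect_equal(cm_over_ann, 3.5, tolerance = 0.05)

  expect_error(ann_cm_index(0, 0), class = "ecochg_data_error")
})

test_that("the index is antisymmetric, scale-invariant, and consistent with the ratio", {
  pairs <- list(c(0.2, 1), c(1.4, 0.7), c(0.05, 0.05), c(3, 0.1))
  for (p in pairs) {
    expect_equal(ann_cm_index(p[1], p[2]), -ann_cm_index(p[2], p[1]))
    for (k in c(0.01, 1, 250)) {
      expect_equal(ann_cm_index(k * p[1], k * p[2]), ann_cm_index(p[1], p[2]))
    }
    ratio <- p[1] / p[2]
    expect_equal(ann_cm_index(p[1], p[2]), (ratio - 1) / (ratio + 1))
  }
})

test_that("dB conversion matches the 20 log10 rule", {
  expect_equal(amplitude_to_db(0.02, 1), -34, tolerance = 0.05)
  expect_equal(amplitude_to_db(1, 1), 0)
  expect_equal(amplitude_to_db(2, 1), 6.02, tolerance = 0.005)
  expect_error(amplitude_to_db(0, 1), class = "ecochg_data_error")
  expect_error(amplitude_to_db(1, -2), class = "ecochg_data_error")
})

test_that("the small-ratio cutoff zeroes the ANN below 5% but keeps the index", {
  low <- apply_small_ratio_cutoff(make_metrics(0.04, 1))
  expect_true(low$cutoff_applied)
  expect_equal(low$ann_magnitude, 0)
  expect_equal(low$ann_cm_index, ann_cm_index(0.04, 1)) # index untouched

  at <- apply_small_ratio_cutoff(make_metrics(0.05, 1))
  expect_false(at$cutoff_applied) # strict inequality
  expect_equal(at$ann_magnitude, 0.05)

  high <- apply_small_ratio_cutoff(make_metrics(0.5, 1))
  expect_equal(as.data.frame(high), as.data.frame(make_metrics(0.5, 1)))
})

test_that("component magnitudes agree across bases only without saturation", {
  g <- default_grid()
  clean <- fit_decomposition(generate_simulated_cycle(
    model_params(saturating_cm(1), ann_params(0.3, 0.1, 0.5)), g
  ))
  mp <- component_magnitudes(clean, "parameter")
  mh <- component_magnitudes(clean, "first_harmonic")
  expect_equal(unname(mp["cm_magnitude"]), unname(mh["cm_magnitude"]), tolerance = 1e-6)

  clipped <- fit_decomposition(generate_simulated_cycle(
    model_params(
      saturating_cm(1, peak_saturation_pct = 50, trough_saturation_pct = 50),
      ann_params(0.3, 0.1, 0.5)
    ), g
  ))
  mp2 <- component_magnitudes(clipped, "parameter")
  mh2 <- component_magnitudes(clipped, "first_harmonic")
  # clipping moves fundamental energy into higher harmonics
  expect_lt(mh2["cm_magnitude"], mp2["cm_magnitude"])

  zero_ann <- generate_simulated_cycle(model_params(saturating_cm(1), ann_params(0)), g)
  fit0 <- fit_decomposition(zero_ann)
  m0 <- decomposition_metrics(fit0)
  expect_lte(m0$ann_cm_ratio, 0.05)
})

test_that("decomposition metrics assemble ratio, index and dB consistently", {
  g <- default_grid()
  fit <- fit_decomposition(generate_simulated_cycle(
    model_params(saturating_cm(1), ann_params(0.4, 0.2, 0.6)), g
  ))
  m <- decomposition_metrics(fit)
  expect_equal(m$ann_cm_ratio, m$ann_magnitude / m$cm_magnitude)
  expect_equal(m$ann_cm_index, (m$ann_cm_ratio - 1) / (m$ann_cm_ratio + 1))
  expect_equal(m$ann_re_cm_db, 20 * log10(m$ann_cm_ratio))
  expect_false(m$cutoff_applied)
})
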
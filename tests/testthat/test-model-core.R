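test_that("CM waveform is a clipped sinusoid with the stated values", {
  g <- default_grid()

  expect_equal(cm_waveform(g, cm_params(0))$amplitude, rep(0, 32))

  w <- cm_waveform(g, cm_params(1, phi_cm = 0, upper_cutoff = 10, lower_cutoff = -10))
  # t = 0.5 ms is a quarter cycle of 500 Hz: sin(pi/2) = 1
  expect_equal(w$amplitude[w$time == 0.0005], 1.0)

  clipped <- cm_waveform(g, cm_params(1, upper_cutoff = 0.5, lower_cutoff = -10))
  expect_equal(max(clipped$amplitude), 0.5)
  expect_equal(min(clipped$amplitude), -1.0)

  expect_error(cm_params(1, upper_cutoff = -1, lower_cutoff = 1), class = "ecochg_config_error")
})

test_that("clipping is idempotent and unclipped CM scales linearly", {
  g <- default_grid()
  once <- cm_waveform(g, cm_params(2, phi_cm = 0.13, upper_cutoff = 1.1, lower_cutoff = -0.7))
  twice <- dplyr::mutate(once, amplitude = pmin(pmax(amplitude, -0.7), 1.1))
  expect_equal(twice$amplitude, once$amplitude)

  for (k in c(0, 0.5, 3)) {
    expect_equal(
      cm_waveform(g, cm_params(k * 1.3, phi_cm = 0.2))$amplitude,
      k * cm_waveform(g, cm_params(1.3, phi_cm = 0.2))$amplitude
    )
  }
})

test_that("unit potential is one zero-mean sine cycle with unit peak", {
  up <- unit_potential(1100, 48000)
  expect_equal(nrow(up), 44) # round(48000 / 1100)
  expect_equal(sum(up$amplitude), 0, tolerance = 1e-12)
  expect_equal(max(abs(up$amplitude)), 1)

  up15 <- unit_potential(1100, 16000)
  expect_equal(nrow(up15), 15)
  expect_equal(max(abs(up15$amplitude)), 1)
  # negative-going half first
  expect_lt(up15$amplitude[2], 0)

  expect_error(unit_potential(1100, 2000), class = "ecochg_config_error")
})

test_that("cycle histogram is unit-peak, widens with SOE, and peaks where the density says", {
  g <- default_grid()
  for (soe in c(0.35, 0.5, 0.65)) {
    h <- cycle_histogram(g, ann_params(1, soe = soe))$density
    expect_gte(min(h), 0)
    expect_equal(max(h), 1)
  }

  fwhm <- function(soe) {
    tt <- seq(0, 1 / 500, length.out = 1e5)
    d <- dlnorm(pmax(tt * 1100, 1e-6), 0, soe)
    d <- d / max(d)
    mean(d >= 0.5) # fraction of the cycle above half maximum
  }
  expect_gt(fwhm(0.65), fwhm(0.35))

  # mode location against a dense-grid maximization of the same density
  tt <- seq(1e-9, 1 / 500, length.out = 1e5)
  dense_mode <- tt[which.max(dlnorm(tt * 1100, 0, 0.5))]
  h <- cycle_histogram(g, ann_params(1, soe = 0.5))
  coarse_mode <- h$time[which.max(h$density)]
  expect_lt(abs(coarse_mode - dense_mode), 1 / 16000) # within one sample

  expect_error(ann_params(1, soe = 0.7), class = "ecochg_config_error")
})

test_that("ANN waveform matches the brute-force circular-convolution oracle", {
  g <- default_grid()
  expect_equal(ann_waveform(g, ann_params(0))$amplitude, rep(0, 32))

  # full-cycle shift is the identity
  expect_equal(
    ann_waveform(g, ann_params(0.7, phi_ann = 1.0, soe = 0.5))$amplitude,
    ann_waveform(g, ann_params(0.7, phi_ann = 0, soe = 0.5))$amplitude
  )

  for (phi in c(0, 0.25, -0.4)) {
    for (soe in c(0.35, 0.55)) {
      got <- ann_waveform(g, ann_params(0.8, phi_ann = phi, soe = soe))$amplitude
      want <- ann_oracle(g, 0.8, phi, soe)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("circular shift composes additively and ANN scales linearly", {
  x <- rnorm(32)
  set.seed(4)
  shift <- ecochg:::circ_shift
  for (a in c(1, 5, 30)) {
    for (b in c(2, 17)) {
      expect_equal(shift(shift(x, a), b), shift(x, (a + b) %% 32))
    }
  }
  g <- default_grid()
  base <- ann_waveform(g, ann_params(1, soe = 0.6))$amplitude
  for (k in c(0, 0.3, 2)) {
    expect_equal(ann_waveform(g, ann_params(k, soe = 0.6))$amplitude, k * base)
  }
})

test_that("the full model is the CM + ANN sum and interference follows phase", {
  g <- default_grid()
  cm <- cm_params(1, phi_cm = 0.1)
  ann <- ann_params(0.5, phi_ann = 0.3, soe = 0.5)
  p <- model_params(cm, ann)

  total <- ecochg_model(g, p)$amplitude
  expect_equal(total, cm_waveform(g, cm)$amplitude + ann_waveform(g, ann)$amplitude)
  expect_equal(total - ann_waveform(g, ann)$amplitude, cm_waveform(g, cm)$amplitude)

  p0 <- model_params(cm_params(1), ann_params(0, soe = 0.5))
  expect_equal(ecochg_model(g, p0)$amplitude, cm_waveform(g, cm_params(1))$amplitude)

  pp <- function(phase_diff) {
    x <- ecochg_model(g, model_params(
      cm_params(1),
      ann_params(1, phi_ann = phase_diff, soe = 0.5)
    ))$amplitude
    diff(range(x))
  }
  expect_gt(pp(0), pp(0.5))
})

test_that("FFT circular convolution agrees with the oracle on grids 8 to 256", {
  set.seed(11)
  for (n in c(8, 9, 16, 33, 64, 127, 256)) {
    a <- rnorm(n)
    b <- rnorm(n)
    expect_equal(ecochg:::circ_conv(a, b), circ_conv_oracle(a, b), tolerance = 1e-10)
  }
})
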
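# shared fixtures: the human-recording-like grid and a brute-force circular
# convolution oracle kept independent of the FFT path under test

default_grid <- function() time_grid(500, 16000)

# O(N^2) circular convolution: c[i] = sum_j a[j] * b[(i - j) mod n]
circ_conv_oracle <- function(a, b) {
  n <- length(a)
  vapply(seq_len(n) - 1, function(i) {
    s <- 0
    for (j in seq_len(n) - 1) {
      s <- s + a[j + 1] * b[((i - j) %% n) + 1]
    }
    s
  }, numeric(1))
}

# ANN series built entirely from the oracle convolution (mirrors the
# documented construction: lognormal CH, one-cycle UP, unit-peak kernel,
# integer-sample circular shift)
ann_oracle <- function(grid, a_ann, phi_ann, soe, up_frequency = 1100) {
  fs <- attr(grid, "sampling_rate")
  n <- attr(grid, "n_samples")
  x <- grid$time * up_frequency
  x[x <= 0] <- 1e-6
  ch <- dlnorm(x, 0, soe)
  ch <- ch / max(ch)
  n_up <- round(fs / up_frequency)
  up <- -sin(2 * pi * (seq_len(n_up) - 1) / n_up)
  up <- up / max(abs(up))
  k <- circ_conv_oracle(ch, c(up, rep(0, n - n_up)))
  # same phase anchoring as the documented construction: the kernel's
  # fundamental is advanced (fractional circular delay) onto an unshifted
  # sine before unit-peak normalization
  ph <- ((-Arg(fft(k)[2]) - pi / 2) / (2 * pi)) %% 1
  kk <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n)
  ramp <- exp(-2i * pi * kk * (-ph * n) / n)
  if (n %% 2 == 0) ramp[n / 2 + 1] <- cos(pi * (-ph * n))
  k <- Re(fft(fft(k) * ramp, inverse = TRUE)) / n
  k <- k / max(abs(k))
  s <- round(phi_ann * n) %% n
  k <- if (s == 0) k else c(k[(n - s + 1):n], k[1:(n - s)])
  a_ann * k
}

sine_cycle <- function(amplitude = 1, phase = 0, grid = default_grid()) {
  f <- attr(grid, "stimulus_frequency")
  amplitude * sin(2 * pi * (f * grid$time - phase))
}

# a valid eco_cycle carrying arbitrary samples
make_cycle <- function(x, sampling_rate = 16000, stimulus_frequency = 500) {
  ecochg:::new_eco_cycle(x, sampling_rate, stimulus_frequency)
}
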
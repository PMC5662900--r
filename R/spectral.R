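#' Harmonic amplitude spectrum with a noise-floor significance test
#'
#' Computes the single-sided amplitude spectrum (uV) of a voltage series and
#' reads off the magnitude at each harmonic of the stimulus frequency. For
#' each harmonic peak the local noise floor is estimated from the 3 FFT bins
#' on either side (6 bins pooled, peak excluded); a harmonic is significant
#' when its magnitude exceeds the noise mean by more than 3 noise standard
#' deviations.
#'
#' An average cycle is analyzed by concatenating `n_cycles` copies (default
#' 8) so that every harmonic falls exactly on an FFT bin; no window function
#' is applied.
#'
#' @param x An `eco_cycle`, an `eco_waveform`, or a numeric voltage series
#'   (uV).
#' @param sampling_rate,stimulus_frequency Required (Hz) when `x` is a bare
#'   numeric vector; taken from attributes otherwise.
#' @param n_harmonics Number of harmonics to report (default 3).
#' @param n_cycles Copies of an average cycle concatenated before the FFT.
#' @return A tibble of class `eco_spectrum` with one row per harmonic:
#'   `harmonic`, `frequency`, `magnitude`, `noise_mean`, `noise_sd`,
#'   `significant`; attribute `fft_length`.
#' @export
harmonic_spectrum <- function(x, sampling_rate = NULL, stimulus_frequency = NULL,
                              n_harmonics = 3, n_cycles = 8) {
  if (inherits(x, "eco_cycle")) {
    ci <- cycle_info(x)
    series <- rep(ci$x, n_cycles)
    fs <- ci$fs
    f0 <- ci$f
  } else if (inherits(x, "eco_waveform")) {
    wi <- waveform_info(x)
    series <- wi$x
    fs <- wi$fs
    f0 <- wi$f
  } else {
    if (is.null(sampling_rate) || is.null(stimulus_frequency)) {
      abort_config("`sampling_rate` and `stimulus_frequency` are required for a bare numeric series.")
    }
    series <- as.numeric(x)
    fs <- sampling_rate
    f0 <- stimulus_frequency
  }
  nfft <- length(series)
  if (n_harmonics * f0 >= fs / 2) {
    abort_config(paste0("Harmonic ", n_harmonics, " (", n_harmonics * f0,
                        " Hz) is at or above the Nyquist frequency."))
  }
  if (nfft < 2 * n_harmonics * round(fs / f0)) {
    abort_data("Series too short to resolve the requested harmonics.")
  }
  mag <- 2 * Mod(fft(series)) / nfft # single-sided amplitude, uV
  df <- fs / nfft
  # numerical floor: bins at double-precision roundoff (relative to the
  # largest spectral line) are treated as exactly zero, so noise-free
  # periodic signals give deterministic significance calls
  floor_uv <- 1e-12 * max(mag)
  rows <- purrr::map_dfr(seq_len(n_harmonics), function(h) {
    bin <- round(h * f0 / df) + 1L
    noise_bins <- c(bin - 3:1, bin + 1:3)
    noise_bins <- noise_bins[noise_bins >= 2 & noise_bins <= nfft %/% 2 + 1]
    nm <- mean(mag[noise_bins])
    ns <- sd(mag[noise_bins])
    tibble(
      harmonic = h,
      frequency = h * f0,
      magnitude = mag[bin],
      noise_mean = nm,
      noise_sd = ns,
      significant = mag[bin] > nm + 3 * ns + floor_uv
    )
  })
  structure(rows,
    fft_length = nfft,
    class = c("eco_spectrum", class(rows))
  )
}

#' Total response across stimulus frequencies
#'
#' Sums the magnitudes of all significant harmonics 1-3 across a set of
#' harmonic spectra, one per stimulus frequency. This is a single summary of
#' overall response strength that pools hair-cell and neural energy.
#'
#' @param summaries An `eco_spectrum` or a list of them.
#' @return Total significant-harmonic magnitude in uV.
#' @export
total_response <- function(summaries) {
  if (inherits(summaries, "eco_spectrum")) summaries <- list(summaries)
  purrr::map_dbl(summaries, function(s) {
    if (nrow(s) < 3) abort_config("Each spectrum must report at least 3 harmonics.")
    keep <- s$harmonic <= 3 & s$significant
    sum(s$magnitude[keep])
  }) |> sum()
}
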
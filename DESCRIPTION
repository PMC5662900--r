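Package: ecochg
Title: Decomposition of Electrocochleography Responses into Hair-Cell and
    Neural Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based decomposition of the ongoing electrocochleography
    (ECochG) response to low-frequency tone bursts into its cochlear
    microphonic (CM) and auditory nerve neurophonic (ANN) components. The CM
    is modeled as a sinusoid at the stimulus frequency with independent peak
    and trough saturation; the ANN as a unit potential convolved circularly
    with a lognormal population cycle histogram. Components are estimated by
    bounded nonlinear least squares on the average cycle of the ongoing
    response. Includes average-cycle extraction from recorded waveforms,
    harmonic spectral analysis with a noise-floor significance test,
    ANN/CM summary metrics, and a simulated-signal harness for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
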
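Package: semgsim
Title: Simulation Toolkit for Multichannel Wireless Surface EMG Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A software twin of a multichannel wireless surface
    electromyography (sEMG) acquisition platform. Generates synthetic
    band-limited sEMG with contraction envelopes, mains interference and
    motion artifacts; models the analog front-end (instrumentation
    amplifier, cascaded high-pass sections, second-order low-pass) and a
    12-bit 1 kS/s digitizer; implements the sensor-to-hub packet format,
    a seeded lossy-link simulator, the hub's channel bookkeeping with
    counter-gap packet-loss accounting (QoS), the hub-to-host serial
    frame codec, and a binary-plus-JSON recording format. Includes the
    evaluation methodology: Bode extraction, component-tolerance Monte
    Carlo, averaged-periodogram spectra, 60 Hz interference deltas,
    loss-versus-distance sweeps, packet-timing rasters and power-budget
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
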
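Package: fireflyeeg
Title: Phase-Alignment Simulation and Empirical Mode Analysis of Event-Related EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation of event-related EEG under the Firefly
    phase-alignment model, in which event-related potentials, band-limited
    (de)synchronization and spectral changes all arise from frequency-dependent
    phase alignment of ongoing oscillations with no change in power, together
    with the analysis chain that discriminates phase alignment from an added
    evoked signal: empirical mode decomposition by sifting, Hilbert
    amplitude/phase/instantaneous-frequency measures, phase-locking values,
    conventional ERP/ERD-ERS/Welch spectra, partial least squares condition
    contrasts with permutation and bootstrap inference, and closed-loop
    estimation of the model's frequency-dependent timing parameters.
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
    purrr,
    readr,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
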
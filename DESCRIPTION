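Package: neuroload
Title: Multifaceted EEG Dynamics of Endogenous Cognitive Load
Version: 0.1.0
Authors@R: person("neuroload", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Analysis pipeline for band-specific and scale-free EEG dynamics
    under endogenous cognitive load (silent backward counting). Implements
    Bartlett-averaged amplitude spectra with a mains-interpolation notch,
    split-band aperiodic (1/f) parameterization with Gaussian peaks and
    split-half reliability, phase-amplitude coupling via the modulation
    index and phase-synchronized Morse-wavelet time-frequency folding,
    cluster-based permutation statistics over electrode topographies with
    paired effect sizes, behavioural scoring of serial-subtraction tasks,
    and a synthetic multi-channel EEG generator with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
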
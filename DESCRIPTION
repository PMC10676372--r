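Package: sdlamina
Title: Laminar Analysis of Spreading Depolarizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of spreading depolarizations (SDs)
    in DC-coupled laminar field-potential and single-channel ECoG recordings.
    Implements SD onset detection from the slow-potential derivative and
    vertical stop-depth determination on silicon-probe geometries,
    depression/no-change/boom classification of SD-related activity changes
    from windowed spectral power (Welch and Slepian multitaper estimators),
    current source density maps, independent-component decomposition of the
    laminar field potential into spatial generators, adaptive multi-unit spike
    detection with three-zone laminar mapping, spike-gamma phase coupling with
    circular statistics, and intracellular depolarization-block metrics.
    Ships a forward model of a cortical column (volume-conducted delta
    generators, propagating SD waves with configurable stop depth, gamma-
    modulated spiking, intracellular trajectories) with full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
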
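Package: anapattern
Title: Automated Evaluation of HEp-2 Indirect Immunofluorescence ANA Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and automated evaluation of antinuclear-antibody (ANA)
    indirect immunofluorescence on HEp-2 cells. Generates ground-truthed
    two-channel (FITC antibody + propidium-iodide counterstain) field images
    for the classical staining patterns, segments nuclei from the counterstain
    channel, decides positive/negative from a normalized image fluorescence
    intensity, classifies per-cell patterns by k-nearest neighbours against a
    labelled reference database of texture and intensity features, synthesizes
    cell results into per-dilution and per-patient reports with endpoint titer
    estimation, and computes the agreement statistics (concordance, Cohen's
    kappa with Altman interpretation, sensitivity/specificity/PPV/NPV) used to
    validate automated readers against visual evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
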
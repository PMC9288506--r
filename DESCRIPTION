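Package: lipsite
Title: Binding-Site Deconvolution from Dose-Resolved Limited-Proteolysis
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating small-molecule binding sites on protein
    structures from dose-resolved limited-proteolysis mass spectrometry
    (LiP-MS) peptide quantification data. Candidate peptides are selected
    by differential testing of high doses against vehicle, fitted with
    four-parameter log-logistic dose-response curves, ranked by goodness
    of fit, and the top-ranking peptides are mapped onto a PDB structure
    where the center of mass of their atoms triangulates the predicted
    site. Also ranks candidate targets from isobaric-label competition
    pulldown experiments, and simulates both experiment types with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
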
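Package: enfacechoroid
Title: Depth-Resolved Enface SS-OCT Choroidal Layer Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the individual choroidal vascular layers from swept-source
    optical coherence tomography (SS-OCT) volumes by enface reconstruction. The
    retinal pigment epithelium (RPE)/Bruch's membrane complex is segmented as a
    reference surface, enface planes are extracted at one-pixel (4.13 micrometre)
    depth intervals, and the choriocapillaris-to-choroidal-vessel transition and
    the choroidal-scleral interface are detected from plane texture statistics.
    Absolute and relative layer thicknesses are derived per eye, averaged per
    subject, and compared between age groups with pooled t-tests; agreement
    statistics (intraclass correlation, Bland-Altman) support internal and
    external validation. A synthetic-data module renders layered, speckled OCT
    volumes of two-eye cohorts with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
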
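Package: gmrscore
Title: Quantitative Gingival Melanosis Scoring from Oral Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-driven quantitative measurement of gingival melanin
    pigmentation from frontal oral photographs. Constructs the gingival
    melanosis record (GMR) sampling lattice from anatomical landmarks
    (baseline at the crown length of the maxillary right lateral incisor,
    vertical lines at mesial/central/distal positions of the six anterior
    maxillary teeth, nine equally spaced points per line restricted to the
    attached gingiva), calls pigmentation at each retained site from CIELAB
    lightness or from manual call tables, reports the GMR percentage and an
    operationalized Hedin 0-4 grade, and provides the reproducibility and
    cohort statistics used with the method: intraclass correlation
    coefficients ICC(1,1)/ICC(2,1), one-way ANOVA across 10-year age groups,
    paired t-tests of baseline versus follow-up, and Spearman rank
    correlation. Includes generators for stylized synthetic oral photographs
    with ground-truth annotations and for simulated longitudinal
    smoking-cessation cohorts, plus an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
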
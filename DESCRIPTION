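Package: metalmon
Title: Trace-Metal Air Biomonitoring Analysis with Leaf and Lichen Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for active biomonitoring surveys of airborne
    trace metals. Provides a survey data model with detection-limit handling,
    Al-normalized accumulation and enrichment factors with their standard
    classification schemes, principal component source apportionment with
    anti-image screening, KMO and Bartlett adequacy statistics and varimax
    rotation, inverse-distance-weighted hotspot mapping, concentric-crown
    distance-decay profiles and quadrant tests around a point source,
    co-located biomonitor comparison via major-axis (Model II) regression
    with permutation tests, and a synthetic paired-survey generator that
    emulates a 49-site, 22-element urban-industrial study design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
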
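Package: drugrec
Title: Cluster-Based Collaborative Filtering for Diabetes Drug Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds drug recommendations for diabetes inpatients from hospital
    encounter records. Encounters in the 130-US-hospitals schema are cleaned and
    transformed into a numeric per-patient feature table, patients are grouped
    by K-means or DBSCAN on principal-component scores with silhouette-based
    model selection, and dose-change codes (no/down/steady/up) form a
    patient-by-drug rating matrix on which cluster-restricted, user-based
    collaborative filtering predicts dose values and ranks top-N drug
    recommendations. Includes held-out evaluation (mean squared error of
    predicted doses, precision of recommendations) and a synthetic encounter
    generator with planted cluster structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
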
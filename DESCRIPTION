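Package: affectselect
Title: Cluster-Based Selection of Representative Stimuli from Normative
    Affective Rating Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening and clustering normative affective rating
    databases (valence, arousal, dominance norms on 9-point scales) in order
    to build empirically grounded experimental stimulus groups. Provides
    duplicate merging, robust median-absolute-deviation outlier removal and
    confidence-interval precision filtering with a full audit trail;
    parsimonious Gaussian mixture clustering via EM under ten
    eigen-decomposed covariance parameterisations with BIC model selection
    and per-stimulus classification uncertainties; k-means and hierarchical
    baseline clusterers with cluster-validity indices; partition concordance
    metrics (Variation of Information, Adjusted Rand Index, Cramer's phi)
    and split-half / jack-knife stability validation; uncertainty-ranked
    exemplar selection; and a synthetic norms generator with known ground
    truth for end-to-end testing without licensed databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    yaml,
    jsonlite
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
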
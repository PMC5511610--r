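Package: mppqtl
Title: QTL Detection in Multi-Parent Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint QTL mapping for multi-parent populations (MPPs) such as
    nested association mapping (NAM) panels of doubled-haploid lines.
    Implements four QTL effect models (parental, ancestral, bi-allelic and
    multi-QTL-effect) crossed with homogeneous (HRT) and cross-specific
    (CSRT) residual variance structures, Wald-test genome scans with
    simple and composite interval mapping, permutation-based significance
    thresholds, backward elimination, and a cross-validation scheme that
    measures explained (pTS) and predicted (pVS) genetic variance. A
    built-in NAM simulator with known QTL architecture supports testing
    and power studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
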
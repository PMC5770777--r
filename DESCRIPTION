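Package: mirclock
Title: Whole-Blood miRNA Aging Clock and Delta-Age Association Pipeline
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating a microRNA-based biological
    age predictor from whole-blood qPCR (cycle-threshold) expression profiles
    in family cohorts. Implements Ct-scale quality control and technical
    normalization, kinship-aware linear mixed models (profile REML on the
    eigendecomposition of the pedigree relationship matrix) for per-miRNA
    differential expression against chronological age, an elastic-net age
    clock with pedigree-respecting data splits, the delta-age biomarker and
    its narrow-sense heritability, Cox proportional-hazards and mixed-model
    associations of delta-age with mortality and cardiometabolic traits,
    surrogate-variable-adjusted miRNA-mRNA coexpression scans with
    Benjamini-Hochberg control, canonical seed-match target prediction
    (8mer, 7mer-m8, 7mer-A1, 6mer), and hypergeometric / Fisher gene-set
    enrichment. A pedigreed synthetic-cohort generator with known ground
    truth makes every stage testable without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    mixOmics,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
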
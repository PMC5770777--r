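# mirclock

An R package for building and interrogating a **whole-blood miRNA aging
clock** in family cohorts: from qPCR cycle-threshold (Ct) matrices to a
sparse "miRNA age" predictor, the **delta-age** biomarker (predicted minus
chronological age), and its downstream genetics and epidemiology —
heritability, all-cause mortality, cardiometabolic traits, miRNA–mRNA
coexpression, seed-match target prediction and gene-set enrichment. A
pedigreed synthetic-cohort generator with full ground truth makes every
stage testable without access to restricted cohort data.

## Who it is for

Statistical geneticists and computational biologists analyzing
qPCR-based miRNA panels in pedigree studies, where every association
model must account for familial relatedness, and anyone who wants a
self-contained, tested reference implementation of the
expression-clock / delta-age analysis pattern.

## The models at the core

**Kinship mixed model.** Every association stage fits
`y = Xβ + g + ε`, `g ~ N(0, σ²_A K)`, `ε ~ N(0, σ²_E I)`, with `K = 2Φ`
the expected additive relationship from the pedigree. The restricted
likelihood is profiled over `h² = σ²_A/(σ²_A + σ²_E)` after one (block-wise)
eigendecomposition of `K`, so scanning 150 miRNAs or thousands of
miRNA–mRNA pairs reuses a single rotation. Narrow-sense heritability is
`h²` from the same fit.

**The clock.** On standardized covariate-adjusted Ct residuals,
chronological age is regressed with the elastic net
(`α = 0.5`, penalty by pedigree-blocked 10-fold cross-validation or fixed
by the caller), trained on a discovery half whose pedigrees never overlap
the replication half. `Δage = predicted age − chronological age`.

**Downstream.** Cox proportional hazards (Efron ties) for mortality per
year of Δage; Kaplan–Meier curves by Δage tertile; kinship mixed models
for Δage vs traits with treatment-based exclusions; surrogate-variable
adjusted per-pair coexpression with Benjamini–Hochberg control; canonical
8mer/7mer-m8/7mer-A1/6mer seed matching; hypergeometric and Fisher exact
enrichment. Note the Ct convention throughout: lower Ct = higher
expression, so positive Ct slopes mean expression declines with age.

## Worked example

```r
library(mirclock)

report <- run_pipeline(pipeline_config(
  seed = 1,
  sim = list(n_families = 120, n_mirna = 40, n_mrna = 80,
             n_coupled_pairs = 20)))
print(report)
```

```
== miRNA aging-clock pipeline report ==
cohort: 584 individuals, 120 pedigrees, 40 miRNAs, 80 mRNAs (3.39% Ct censored)
QC: kept 584/584 samples, 35/40 miRNAs; 213 values filled
age scan: 24/35 miRNAs significant (Bonferroni p < 0.00143)
clock: 24 miRNAs; r = 0.76 (discovery, n=292) / 0.69 (replication, n=292)
delta-age heritability: h2 = 0.258 (SE 0.083)
mortality: HR 1.114 per delta-age year (95% CI 1.063-1.168; p = 6.9e-06; 50 events)
traits: 4/10 associated with delta age at Bonferroni p < 0.005
coexpression: 17 significant pairs (FDR < 0.05), 8 SVs retained
targets: 17/17 scanned pairs predicted by seed match
enrichment: top category planted_targets (FDR 6.74e-14)
```

Reading it: 24 of the 35 QC-surviving miRNAs show a Ct-scale age slope at
the Bonferroni level (the generator planted effects in ~85% of them); the
elastic net selects 24 miRNAs and predicts age in the untouched
replication half at r = 0.69; the resulting Δage is partly heritable,
and each extra year of Δage multiplies the mortality hazard by ~1.11 —
the generator's planted hazard ratio is 1.10 per year of the latent aging
deviation, so the recovered association sits where it should. The top
ranked scan rows look like:

```
          mirna    beta     se     t        p r_squared    h2 significant     direction
1 miR-synth-004  0.1030 0.0112  9.17 4.94e-20     0.137 0.331        TRUE down-with-age
2 miR-synth-035 -0.0936 0.0102 -9.14 6.48e-20     0.136 0.217        TRUE   up-with-age
```

`beta` is Ct per year (positive = expression falling with age),
`r_squared` the partial r² for age, `h2` the miRNA's own polygenic
fraction.

Individual stages are plain functions returning classed objects —
`qc_filter()`, `diffexpr_scan()`, `split_by_pedigree()` +
`train_clock()` + `predict_age()` + `delta_age()`, `heritability()`,
`cox_fit()` / `km_by_groups()`, `trait_assoc_table()`,
`estimate_svs()` + `coexpression_scan()`, `seed_sites()` /
`seed_site_report()`, `fisher_enrichment()` — see the methods vignette
(`vignettes/mirclock-methods.Rmd`) for the models, assumptions and
parameter choices.

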
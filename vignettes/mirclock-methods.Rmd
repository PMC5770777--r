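---
title: "Methods: the miRNA aging clock pipeline and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miRNA aging clock pipeline and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirclock)
```

# The scientific problem

Whole-blood microRNA expression changes with age, and a sparse linear
combination of miRNA levels — a "miRNA age" — can predict chronological
age well enough that the residual, **delta age** (predicted minus
chronological age), behaves as a biomarker of accelerated biological
aging: it is partly heritable and associates with mortality and
cardiometabolic traits. mirclock implements the full analysis chain for
qPCR (cycle-threshold, Ct) miRNA panels measured in *family* cohorts,
where relatedness must enter every association model, and couples it to a
synthetic-cohort generator so that each stage can be validated against
known ground truth without access to restricted cohort data.

Throughout, note the Ct sign convention: lower Ct means higher
expression, so a *positive* Ct-per-year slope means expression *declines*
with age.

# Models and procedures

## Quality control of the Ct matrix

`qc_filter()` applies the panel's rules in a fixed order:

1. values at or above the detection limit (default Ct 27) are marked
   missing ("not expressed");
2. per-miRNA outliers at least 5 SD from the mean are marked missing; the
   mean and SD are computed *after* limit masking so censored values
   cannot inflate the SD (the order is a package decision — computing
   outlier statistics before masking would let the limit values mask real
   outliers);
3. miRNAs expressed in fewer than `min_expressed_frac` of samples are
   dropped (default 0.95, a cohort-size-free generalization of an
   absolute sample count);
4. samples with more than 10% missing values over the kept miRNAs are
   dropped;
5. remaining missing cells are filled with the limit value.

The outlier rule is two-sided; applying the filter to its own output
changes nothing (idempotence is a tested property).

## Technical normalization and standardized residuals

`technical_normalize()` regresses each miRNA on isolation batch
(categorical), RNA concentration, RNA integrity (RIN) and the 260/280
absorbance ratio, returning residuals and per-miRNA variance explained.
`standardized_residuals()` — the clock's input — residualizes on the
three continuous technical covariates plus sex and z-scores each column;
batch is deliberately *excluded* by default because profiling batches may
coincide with cohorts, and removing batch would then remove the age
signal itself. A flag restores batch adjustment.

## Kinship and the mixed model

`kinship_from_pedigree()` computes kinship coefficients by the standard
recursion (founders unrelated) and returns the expected additive
relationship `2*phi`, so the polygenic variance component is on the
additive scale. Because individuals in different pedigrees are unrelated,
the matrix is block diagonal; `kinship_eigen()` exploits this with
per-family eigendecompositions, which keeps mixed-model fits essentially
linear in sample size.

`reml_fit()` fits `y = Xb + g + e`, `g ~ N(0, sigma2_A K)`,
`e ~ N(0, sigma2_E I)` by rotating the data into the eigenbasis of `K`
and profiling the *restricted* likelihood over the heritability ratio
`h2 = sigma2_A / (sigma2_A + sigma2_E)` on `[0, 1)`: at each candidate
`h2` the fixed effects and total variance have closed generalized
least-squares forms. A 21-point coarse grid guards against local optima
before golden-section refinement (tolerance 1e-9); ties are broken toward
`h2 = 0`, i.e. toward the simpler independent-errors model, and at that
boundary the fit reproduces ordinary least squares exactly. REML (rather
than ML) matches standard variance-component practice. Wald p-values use
the normal approximation; t statistics and `n - p` residual df are also
reported. When `K` is proportional to the identity the two variance
components are not separately identifiable and the fit says so.
`heritability()` is a thin wrapper; its standard error comes from the
curvature of the profile restricted log-likelihood.

Why a mixed model at all: with a polygenic trait and a covariate that
itself aggregates in families, ordinary least squares is anticonservative
— the test suite demonstrates the inflation and the mixed model's
calibration side by side.

## The age scan and the clock

`diffexpr_scan()` fits one mixed model per miRNA (age tested; sex, batch
and technical covariates adjusted; optional imputed cell proportions as a
sensitivity mode) and applies a Bonferroni threshold `alpha / m` where
`m` is the number of miRNAs actually tested in the run — not a hard-coded
panel size. `partial_r2()` reports `t^2 / (t^2 + df)`, the symmetric
squared partial correlation; the package uses this definition for the
per-miRNA r² column since either regression direction gives the same
quantity.

`split_by_pedigree()` assigns whole pedigrees to discovery or replication
(greedy largest-first, ties seed-shuffled, each pedigree to the set with
the larger remaining deficit), so the two sets share no relatedness.

`train_clock()` uses the elastic net (glmnet) on standardized residuals
with mixing parameter `alpha = 0.5`. The penalty is either fixed by the
caller or selected by 10-fold cross-validation minimizing squared error;
CV folds are *pedigree-blocked* — a package decision, since letting
relatives straddle folds would leak family signal into the apparent CV
error. Because the numerical value of the penalty depends on the
implementation's loss scaling (documented in `?train_clock`, including
glmnet's internal response standardization, which divides the effective
ridge weight by the response SD), CV selection is the default and a fixed
penalty is available for protocol fidelity. Standardization parameters
are computed on the training set only and frozen into the prediction
path; predictions are a pure linear form of the stored coefficients.
`delta_age()` is the exact subtraction, with the correlation of delta age
against predicted age attached as a diagnostic.

## Survival and trait associations

`cox_fit()` wraps the proportional-hazards partial-likelihood fit (Efron
tie correction by default, Breslow optional) and returns hazard ratios
with 95% CIs; perfect separation is reported as an error instead of a
divergent estimate. The package checks its optimum against a brute-force
partial-likelihood grid search and a closed-form three-subject example in
the test suite. Plain Cox models are used (no familial frailty term);
this mirrors common practice for mortality analyses of this design and is
a documented simplification. `km_by_groups()` gives product-limit curves,
and `delta_age_tertiles()` cuts at the 1/3 and 2/3 sample quantiles with
boundary ties going to the lower tertile.

`trait_assoc()` regresses delta age on one trait at a time with age, sex
and BMI adjustment (BMI never adjusts itself) in a kinship mixed model,
after per-trait treatment exclusions: continuous cardiometabolic traits
in participants free of antihypertensive, lipid and antidiabetic
treatment; hypertension and diabetes status in those untreated for the
respective condition; prevalent coronary heart disease in everyone. The
panel-level wrapper applies a Bonferroni threshold of 0.05 over the
number of traits tested.

## Coexpression, surrogate variables, targets, enrichment

`estimate_svs()` builds surrogate variables as the top sample-space
singular vectors of the covariate-residualized mRNA matrix — a
deliberate, deterministic simplification of permutation-based surrogate
variable analysis — then retains only SVs associated with at least one
miRNA at the Bonferroni level, mirroring the retention filter used with
real shared-batch structure. `coexpression_scan()` fits one mixed model
per (miRNA, mRNA) pair with the mRNA as response (the direction is a
package decision), reusing one kinship eigendecomposition across all
pairs, and controls the false discovery rate by Benjamini–Hochberg across
the whole table. Because miRNA abundance is on the Ct scale, the reported
`expr_sign` flips the fitted slope's sign.

`seed_sites()` classifies canonical seed-match sites on the target's
sense strand only: the 6mer core is the reverse complement of miRNA
positions 2–7; extending by the complement of position 8 upstream gives
the 7mer-m8, by an A downstream (opposite position 1) the 7mer-A1, and by
both the 8mer. Every core occurrence is counted once under its most
specific type; overlapping occurrences are all found. Context scores,
conservation and 3'-supplementary pairing are out of scope. Per-region
counts are reported and the default predicted-target call requires at
least one non-6mer site in any region, leaving stricter aggregation to
the user.

`hypergeom_tail()` (log-scale upper tail), `fisher_enrichment()`
(one-sided exact tests per gene set with BH adjustment) and `bh_fdr()`
expose the enrichment statistics; the Fisher one-sided p equals the
hypergeometric tail on the same margins, an identity the tests exploit.

## Orchestration

`run_pipeline()` executes simulate → QC → scan → clock → delta age →
heritability → survival/traits → coexpression → targets → enrichment from
a single seeded configuration (R list or YAML) and collects one report;
stages toggle independently where the dependency graph allows.

# The synthetic cohort: what it emulates, and what it does not

`sim_params()` fixes the study conditions; the defaults are the
generator's definition of a realistic cohort of this design:

* **Families.** 300 nuclear pedigrees of 3–6 (two founders plus
  children), 15% extended to three generations; ~1,400 individuals at
  desk scale. Small pedigrees keep the kinship matrix block diagonal.
* **Two-cohort age structure.** 44% older cohort (mean 66, SD 9 years)
  and 56% younger (mean 46, SD 9), assigned per individual.
* **Latent aging deviation.** `delta` has SD 10 years and narrow-sense
  heritability 0.38 (polygenic within families). It drives mortality at
  log-hazard ln(1.10) per year, blood pressure (0.5 and 0.25 mmHg/year
  systolic/diastolic), glucose (0.5 mg/dL/year) and disease risks.
* **miRNA panel.** 150 miRNAs; ~85% carry a linear effect of *biological*
  age (chronological age + delta + shared "aging-program" noise, SD 8
  years in 2 programs) with |slope| uniform on 0.02–0.11 Ct/year, ~81% of
  them positive on the Ct scale (expression declining with age). The
  program noise is what bounds the age information jointly extractable
  from the panel: without it, 127 informative miRNAs with independent
  noise would predict age almost perfectly, which real panels do not.
  Per-miRNA biological SD is 2 Ct, of which 30% is polygenic and a shared
  non-age factor contributes 1 Ct²; technical covariates (50 batches
  nested in cohort by default, RNA concentration, RIN, 260/280) are
  scaled to explain 25–55% of raw variance per miRNA. Baselines sit at
  Ct 15–23 with 4% of miRNAs near the limit, yielding ~1% filled values
  among kept miRNAs after QC and a realistic handful of dropped panels.
* **mRNA and cells.** 300 transcripts; Dirichlet cell proportions times
  cell signatures, two latent factors (the first follows the shared
  isolation-batch structure, so surrogate variables genuinely associate
  with the miRNA panel), unit-SD noise, and 60 planted couplings of
  strength 0.6 log2 units per SD of the miRNA's *biological* signal —
  negative on the expression scale, as repression requires. Planting on
  the biological rather than observed signal reflects that measurement
  noise in the miRNA assay does not propagate into the target mRNA; the
  strength is calibrated once so planted couplings are recoverable at
  FDR 0.05 after realistic technical and surrogate-variable attenuation.
* **Survival.** Exponential hazards, baseline 0.006/year at the reference
  age of 55, log-hazard 0.085 per year of age, administrative censoring
  at 6 years.
* **Sequences.** Random 22-nt miRNAs; random-background 3'UTR/5'UTR/CDS
  regions (600/150/900 nt) with one 8mer site planted per coupled pair in
  the 3'UTR, coordinates recorded as ground truth.

Every generating quantity (per-miRNA slopes, heritabilities, technical
shares, the latent deviation, couplings, planted site coordinates) is
emitted alongside the data, which is what makes parameter-recovery
testing possible.

**What passing tests do and do not show.** The generator is linear and
Gaussian with exponential survival; real Ct data have
amplification-efficiency artefacts, plate effects beyond a single batch
factor, non-Gaussian tails, age-varying effect sizes across cohorts, and
miRNA–miRNA correlation structure richer than a few shared programs.
Recovery of planted parameters therefore validates the *estimators and
their calibration*, not the biological claims; on real data the same
pipeline inherits whatever confounding the design cannot remove (the
batch-within-cohort flag exists precisely to let users study that
failure mode — with batches nested in cohorts and no batch adjustment,
"null" miRNAs show genuinely confounded age associations, which is
demonstrated in the tests).

# Numerical choices

* Profile REML tolerance 1e-9 in `h2`; boundary tie broken toward 0;
  negative kinship eigenvalues clipped at 1e-8 with a warning; rank
  deficient fixed-effect designs drop aliased columns with a warning.
* Wald p-values are floored at the smallest positive double to keep them
  in `(0, 1]`.
* glmnet convergence threshold 1e-12 with exact refitting at the
  requested penalty; the soft-threshold and least-squares limits are
  verified to 1e-6.
* The hypergeometric tail is computed on the log scale, exact against
  rational enumeration for populations up to 60.
* Tertile boundaries are sample quantiles (type 7); boundary ties go to
  the lower tertile.
* Problem sizes in the test suite and acceptance script: recovery
  experiments use ~2,000 individuals (450 families) with 500 replicates
  for interval coverage and heritability, 30-miRNA panels for slope
  recovery, and the default desk-scale cohort (~1,400 individuals, 150
  miRNAs, 300 mRNAs) for the clock band; coexpression recovery uses 150
  families with a 15x40 panel. These sizes were chosen so each
  experiment's Monte-Carlo error is small relative to the tolerance it
  must meet.

# Known limitations

* One random effect only: no separate household or dominance components,
  no SNP-based relationship matrices, and no genome-wide association
  machinery (the mixed-model core is reusable for it).
* Cox models carry no familial frailty term.
* Surrogate variables come from a residual SVD, not the permutation-based
  dimension selection of the published SVA method.
* Seed matching implements canonical site classes only; no context
  scoring, so predicted targets are a superset of what a full target
  predictor would rank highly.
* The penalty value of a published elastic-net protocol is only
  meaningful relative to its implementation's loss scaling; reproducing a
  literal penalty value therefore requires the fixed-lambda mode and the
  same software conventions.
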
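#' Parameters for the synthetic family-cohort generator
#'
#' Bundles every knob of the generator with defaults calibrated to the
#' two-cohort whole-blood study design the package targets: an older cohort
#' (mean 66, SD 9 years) and a younger one (mean 46, SD 9) mixed roughly
#' 44:56, nuclear families of 3-6, a 150-miRNA Ct panel in which ~85% of
#' miRNAs have a linear age effect (mostly with expression declining in
#' older individuals, i.e. positive Ct-scale slope), technical covariates
#' explaining 25-55% of raw Ct variance, detection censoring at Ct 27, a
#' latent aging deviation ("delta") with narrow-sense heritability 0.38
#' driving mortality (log-hazard 0.0953 per year, hazard ratio 1.10) and
#' cardiometabolic traits, and miRNA-coupled mRNA expression with latent
#' batch factors and blood-cell-mixture structure.
#'
#' @param n_families number of pedigrees.
#' @param family_sizes vector of possible family sizes (2 founders plus
#'   1-4 children by default), sampled uniformly.
#' @param extension_prob probability that a family is extended to three
#'   generations (one child gains a spouse and a grandchild).
#' @param cohort_frac_old fraction of individuals in the older cohort.
#' @param age_mean_old,age_sd_old,age_mean_young,age_sd_young age mixture.
#' @param n_mirna panel size.
#' @param frac_age_affected fraction of miRNAs with a true age effect.
#' @param frac_negative_assoc among affected miRNAs, fraction whose
#'   expression falls with age (positive Ct slope).
#' @param beta_age_range range of |Ct per year| effect sizes.
#' @param mirna_h2 polygenic share of each miRNA's biological variance.
#' @param mirna_bio_sd residual (non-technical) Ct SD per miRNA.
#' @param n_programs,program_sd shared "aging-program" noise: affected
#'   miRNAs respond to biological age = age + delta + program noise, the
#'   program noise (SD in years) being shared within `n_programs` groups.
#'   This caps the age information jointly carried by the panel, emulating
#'   the strong cross-correlation of real miRNA panels.
#' @param n_mirna_factors,mirna_factor_sd latent non-age factors shared
#'   across miRNAs (Ct units).
#' @param tech_frac_range per-miRNA fraction of raw Ct variance explained
#'   by technical covariates (batch, RNA concentration, RIN, 260/280),
#'   drawn uniformly from this range.
#' @param n_batches number of isolation batches.
#' @param confound_batch_cohort if `TRUE` batches are nested within cohort.
#' @param detection_limit Ct detection limit; values at or above are
#'   recorded as missing.
#' @param baseline_range,near_limit_frac,near_limit_range baseline Ct
#'   levels; a small fraction of miRNAs sit near the detection limit so the
#'   generator produces a realistically small share of censored values.
#' @param delta_sd,delta_h2 SD (years) and heritability of the latent aging
#'   deviation.
#' @param n_mrna,n_coupled_pairs,coupling_strength mRNA panel size, number
#'   of planted miRNA->mRNA couplings, and their log2-per-Ct-SD strength
#'   (positive on the Ct scale = negative on the expression scale).
#' @param n_cell_types,n_mrna_factors,mrna_factor_sd,mrna_noise_sd cell
#'   mixture and latent factor structure of the mRNA matrix.
#' @param baseline_hazard,followup_years,log_hr_delta,log_hr_age survival
#'   generator: exponential baseline hazard per year at the reference age
#'   (55), administrative censoring horizon, log-hazard per year of latent
#'   delta and per year of age.
#' @param sbp_delta,dbp_delta,glucose_delta trait effects per year of
#'   latent delta.
#' @param utr3_len,utr5_len,cds_len transcript region lengths for the
#'   sequence generator.
#' @param rng_seed integer seed; every generator stage derives its stream
#'   from it, so identical parameters give identical cohorts.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_families = 300,
                       family_sizes = 3:6,
                       extension_prob = 0.15,
                       cohort_frac_old = 0.44,
                       age_mean_old = 66, age_sd_old = 9,
                       age_mean_young = 46, age_sd_young = 9,
                       n_mirna = 150,
                       frac_age_affected = 127 / 150,
                       frac_negative_assoc = 103 / 127,
                       beta_age_range = c(0.02, 0.11),
                       mirna_h2 = 0.30,
                       mirna_bio_sd = 2.0,
                       n_programs = 2,
                       program_sd = 8,
                       n_mirna_factors = 3,
                       mirna_factor_sd = 1.0,
                       tech_frac_range = c(0.25, 0.55),
                       n_batches = 50,
                       confound_batch_cohort = TRUE,
                       detection_limit = 27,
                       baseline_range = c(15, 23),
                       near_limit_frac = 0.04,
                       near_limit_range = c(25, 26.5),
                       delta_sd = 10,
                       delta_h2 = 0.38,
                       n_mrna = 300,
                       n_coupled_pairs = 60,
                       coupling_strength = 0.6,
                       n_cell_types = 4,
                       n_mrna_factors = 2,
                       mrna_factor_sd = 0.6,
                       mrna_noise_sd = 1.0,
                       baseline_hazard = 0.006,
                       followup_years = 6,
                       log_hr_delta = log(1.10),
                       log_hr_age = 0.085,
                       sbp_delta = 0.5,
                       dbp_delta = 0.25,
                       glucose_delta = 0.5,
                       utr3_len = 600,
                       utr5_len = 150,
                       cds_len = 900,
                       rng_seed = 20160512) {
  p <- as.list(environment())
  fracs <- c(p$cohort_frac_old, p$frac_age_affected, p$frac_negative_assoc,
             p$near_limit_frac, p$extension_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$mirna_h2 < 0 || p$mirna_h2 >= 1 || p$delta_h2 < 0 || p$delta_h2 >= 1)
    stop("heritabilities must lie in [0, 1)")
  counts <- c(p$n_families, p$n_mirna, p$n_mrna, p$n_batches)
  if (any(counts < 1)) stop("counts must be positive")
  if (any(p$family_sizes < 1)) stop("invalid family-size distribution")
  if (p$detection_limit < 10 || p$detection_limit > 40)
    stop("detection limit outside the plausible Ct range (10-40)")
  if (p$n_coupled_pairs > p$n_mrna)
    stop("n_coupled_pairs must not exceed n_mrna ",
         "(each mRNA is targeted by at most one planted coupling)")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters:\n")
  cat(sprintf("  %d families (sizes %s), cohort mix %.0f%% old (%g+/-%g) / %.0f%% young (%g+/-%g)\n",
              x$n_families, paste(range(x$family_sizes), collapse = "-"),
              100 * x$cohort_frac_old, x$age_mean_old, x$age_sd_old,
              100 * (1 - x$cohort_frac_old), x$age_mean_young, x$age_sd_young))
  cat(sprintf("  %d miRNAs (%.0f%% age-affected), %d mRNAs (%d couplings), limit Ct %g\n",
              x$n_mirna, 100 * x$frac_age_affected, x$n_mrna,
              x$n_coupled_pairs, x$detection_limit))
  cat(sprintf("  latent delta: SD %g y, h2 %.2f; mortality log-HR %.4f/y over %g y\n",
              x$delta_sd, x$delta_h2, x$log_hr_delta, x$followup_years))
  invisible(x)
}

#' Simulate pedigrees
#'
#' Families are nuclear (two founders plus children drawn from the size
#' distribution); with probability `extension_prob` a family is extended to
#' three generations by marrying one child to a new founder and adding a
#' grandchild. Deterministic given `params$rng_seed`.
#'
#' @param params [sim_params()] object.
#' @return pedigree data.frame (`pedigree_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`; founder marker `"0"`).
#' @export
simulate_pedigrees <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed + 1L, {
    rows <- vector("list", params$n_families)
    for (f in seq_len(params$n_families)) {
      fid <- sprintf("F%04d", f)
      size <- sample(params$family_sizes, 1)
      n_children <- max(1L, size - 2L)
      dad <- sprintf("%s_I1", fid); mom <- sprintf("%s_I2", fid)
      recs <- list(
        c(fid, dad, "0", "0", "male"),
        c(fid, mom, "0", "0", "female"))
      kid_sex <- sample(c("male", "female"), n_children, replace = TRUE)
      kids <- sprintf("%s_I%d", fid, 2L + seq_len(n_children))
      for (k in seq_len(n_children))
        recs[[length(recs) + 1L]] <- c(fid, kids[k], dad, mom, kid_sex[k])
      if (stats::runif(1) < params$extension_prob) {
        k <- sample.int(n_children, 1)
        spouse_sex <- if (kid_sex[k] == "male") "female" else "male"
        spouse <- sprintf("%s_S%d", fid, k)
        gkid <- sprintf("%s_G%d", fid, k)
        recs[[length(recs) + 1L]] <- c(fid, spouse, "0", "0", spouse_sex)
        fa <- if (kid_sex[k] == "male") kids[k] else spouse
        mo <- if (kid_sex[k] == "male") spouse else kids[k]
        recs[[length(recs) + 1L]] <-
          c(fid, gkid, fa, mo, sample(c("male", "female"), 1))
      }
      rows[[f]] <- do.call(rbind, recs)
    }
    ped <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(ped) <- c("pedigree_id", "individual_id", "father_id",
                    "mother_id", "sex")
    validate_pedigree(ped)
    ped
  })
}

# Draw a polygenic vector with Var = h2 * sd2 * K, block-wise by pedigree.
.polygenic_draw <- function(ped, sd_total, h2) {
  ids <- ped$individual_id
  g <- stats::setNames(numeric(length(ids)), ids)
  if (h2 <= 0 || sd_total <= 0) return(g)
  for (fid in unique(ped$pedigree_id)) {
    sub <- ped[ped$pedigree_id == fid, , drop = FALSE]
    Kb <- kinship_from_pedigree(sub)
    L <- chol(Kb + diag(1e-10, nrow(Kb)))
    g[sub$individual_id] <-
      drop(crossprod(L, stats::rnorm(nrow(sub)))) * sd_total * sqrt(h2)
  }
  g
}

#' Simulate phenotypes, the latent aging deviation, survival and traits
#'
#' Ages are drawn from the two-cohort mixture (cohort assigned per
#' individual). The latent aging deviation `delta` is polygenic with
#' heritability `delta_h2` (kinship-correlated within families) plus an
#' independent environmental part. Technical covariates are independent of
#' age; traits are linear (or logistic, for disease status) in age and
#' delta plus noise; survival times are exponential with log-hazard linear
#' in age and delta and administrative censoring at the follow-up horizon.
#' The generating delta is attached as attribute `"truth"` and also
#' returned in the column `delta_true` of the truth table written by
#' [write_cohort()].
#'
#' @param ped pedigree from [simulate_pedigrees()].
#' @param params [sim_params()] object.
#' @return phenotype data.frame, one row per individual, with attribute
#'   `"truth"` (list with `delta`).
#' @export
simulate_phenotypes <- function(ped, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_pedigree(ped)
  with_seed(params$rng_seed + 2L, {
    n <- nrow(ped)
    ids <- ped$individual_id
    old <- stats::runif(n) < params$cohort_frac_old
    age <- ifelse(old,
                  stats::rnorm(n, params$age_mean_old, params$age_sd_old),
                  stats::rnorm(n, params$age_mean_young, params$age_sd_young))
    age <- pmax(age, 20)
    cohort <- ifelse(old, "old", "young")
    # latent aging deviation: polygenic + environmental
    g <- .polygenic_draw(ped, params$delta_sd, params$delta_h2)
    delta <- g + stats::rnorm(n, 0, params$delta_sd *
                                sqrt(1 - params$delta_h2))
    # technical covariates, independent of age
    if (params$confound_batch_cohort) {
      n_old_b <- max(1L, round(params$n_batches * params$cohort_frac_old))
      batch <- integer(n)
      batch[old] <- sample.int(n_old_b, sum(old), replace = TRUE)
      batch[!old] <- n_old_b +
        sample.int(max(1L, params$n_batches - n_old_b), sum(!old),
                   replace = TRUE)
    } else {
      batch <- sample.int(params$n_batches, n, replace = TRUE)
    }
    rna_concentration <- stats::rlnorm(n, log(50), 0.4)
    rin <- pmin(10, pmax(5, stats::rnorm(n, 8, 0.7)))
    ratio_260_280 <- stats::rnorm(n, 1.9, 0.08)
    sex <- ped$sex
    male <- as.integer(sex == "male")
    a55 <- age - 55
    bmi <- stats::rnorm(n, 28, 5.5)
    sbp <- 95 + 0.55 * age + params$sbp_delta * delta + stats::rnorm(n, 0, 12)
    dbp <- 65 + 0.12 * age + params$dbp_delta * delta + stats::rnorm(n, 0, 8)
    glucose <- 75 + 0.45 * age + params$glucose_delta * delta +
      stats::rnorm(n, 0, 15)
    total_cholesterol <- 150 + 0.55 * age + stats::rnorm(n, 0, 33)
    hdl <- 62 - 3 * male + stats::rnorm(n, 0, 17)
    triglycerides <- pmax(30, 80 + 0.55 * age + stats::rnorm(n, 0, 60))
    smoker <- stats::rbinom(n, 1, stats::plogis(-1.4 - 0.05 * a55))
    chd <- stats::rbinom(n, 1, stats::plogis(-3.6 + 0.085 * a55 +
                                               0.10 * delta + 0.4 * male))
    hypertension <- as.integer(sbp >= 140 | dbp >= 90)
    diabetes <- stats::rbinom(n, 1, stats::plogis(-3.2 + 0.06 * a55 +
                                                    0.05 * delta +
                                                    0.05 * (bmi - 28)))
    rx_htn <- as.integer(hypertension == 1 & stats::runif(n) < 0.75)
    hypertension <- as.integer(hypertension == 1 | rx_htn == 1)
    rx_dm <- as.integer(diabetes == 1 & stats::runif(n) < 0.6)
    rx_lipid <- stats::rbinom(n, 1, stats::plogis(-2.5 + 0.07 * a55))
    # survival: exponential PH, administrative censoring
    lam <- params$baseline_hazard *
      exp(params$log_hr_age * a55 + params$log_hr_delta * delta)
    t_event <- stats::rexp(n, rate = lam)
    surv_event <- as.integer(t_event <= params$followup_years)
    surv_time <- pmin(t_event, params$followup_years)
    phen <- data.frame(
      sample_id = ids, pedigree_id = ped$pedigree_id, cohort = cohort,
      age = age, sex = sex, batch = factor(batch),
      rna_concentration = rna_concentration, rin = rin,
      ratio_260_280 = ratio_260_280,
      sbp = sbp, dbp = dbp, glucose = glucose, bmi = bmi,
      total_cholesterol = total_cholesterol, hdl = hdl,
      triglycerides = triglycerides, smoker = smoker,
      chd = chd, hypertension = hypertension, diabetes = diabetes,
      rx_htn = rx_htn, rx_dm = rx_dm, rx_lipid = rx_lipid,
      surv_time = surv_time, surv_event = surv_event,
      stringsAsFactors = FALSE)
    attr(phen, "truth") <- list(delta = stats::setNames(delta, ids))
    phen
  })
}

#' Simulate the miRNA Ct matrix
#'
#' Each miRNA's Ct value is baseline + age effect + sex effect + technical
#' effects + shared latent factors + polygenic term + noise. Age-affected
#' miRNAs respond to *biological* age (chronological age + latent delta +
#' shared aging-program noise), so an age clock trained on the panel
#' inherits the latent deviation. Technical effects are scaled per miRNA so
#' they explain a target fraction of raw variance. Values at or above the
#' detection limit are recorded as `NA` (not expressed). Generating
#' parameters are attached as attribute `"truth"`:
#' `beta_age` (Ct per year; positive = expression declining with age),
#' `affected`, `h2` (polygenic share of biological variance),
#' `tech_frac`, and `baseline`.
#'
#' @param ped pedigree.
#' @param phen phenotypes from [simulate_phenotypes()] (must cover all
#'   pedigree members).
#' @param params [sim_params()] object.
#' @return Ct matrix (samples x miRNAs, `NA` = not expressed) with
#'   attributes `"truth"` and `"detection_limit"`.
#' @export
simulate_mirna_ct <- function(ped, phen, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!all(ped$individual_id %in% phen$sample_id))
    stop("phenotypes do not cover all pedigree members")
  phen <- phen[match(ped$individual_id, phen$sample_id), ]
  with_seed(params$rng_seed + 3L, {
    n <- nrow(ped); m <- params$n_mirna
    mirna_ids <- sprintf("miR-synth-%03d", seq_len(m))
    truth_delta <- attr(phen, "truth")$delta
    if (is.null(truth_delta)) truth_delta <- rep(0, n)
    affected <- stats::runif(m) < params$frac_age_affected
    sign_pos <- stats::runif(m) < params$frac_negative_assoc  # Ct slope > 0
    beta <- stats::runif(m, params$beta_age_range[1], params$beta_age_range[2]) *
      ifelse(sign_pos, 1, -1) * as.numeric(affected)
    near <- stats::runif(m) < params$near_limit_frac
    baseline <- ifelse(near,
                       stats::runif(m, params$near_limit_range[1],
                                    params$near_limit_range[2]),
                       stats::runif(m, params$baseline_range[1],
                                    params$baseline_range[2]))
    program <- sample.int(max(1L, params$n_programs), m, replace = TRUE)
    u <- matrix(stats::rnorm(n * max(1L, params$n_programs), 0,
                             params$program_sd),
                n, max(1L, params$n_programs))
    fac <- matrix(stats::rnorm(n * params$n_mirna_factors), n,
                  params$n_mirna_factors)
    load <- matrix(stats::rnorm(params$n_mirna_factors * m, 0,
                                params$mirna_factor_sd /
                                  sqrt(max(1, params$n_mirna_factors))),
                   params$n_mirna_factors, m)
    sex_eff <- stats::rnorm(m, 0, 0.1)
    male <- as.numeric(phen$sex == "male")
    # technical component, standardized pieces
    zconc <- scale(log(phen$rna_concentration))[, 1]
    zrin <- scale(phen$rin)[, 1]
    zratio <- scale(phen$ratio_260_280)[, 1]
    batch_f <- factor(phen$batch)
    tech_frac <- stats::runif(m, params$tech_frac_range[1],
                              params$tech_frac_range[2])
    h2 <- rep(params$mirna_h2, m)
    # affected miRNAs pick up their program's noise, scaled by their slope
    prog_term <- sweep(u[, program, drop = FALSE], 2, beta, `*`)
    # baseline is the Ct at the reference age (55); affected miRNAs track
    # biological age = age + delta (plus their program's shared noise)
    ct <- matrix(baseline, n, m, byrow = TRUE) +
      outer(phen$age - 55 + truth_delta, beta) + prog_term +
      outer(male, sex_eff) + fac %*% load
    sd_noise <- params$mirna_bio_sd *
      sqrt(pmax(1e-8, 1 - h2 - (params$mirna_factor_sd /
                                  params$mirna_bio_sd)^2))
    for (j in seq_len(m)) {
      gj <- .polygenic_draw(ped, params$mirna_bio_sd, h2[j])
      ct[, j] <- ct[, j] + gj[ped$individual_id] +
        stats::rnorm(n, 0, sd_noise[j])
    }
    bio <- ct  # biological signal before technical effects and censoring
    # technical effects scaled to the target variance share, per miRNA
    bcoef <- stats::rnorm(nlevels(batch_f))
    zbatch <- scale(bcoef[as.integer(batch_f)])[, 1]
    wt <- matrix(stats::rnorm(4 * m), 4, m)
    wt <- sweep(wt, 2, sqrt(colSums(wt^2)), `/`)
    techbase <- cbind(zbatch, zconc, zrin, zratio) %*% wt
    v_bio <- apply(ct, 2, stats::var)
    v_tech_target <- tech_frac / (1 - tech_frac) * v_bio
    tech <- sweep(techbase, 2,
                  sqrt(v_tech_target / apply(techbase, 2, stats::var)), `*`)
    ct <- ct + tech
    dimnames(ct) <- list(ped$individual_id, mirna_ids)
    dimnames(bio) <- dimnames(ct)
    ct[ct >= params$detection_limit] <- NA
    structure(ct,
              truth = list(bio = bio,
                           beta_age = stats::setNames(beta, mirna_ids),
                           affected = stats::setNames(affected, mirna_ids),
                           h2 = stats::setNames(h2, mirna_ids),
                           tech_frac = stats::setNames(tech_frac, mirna_ids),
                           baseline = stats::setNames(baseline, mirna_ids),
                           program = stats::setNames(program, mirna_ids)),
              detection_limit = params$detection_limit)
  })
}

#' Simulate mRNA expression and cell proportions
#'
#' mRNA log2 values are a cell-mixture signal (Dirichlet proportions times
#' cell-type signatures) plus latent batch factors plus, for designated
#' target pairs, a term coupled to miRNA expression (positive on the Ct
#' scale, i.e. negative on the expression scale) plus noise.
#'
#' @param ct Ct matrix from [simulate_mirna_ct()] (missing values are
#'   mean-imputed internally before coupling).
#' @param params [sim_params()] object.
#' @param coupling optional data.frame (`mirna`, `mrna`, `strength`) to
#'   override the randomly drawn coupling map; `mirna` ids must exist.
#' @param phen optional phenotype table; when supplied, the first latent
#'   mRNA factor is a per-batch shift shared with the miRNA panel's batch
#'   structure (so surrogate variables estimated from mRNA are genuinely
#'   associated with miRNA measurements, as in real shared-batch designs).
#' @return list with `mrna` (samples x mRNAs), `cells` (samples x cell
#'   types, rows summing to 1), `coupling` (data.frame of planted pairs).
#' @export
simulate_mrna_and_cells <- function(ct, params, coupling = NULL,
                                    phen = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed + 4L, {
    n <- nrow(ct); G <- params$n_mrna
    mrna_ids <- sprintf("mRNA-synth-%04d", seq_len(G))
    if (is.null(coupling)) {
      pairs <- cbind(sample.int(ncol(ct), params$n_coupled_pairs,
                                replace = TRUE),
                     sample.int(G, params$n_coupled_pairs))
      pairs <- pairs[!duplicated(pairs[, 2]), , drop = FALSE]
      coupling <- data.frame(mirna = colnames(ct)[pairs[, 1]],
                             mrna = mrna_ids[pairs[, 2]],
                             strength = params$coupling_strength,
                             stringsAsFactors = FALSE)
    } else {
      if (!all(coupling$mirna %in% colnames(ct)))
        stop("coupling refers to unknown miRNA id(s): ",
             paste(setdiff(coupling$mirna, colnames(ct)), collapse = ", "))
      if (is.null(coupling$strength))
        coupling$strength <- params$coupling_strength
    }
    C <- params$n_cell_types
    cells <- matrix(stats::rgamma(n * C, shape = 2), n, C)
    cells <- cells / rowSums(cells)
    dimnames(cells) <- list(rownames(ct),
                            sprintf("cell_%d", seq_len(C)))
    sig <- matrix(stats::rnorm(C * G, 0, 2), C, G)
    fac <- matrix(stats::rnorm(n * params$n_mrna_factors), n,
                  params$n_mrna_factors)
    if (!is.null(phen)) {
      b <- factor(phen$batch[match(rownames(ct), phen$sample_id)])
      fac[, 1] <- scale(stats::rnorm(nlevels(b))[as.integer(b)])[, 1]
    }
    load <- matrix(stats::rnorm(params$n_mrna_factors * G, 0,
                                params$mrna_factor_sd),
                   params$n_mrna_factors, G)
    mrna <- 8 + cells %*% sig + fac %*% load +
      matrix(stats::rnorm(n * G, 0, params$mrna_noise_sd), n, G)
    dimnames(mrna) <- list(rownames(ct), mrna_ids)
    if (nrow(coupling)) {
      # targets respond to the miRNA's true (biological) abundance when the
      # generator recorded it; observed Ct (mean-imputed) is the fallback
      ctf <- attr(ct, "truth")$bio
      if (is.null(ctf)) {
        ctf <- ct
        for (j in seq_len(ncol(ctf))) {
          cj <- ctf[, j]
          cj[is.na(cj)] <- mean(cj, na.rm = TRUE)
          ctf[, j] <- cj
        }
      }
      for (r in seq_len(nrow(coupling))) {
        x <- scale(ctf[, coupling$mirna[r]])[, 1]
        gi <- match(coupling$mrna[r], mrna_ids)
        if (is.na(gi)) stop("coupling refers to unknown mRNA id: ",
                            coupling$mrna[r])
        mrna[, gi] <- mrna[, gi] + coupling$strength[r] * x
      }
    }
    list(mrna = mrna, cells = cells, coupling = coupling,
         factors = fac)
  })
}

#' Simulate miRNA and transcript-region sequences
#'
#' Generates random mature miRNA sequences (RNA alphabet, 22 nt) and
#' random-background transcript regions (3UTR, 5UTR, CDS per mRNA). For
#' every coupled ("target") pair an 8mer seed-match site is planted in the
#' transcript's 3UTR; planted coordinates (0-based, half-open) are returned
#' as ground truth. Deterministic given `params$rng_seed`.
#'
#' @param params [sim_params()] object.
#' @param coupling coupling data.frame (`mirna`, `mrna`).
#' @param mirna_ids,mrna_ids id vectors (defaults match the generator's).
#' @return list with `mirna_fasta` (named RNA strings), `region_fasta`
#'   (named DNA strings, headers `transcript|region`), `planted`
#'   (data.frame mirna, transcript, region, start, end).
#' @export
simulate_sequences <- function(params, coupling,
                               mirna_ids = sprintf("miR-synth-%03d",
                                                   seq_len(params$n_mirna)),
                               mrna_ids = sprintf("mRNA-synth-%04d",
                                                  seq_len(params$n_mrna))) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed + 5L, {
    rna <- c("A", "C", "G", "U"); dna <- c("A", "C", "G", "T")
    mir <- vapply(mirna_ids, function(id)
      paste(sample(rna, 22, replace = TRUE), collapse = ""), character(1))
    lens <- c(`3UTR` = params$utr3_len, `5UTR` = params$utr5_len,
              CDS = params$cds_len)
    regions <- list()
    for (tid in mrna_ids)
      for (rg in names(lens))
        regions[[paste0(tid, "|", rg)]] <-
          paste(sample(dna, lens[[rg]], replace = TRUE), collapse = "")
    planted <- NULL
    if (!is.null(coupling) && nrow(coupling)) {
      bad <- setdiff(coupling$mrna, mrna_ids)
      if (length(bad))
        stop("coupling refers to transcript(s) without sequences: ",
             paste(utils::head(bad, 3), collapse = ", "))
      if (!all(coupling$mirna %in% names(mir)))
        stop("coupling refers to miRNA(s) without sequences")
      rows <- vector("list", nrow(coupling))
      for (r in seq_len(nrow(coupling))) {
        ms <- mir[[coupling$mirna[r]]]
        site <- paste0(.revcomp_dna(chartr("U", "T", substr(ms, 2, 8))), "A")
        key <- paste0(coupling$mrna[r], "|3UTR")
        tgt <- regions[[key]]
        pos <- sample.int(nchar(tgt) - nchar(site) + 1L, 1)
        substr(tgt, pos, pos + nchar(site) - 1L) <- site
        regions[[key]] <- tgt
        rows[[r]] <- data.frame(mirna = coupling$mirna[r],
                                transcript = coupling$mrna[r],
                                region = "3UTR",
                                start = pos - 1L,
                                end = pos - 1L + nchar(site),
                                stringsAsFactors = FALSE)
      }
      planted <- do.call(rbind, rows)
    }
    list(mirna_fasta = mir, region_fasta = unlist(regions),
         planted = planted)
  })
}

#' Simulate a complete cohort
#'
#' Orchestrates [simulate_pedigrees()], [simulate_phenotypes()],
#' [simulate_mirna_ct()], [simulate_mrna_and_cells()] and
#' [simulate_sequences()] and collects all generating ground truths.
#'
#' @param params [sim_params()] object.
#' @param sequences if `FALSE`, skip the sequence generator.
#' @return object of class `mir_cohort`: list with `ped`, `phen`, `ct`,
#'   `mrna`, `cells`, `coupling`, `sequences`, `truth`, `params`.
#' @export
simulate_cohort <- function(params = sim_params(), sequences = TRUE) {
  ped <- simulate_pedigrees(params)
  phen <- simulate_phenotypes(ped, params)
  ct <- simulate_mirna_ct(ped, phen, params)
  mr <- simulate_mrna_and_cells(ct, params, phen = phen)
  seqs <- if (sequences) simulate_sequences(params, mr$coupling) else NULL
  truth <- c(attr(phen, "truth"), attr(ct, "truth"),
             list(coupling = mr$coupling, planted_sites = seqs$planted,
                  cells = mr$cells))
  structure(list(ped = ped, phen = phen, ct = ct, mrna = mr$mrna,
                 cells = mr$cells, coupling = mr$coupling,
                 sequences = seqs, truth = truth, params = params),
            class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals in %d pedigrees\n",
              nrow(x$ped), length(unique(x$ped$pedigree_id))))
  cat(sprintf("  Ct panel: %d miRNAs (%.2f%% values censored at Ct %g)\n",
              ncol(x$ct), 100 * mean(is.na(x$ct)),
              attr(x$ct, "detection_limit")))
  cat(sprintf("  mRNA panel: %d transcripts, %d planted couplings\n",
              ncol(x$mrna), nrow(x$coupling)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the phenotype, Ct, mRNA, pedigree and kinship TSVs, miRNA and
#' region FASTAs, and a ground-truth TSV of per-miRNA generating
#' parameters plus the per-sample latent deviation.
#'
#' @param cohort `mir_cohort` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree_tsv(cohort$ped, file.path(dir, "pedigree.tsv"))
  write_phenotypes_tsv(cohort$phen, file.path(dir, "phenotypes.tsv"))
  write_matrix_tsv(cohort$ct, file.path(dir, "mirna_ct.tsv"))
  write_matrix_tsv(cohort$mrna, file.path(dir, "mrna_log2.tsv"))
  write_matrix_tsv(cohort$cells, file.path(dir, "cell_proportions.tsv"))
  tr <- cohort$truth
  truth_mir <- data.frame(mirna = names(tr$beta_age),
                          beta_age = tr$beta_age,
                          affected = as.integer(tr$affected),
                          h2 = tr$h2, tech_frac = tr$tech_frac,
                          baseline = tr$baseline, row.names = NULL)
  utils::write.table(truth_mir, file.path(dir, "truth_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(tr$delta),
                                delta_true = tr$delta, row.names = NULL),
                     file.path(dir, "truth_delta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$coupling, file.path(dir, "truth_coupling.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$sequences)) {
    write_fasta(cohort$sequences$mirna_fasta, file.path(dir, "mirna.fa"))
    write_fasta(cohort$sequences$region_fasta, file.path(dir, "regions.fa"))
    if (!is.null(cohort$sequences$planted))
      utils::write.table(cohort$sequences$planted,
                         file.path(dir, "truth_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
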
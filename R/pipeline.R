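#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]: generator
#' parameters, stage toggles and stage parameters. Override entries via
#' `...` (nested lists are merged shallowly per stage).
#'
#' @param ... named overrides, e.g. `stages = list(coexpression = FALSE)`
#'   or `sim = list(n_families = 100)`.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(),                 # overrides for sim_params()
    stages = list(qc = TRUE, diffexpr = TRUE, clock = TRUE,
                  heritability = TRUE, survival = TRUE, traits = TRUE,
                  coexpression = TRUE, targets = TRUE, enrichment = TRUE),
    qc = list(limit = 27, outlier_sd = 5, min_expressed_frac = 0.95,
              max_sample_missing_frac = 0.10),
    diffexpr = list(alpha = 0.05,
                    covariates = c("sex", "batch", "rna_concentration",
                                   "rin", "ratio_260_280")),
    clock = list(alpha_mix = 0.5, lambda = NULL, folds = 10, ratio = 0.5),
    coexpression = list(n_sv = 10, fdr = 0.05),
    out_dir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order -- simulate, QC,
#' normalization, per-miRNA age scan, clock training/prediction and delta
#' age, delta-age heritability, survival and trait associations,
#' surrogate-variable-adjusted coexpression, seed-match target prediction
#' and gene-set enrichment -- and collects a single report. Every random
#' operation is seeded from `config$seed`, so identical configurations
#' give identical reports. When `config$out_dir` is set, the cohort and
#' the main result tables are written there as TSVs.
#'
#' @param config list from [pipeline_config()] (or a YAML path).
#' @return list of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- config$stages
  report <- list(config = config)
  params <- do.call(sim_params,
                    c(config$sim,
                      if (is.null(config$sim$rng_seed))
                        list(rng_seed = config$seed)))
  cohort <- simulate_cohort(params)
  report$cohort <- list(n = nrow(cohort$ped),
                        n_pedigrees = length(unique(cohort$ped$pedigree_id)),
                        n_mirna = ncol(cohort$ct),
                        n_mrna = ncol(cohort$mrna),
                        censored_frac = mean(is.na(cohort$ct)))
  K <- kinship_from_pedigree(cohort$ped)
  phen <- cohort$phen
  # --- QC ---------------------------------------------------------------
  if (isTRUE(stages$qc)) {
    qc <- do.call(qc_filter, c(list(ct = cohort$ct), config$qc))
    report$qc <- qc$report
    ct <- qc$ct
  } else ct <- cohort$ct
  phen <- phen[match(rownames(ct), phen$sample_id), ]
  Kct <- K[rownames(ct), rownames(ct)]
  attr(Kct, "blocks") <- attr(K, "blocks")[rownames(ct)]
  class(Kct) <- class(K)
  Ect <- kinship_eigen(Kct)
  # --- differential expression -----------------------------------------
  if (isTRUE(stages$diffexpr)) {
    de <- diffexpr_scan(ct, phen, Ect,
                        covariates = config$diffexpr$covariates,
                        alpha = config$diffexpr$alpha)
    report$diffexpr <- de
  }
  # --- clock + delta age ------------------------------------------------
  delta_tab <- NULL
  if (isTRUE(stages$clock)) {
    resid <- standardized_residuals(ct, phen)
    split <- split_by_pedigree(cohort$ped[cohort$ped$individual_id %in%
                                            rownames(ct), ],
                               ratio = config$clock$ratio,
                               seed = config$seed)
    disc <- split$individual_id[split$set == "discovery"]
    repl <- split$individual_id[split$set == "replication"]
    # re-standardize within the training set only (no test-set leakage)
    tr_raw <- resid[disc, , drop = FALSE]
    mu <- colMeans(tr_raw); sdv <- apply(tr_raw, 2, stats::sd)
    tr <- scale(tr_raw, center = mu, scale = sdv)
    te <- scale(resid[repl, , drop = FALSE], center = mu, scale = sdv)
    ages <- stats::setNames(phen$age, phen$sample_id)
    clock <- train_clock(tr, ages[disc],
                         alpha_mix = config$clock$alpha_mix,
                         lambda = config$clock$lambda,
                         folds = config$clock$folds, seed = config$seed,
                         pedigree_id = split$pedigree_id[split$set ==
                                                           "discovery"])
    pred_disc <- predict_age(clock, tr, ages[disc])
    pred_repl <- predict_age(clock, te, ages[repl])
    delta_tab <- delta_age(c(pred_disc, pred_repl),
                           ages[c(disc, repl)])
    report$clock <- list(model = clock,
                         r_discovery = attr(pred_disc, "cor"),
                         r_replication = attr(pred_repl, "cor"),
                         n_discovery = length(disc),
                         n_replication = length(repl),
                         delta = delta_tab)
  }
  # --- heritability of delta age ---------------------------------------
  if (isTRUE(stages$heritability) && !is.null(delta_tab)) {
    dvec <- stats::setNames(delta_tab$delta_age, delta_tab$sample_id)
    covs <- cbind(age = phen$age,
                  sex = as.integer(phen$sex == "male"))
    rownames(covs) <- phen$sample_id
    h <- heritability(dvec[rownames(ct)], covs[rownames(ct), ], Kct)
    report$heritability <- list(h2 = h$h2, h2_se = h$h2_se)
  }
  # --- survival ---------------------------------------------------------
  if (isTRUE(stages$survival) && !is.null(delta_tab)) {
    idx <- match(delta_tab$sample_id, phen$sample_id)
    cx <- cox_fit(phen$surv_time[idx], phen$surv_event[idx],
                  cbind(delta_age = delta_tab$delta_age,
                        age = phen$age[idx],
                        sex = as.integer(phen$sex == "male")[idx]))
    tert <- delta_age_tertiles(delta_tab$delta_age)
    km <- km_by_groups(phen$surv_time[idx], phen$surv_event[idx], tert)
    report$survival <- list(cox = cx, km = km)
  }
  # --- trait associations ----------------------------------------------
  if (isTRUE(stages$traits) && !is.null(delta_tab)) {
    report$traits <- trait_assoc_table(delta_tab, phen, Kct)
  }
  # --- coexpression -----------------------------------------------------
  coex <- NULL
  if (isTRUE(stages$coexpression)) {
    mrna <- cohort$mrna[rownames(ct), , drop = FALSE]
    Xc <- cbind(`(Intercept)` = 1, age = phen$age,
                sex = as.integer(phen$sex == "male"),
                cohort$cells[rownames(ct), -1, drop = FALSE])
    rownames(Xc) <- rownames(ct)
    svs <- estimate_svs(mrna, Xc,
                        n_sv = config$coexpression$n_sv,
                        mirna_resid = technical_normalize(ct, phen))
    coex <- coexpression_scan(technical_normalize(ct, phen), mrna, Xc,
                              Ect, svs,
                              fdr_threshold = config$coexpression$fdr)
    report$coexpression <- list(svs_retained = ncol(svs), table = coex)
  }
  # --- seed-match targets ----------------------------------------------
  targ <- NULL
  if (isTRUE(stages$targets) && !is.null(cohort$sequences) &&
      !is.null(coex)) {
    sig_pairs <- coex[coex$significant, c("mirna", "mrna")]
    if (nrow(sig_pairs)) {
      rep_tab <- seed_site_report(cohort$sequences$mirna_fasta,
                                  cohort$sequences$region_fasta,
                                  pairs = sig_pairs)
      targ <- predicted_targets(rep_tab)
      report$targets <- list(sites = rep_tab, predicted = targ,
                             n_pairs_scanned = nrow(sig_pairs),
                             n_predicted = nrow(targ))
    }
  }
  # --- enrichment -------------------------------------------------------
  if (isTRUE(stages$enrichment) && !is.null(coex)) {
    hits <- unique(coex$mrna[coex$significant])
    background <- colnames(cohort$mrna)
    planted <- unique(cohort$coupling$mrna)
    sets <- list(planted_targets = planted)
    with_seed(config$seed + 99L, {
      for (i in 1:5)
        sets[[sprintf("random_set_%d", i)]] <-
          sample(background, length(planted))
    })
    if (length(hits))
      report$enrichment <- fisher_enrichment(hits, background, sets)
  }
  if (!is.null(config$out_dir)) .write_pipeline_outputs(report, cohort,
                                                        config$out_dir)
  structure(report, class = "pipeline_report")
}

.write_pipeline_outputs <- function(report, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, file.path(dir, "cohort"))
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$diffexpr)) wt(report$diffexpr, "diffexpr.tsv")
  if (!is.null(report$clock)) {
    write_clock(report$clock$model, file.path(dir, "clock_model.txt"))
    wt(report$clock$delta, "delta_age.tsv")
  }
  if (!is.null(report$survival)) {
    wt(report$survival$cox$table, "cox.tsv")
    wt(report$survival$km, "km_curves.tsv")
  }
  if (!is.null(report$traits)) wt(report$traits, "trait_assoc.tsv")
  if (!is.null(report$coexpression))
    wt(report$coexpression$table, "coexpression.tsv")
  if (!is.null(report$targets)) wt(report$targets$sites, "seed_sites.tsv")
  if (!is.null(report$enrichment)) wt(report$enrichment, "enrichment.tsv")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== miRNA aging-clock pipeline report ==\n")
  cat(sprintf("cohort: %d individuals, %d pedigrees, %d miRNAs, %d mRNAs (%.2f%% Ct censored)\n",
              x$cohort$n, x$cohort$n_pedigrees, x$cohort$n_mirna,
              x$cohort$n_mrna, 100 * x$cohort$censored_frac))
  if (!is.null(x$qc))
    cat(sprintf("QC: kept %d/%d samples, %d/%d miRNAs; %d values filled\n",
                x$qc$n_kept_samples, x$qc$n_input_samples,
                x$qc$n_kept_mirnas, x$qc$n_input_mirnas,
                x$qc$n_values_filled))
  if (!is.null(x$diffexpr))
    cat(sprintf("age scan: %d/%d miRNAs significant (Bonferroni p < %.3g)\n",
                sum(x$diffexpr$significant), nrow(x$diffexpr),
                attr(x$diffexpr, "threshold")))
  if (!is.null(x$clock))
    cat(sprintf("clock: %d miRNAs; r = %.2f (discovery, n=%d) / %.2f (replication, n=%d)\n",
                length(x$clock$model$coefficients), x$clock$r_discovery,
                x$clock$n_discovery, x$clock$r_replication,
                x$clock$n_replication))
  if (!is.null(x$heritability))
    cat(sprintf("delta-age heritability: h2 = %.3f%s\n",
                x$heritability$h2,
                if (is.na(x$heritability$h2_se)) "" else
                  sprintf(" (SE %.3f)", x$heritability$h2_se)))
  if (!is.null(x$survival)) {
    d <- x$survival$cox$table[x$survival$cox$table$term == "delta_age", ]
    cat(sprintf("mortality: HR %.3f per delta-age year (95%% CI %.3f-%.3f; p = %.2g; %d events)\n",
                d$hr, d$ci_lo, d$ci_hi, d$p, x$survival$cox$n_events))
  }
  if (!is.null(x$traits))
    cat(sprintf("traits: %d/%d associated with delta age at Bonferroni p < %.3g\n",
                sum(x$traits$significant), nrow(x$traits),
                attr(x$traits, "threshold")))
  if (!is.null(x$coexpression))
    cat(sprintf("coexpression: %d significant pairs (FDR < %g), %d SVs retained\n",
                sum(x$coexpression$table$significant),
                attr(x$coexpression$table, "fdr_threshold"),
                x$coexpression$svs_retained))
  if (!is.null(x$targets))
    cat(sprintf("targets: %d/%d scanned pairs predicted by seed match\n",
                x$targets$n_predicted, x$targets$n_pairs_scanned))
  if (!is.null(x$enrichment))
    cat(sprintf("enrichment: top category %s (FDR %.3g)\n",
                x$enrichment$category[1], x$enrichment$fdr[1]))
  invisible(x)
}
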
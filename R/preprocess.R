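#' Quality control for a Ct matrix
#'
#' Applies the panel's QC rules in a fixed order: (1) values at or above
#' the detection limit are marked missing (not expressed); (2) per-miRNA
#' outliers at least `outlier_sd` standard deviations from the post-masking
#' mean are marked missing (two-sided); (3) miRNAs expressed in fewer than
#' `min_expressed_frac` of samples are dropped; (4) samples with more than
#' `max_sample_missing_frac` missing values over the kept miRNAs are
#' dropped; (5) remaining missing cells are filled with the limit value.
#' Outlier statistics are computed after limit masking so that censored
#' values cannot inflate the SD.
#'
#' @param ct numeric samples x miRNAs matrix (may contain `NA`).
#' @param limit detection limit in Ct units.
#' @param outlier_sd outlier threshold in per-miRNA SD units.
#' @param min_expressed_frac minimum fraction of samples in which a miRNA
#'   must be expressed to be kept.
#' @param max_sample_missing_frac maximum tolerated per-sample missing
#'   fraction over kept miRNAs.
#' @return list with `ct` (filtered, filled matrix) and `report`
#'   (class `qc_report`).
#' @export
qc_filter <- function(ct, limit = 27, outlier_sd = 5,
                      min_expressed_frac = 0.95,
                      max_sample_missing_frac = 0.10) {
  stopifnot(is.matrix(ct), nrow(ct) > 0, ncol(ct) > 0)
  n0 <- nrow(ct); m0 <- ncol(ct)
  miss <- is.na(ct)
  at_limit <- !miss & ct >= limit
  ct[at_limit] <- NA
  n_limit <- sum(at_limit)
  mu <- colMeans(ct, na.rm = TRUE)
  sdv <- apply(ct, 2, stats::sd, na.rm = TRUE)
  out <- !is.na(ct) &
    abs(sweep(ct, 2, mu)) >= sweep(matrix(1, nrow(ct), ncol(ct)), 2,
                                   outlier_sd * sdv, `*`)
  out[, is.na(sdv) | sdv == 0] <- FALSE
  ct[out] <- NA
  n_outlier <- sum(out)
  expr_frac <- colMeans(!is.na(ct))
  keep_mir <- expr_frac >= min_expressed_frac
  excluded_mirnas <- data.frame(
    mirna = colnames(ct)[!keep_mir],
    reason = sprintf("expressed in %.1f%% of samples (< %.1f%%)",
                     100 * expr_frac[!keep_mir], 100 * min_expressed_frac),
    stringsAsFactors = FALSE)
  if (!any(keep_mir))
    stop("empty panel: all miRNAs removed by the expression filter")
  ct <- ct[, keep_mir, drop = FALSE]
  samp_miss <- rowMeans(is.na(ct))
  keep_samp <- samp_miss <= max_sample_missing_frac
  excluded_samples <- data.frame(
    sample = rownames(ct)[!keep_samp],
    reason = sprintf("%.1f%% of kept miRNAs missing (> %.1f%%)",
                     100 * samp_miss[!keep_samp],
                     100 * max_sample_missing_frac),
    stringsAsFactors = FALSE)
  ct <- ct[keep_samp, , drop = FALSE]
  n_fill <- sum(is.na(ct))
  ct[is.na(ct)] <- limit
  report <- structure(list(
    n_input_samples = n0, n_input_mirnas = m0,
    n_kept_samples = nrow(ct), n_kept_mirnas = ncol(ct),
    excluded_mirnas = excluded_mirnas,
    excluded_samples = excluded_samples,
    n_values_marked_missing = c(limit = n_limit, outlier = n_outlier),
    n_values_filled = n_fill, fill_value = limit), class = "qc_report")
  list(ct = ct, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Ct matrix QC report\n")
  cat(sprintf("  samples: %d in, %d kept (%d excluded)\n",
              x$n_input_samples, x$n_kept_samples,
              nrow(x$excluded_samples)))
  cat(sprintf("  miRNAs:  %d in, %d kept (%d excluded)\n",
              x$n_input_mirnas, x$n_kept_mirnas, nrow(x$excluded_mirnas)))
  cat(sprintf("  values marked missing: %d at limit, %d outliers\n",
              x$n_values_marked_missing[["limit"]],
              x$n_values_marked_missing[["outlier"]]))
  cat(sprintf("  values filled with Ct = %g: %d\n", x$fill_value,
              x$n_values_filled))
  invisible(x)
}

# Build a covariate design matrix from the phenotype table; batch becomes
# a factor, sex a 0/1 indicator.
.covariate_design <- function(phen, covariates) {
  missing <- setdiff(covariates, names(phen))
  if (length(missing))
    stop("covariate(s) not in phenotype table: ",
         paste(missing, collapse = ", "))
  df <- phen[, covariates, drop = FALSE]
  if ("batch" %in% covariates) df$batch <- factor(df$batch)
  if ("sex" %in% covariates && !is.numeric(df$sex))
    df$sex <- as.integer(df$sex == "male")
  X <- stats::model.matrix(~ ., data = df)
  rownames(X) <- phen$sample_id
  X
}

#' Adjust Ct values for technical covariates
#'
#' Per-miRNA least-squares regression of Ct on the technical covariates
#' (batch treated as categorical); returns residuals plus the fraction of
#' variance each miRNA's regression explained. Aliased design columns are
#' dropped with a warning.
#'
#' @param ct Ct matrix after [qc_filter()].
#' @param phen phenotype table with the covariates, rows matched to `ct` by
#'   `sample_id`.
#' @param covariates covariate names (default: the four technical ones).
#' @return residual matrix with attributes `covariates_removed` and
#'   `variance_explained` (per miRNA).
#' @export
technical_normalize <- function(ct, phen,
                                covariates = c("batch", "rna_concentration",
                                               "rin", "ratio_260_280")) {
  phen <- phen[match(rownames(ct), phen$sample_id), ]
  if (anyNA(phen$sample_id)) stop("phenotypes missing for some samples")
  X <- .covariate_design(phen, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warning("rank-deficient design; dropping aliased column(s): ",
            paste(aliased, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, ct)
  ve <- 1 - apply(res, 2, stats::var) / apply(ct, 2, stats::var)
  structure(res, covariates_removed = covariates, variance_explained = ve)
}

#' Standardized covariate-adjusted residuals of Ct values
#'
#' Residualizes Ct values on the given covariates (by default the three
#' technical covariates plus sex; batch deliberately excluded, matching the
#' convention that profiling batches may coincide with cohorts) and
#' z-scores each miRNA column. These standardized residuals are the input
#' to the age clock.
#'
#' @inheritParams technical_normalize
#' @return standardized residual matrix (per-column mean 0, SD 1) with
#'   attribute `covariates_removed`.
#' @export
standardized_residuals <- function(ct, phen,
                                   covariates = c("sex", "rna_concentration",
                                                  "rin", "ratio_260_280")) {
  res <- technical_normalize(ct, phen, covariates)
  sdv <- apply(res, 2, stats::sd)
  sdv[sdv < 1e-8] <- 0
  if (any(sdv == 0))
    stop("zero-variance miRNA column(s): ",
         paste(colnames(res)[sdv == 0], collapse = ", "))
  out <- scale(res)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  structure(out, covariates_removed = covariates, standardized = TRUE)
}

#' Impute blood cell-count proportions from mRNA expression
#'
#' Fits a partial least-squares regression (via mixOmics) of measured cell
#' proportions on mRNA expression in the training subset, predicts
#' proportions for all samples, and reports k-fold cross-validated r^2
#' (squared Pearson correlation of held-out predictions with the measured
#' values) per cell type.
#'
#' @param mrna samples x genes log2 expression matrix.
#' @param training_cells samples x cell-types proportion matrix for a
#'   subset of `rownames(mrna)`.
#' @param n_components number of PLS components; must not exceed the rank
#'   of the centered training predictors.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold split.
#' @return list with `imputed` (all samples) and `cv_r2` (per cell type).
#' @export
impute_cell_counts <- function(mrna, training_cells, n_components = 10,
                               folds = 5, seed = 1) {
  stopifnot(is.matrix(mrna), is.matrix(training_cells),
            nrow(training_cells) > 0)
  train_ids <- rownames(training_cells)
  if (!all(train_ids %in% rownames(mrna)))
    stop("training samples absent from the mRNA matrix")
  Xtr <- mrna[train_ids, , drop = FALSE]
  rk <- qr(scale(Xtr, scale = FALSE))$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds the rank (", rk,
         ") of the centered training predictors")
  fit <- mixOmics::pls(Xtr, training_cells, ncomp = n_components,
                       mode = "regression")
  pr <- predict(fit, mrna)$predict[, , n_components]
  imputed <- matrix(pr, nrow(mrna), ncol(training_cells),
                    dimnames = list(rownames(mrna),
                                    colnames(training_cells)))
  cv_pred <- matrix(NA_real_, nrow(Xtr), ncol(training_cells),
                    dimnames = dimnames(training_cells))
  fold_id <- with_seed(seed,
                       sample(rep_len(seq_len(folds), nrow(Xtr))))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ncf <- min(n_components, qr(scale(Xtr[tr, , drop = FALSE],
                                      scale = FALSE))$rank)
    ff <- mixOmics::pls(Xtr[tr, , drop = FALSE],
                        training_cells[tr, , drop = FALSE],
                        ncomp = ncf, mode = "regression")
    cv_pred[!tr, ] <- predict(ff, Xtr[!tr, , drop = FALSE])$predict[, , ncf]
  }
  cv_r2 <- vapply(seq_len(ncol(training_cells)), function(j)
    stats::cor(cv_pred[, j], training_cells[, j])^2, numeric(1))
  names(cv_r2) <- colnames(training_cells)
  list(imputed = imputed, cv_r2 = cv_r2)
}
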
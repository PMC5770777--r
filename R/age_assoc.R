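#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a positive count")
  alpha / m
}

# Shared-rotation REML scan: one eigendecomposition, many responses.
# Y: samples x responses; X: common fixed design; extra: optional samples x
# q matrix whose j-th column is appended to X for response j (paired scan).
.reml_scan <- function(Y, X, E, test_col, extra = NULL) {
  d <- .eigen_values(E)
  tY <- .rotate(E, Y)
  tX <- .rotate(E, X)
  tE <- if (is.null(extra)) NULL else .rotate(E, extra)
  p_extra <- if (is.null(extra)) 0L else 1L
  q <- ncol(Y)
  res <- vector("list", q)
  for (j in seq_len(q)) {
    Xj <- if (is.null(tE)) tX else cbind(tX, test = tE[, j])
    fit <- .reml_profile(tY[, j], Xj, d)
    k <- if (is.null(tE)) match(test_col, colnames(X)) else ncol(Xj)
    covb <- fit$sigma2 * chol2inv(fit$ch)
    se <- sqrt(covb[k, k])
    tval <- fit$beta[k] / se
    df <- nrow(tY) - ncol(Xj)
    res[[j]] <- c(beta = fit$beta[[k]], se = se, t = tval,
                  p = 2 * stats::pnorm(-abs(tval)),
                  r2 = tval^2 / (tval^2 + df), h2 = fit$h2)
  }
  out <- as.data.frame(do.call(rbind, res))
  out$p <- pmax(out$p, .Machine$double.xmin)
  rownames(out) <- colnames(Y)
  out
}

#' Per-miRNA differential expression scan against chronological age
#'
#' Fits one kinship linear mixed model per miRNA with the (QC'd) Ct value
#' as response and chronological age as the tested covariate, adjusting for
#' the given covariates and family structure. Significance uses the
#' Bonferroni threshold `alpha / m` with `m` the number of miRNAs actually
#' tested. On the Ct scale a positive slope means expression declines with
#' age, so `direction` is `"down-with-age"` iff `beta > 0`.
#'
#' @param ct Ct (or residual) matrix, samples x miRNAs.
#' @param phen phenotype table (`sample_id`, `age`, covariates).
#' @param K kinship matrix or [kinship_eigen()] object.
#' @param covariates adjustment covariates from `phen`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param cells optional samples x cell-types matrix appended to the
#'   design (cell-count sensitivity mode).
#' @return data.frame of class `diffexpr_table`, ranked by p, with columns
#'   `mirna`, `beta`, `se`, `t`, `p`, `r_squared`, `h2`, `significant`,
#'   `direction`; attributes `m` and `threshold`.
#' @export
diffexpr_scan <- function(ct, phen, K,
                          covariates = c("sex", "batch", "rna_concentration",
                                         "rin", "ratio_260_280"),
                          alpha = 0.05, cells = NULL) {
  phen <- phen[match(rownames(ct), phen$sample_id), ]
  if (anyNA(phen$sample_id))
    stop("samples missing from phenotype table: ",
         paste(utils::head(setdiff(rownames(ct), phen$sample_id), 5),
               collapse = ", "))
  X <- cbind(.covariate_design(phen, covariates), age = phen$age)
  if (!is.null(cells)) {
    cells <- cells[rownames(ct), -1, drop = FALSE]  # drop one (simplex)
    colnames(cells) <- paste0("cell_", seq_len(ncol(cells)))
    X <- cbind(X, cells)
  }
  if (anyNA(ct))
    stop("Ct matrix contains missing values; run qc_filter() first")
  E <- kinship_eigen(.subset_kinship(K, rownames(ct)))
  ord <- match(E$ids, rownames(ct))
  scan <- .reml_scan(ct[ord, , drop = FALSE], X[ord, , drop = FALSE],
                     E, "age")
  m <- ncol(ct)
  thr <- bonferroni_threshold(alpha, m)
  out <- data.frame(mirna = rownames(scan), beta = scan$beta, se = scan$se,
                    t = scan$t, p = scan$p, r_squared = scan$r2,
                    h2 = scan$h2,
                    significant = scan$p < thr,
                    direction = ifelse(scan$beta > 0, "down-with-age",
                                       "up-with-age"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  structure(out, m = m, threshold = thr, alpha = alpha,
            class = c("diffexpr_table", "data.frame"))
}

#' @export
print.diffexpr_table <- function(x, n = 10, ...) {
  cat(sprintf("Differential expression vs age: %d miRNAs, %d significant at p < %.3g (Bonferroni %g/%d)\n",
              attr(x, "m"), sum(x$significant), attr(x, "threshold"),
              attr(x, "alpha"), attr(x, "m")))
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n")
  invisible(x)
}

#' Discovery/replication concordance of two differential-expression scans
#'
#' @param table_a,table_b `diffexpr_table` objects on the same panel.
#' @param threshold significance threshold used for the replication
#'   fraction (default: table A's Bonferroni threshold).
#' @return list of class `replication_summary`: Pearson correlation of
#'   betas and of log10 p-values, fraction of A-significant miRNAs also
#'   significant in B, and direction concordance among A-significant
#'   miRNAs.
#' @export
replication_compare <- function(table_a, table_b, threshold = NULL) {
  common <- intersect(table_a$mirna, table_b$mirna)
  if (!length(common)) stop("the two tables share no miRNAs")
  a <- table_a[match(common, table_a$mirna), ]
  b <- table_b[match(common, table_b$mirna), ]
  if (is.null(threshold)) threshold <- attr(table_a, "threshold")
  sig_a <- a$p < threshold
  structure(list(
    n_common = length(common),
    beta_cor = stats::cor(a$beta, b$beta),
    logp_cor = stats::cor(log10(a$p), log10(b$p)),
    replication_fraction = if (any(sig_a))
      mean(b$p[sig_a] < threshold) else NA_real_,
    direction_concordance = if (any(sig_a))
      mean(sign(a$beta[sig_a]) == sign(b$beta[sig_a])) else NA_real_,
    threshold = threshold), class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat("Discovery/replication concordance\n")
  cat(sprintf("  shared miRNAs: %d\n", x$n_common))
  cat(sprintf("  Pearson r (beta): %.3f; Pearson r (log10 p): %.3f\n",
              x$beta_cor, x$logp_cor))
  cat(sprintf("  replicated at p < %.3g: %.0f%%; direction concordance: %.0f%%\n",
              x$threshold, 100 * x$replication_fraction,
              100 * x$direction_concordance))
  invisible(x)
}
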
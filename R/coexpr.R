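#' Estimate surrogate variables from mRNA expression
#'
#' Residualizes the mRNA matrix on the model covariates and takes the top
#' `n_sv` sample-space singular vectors of the residual matrix as
#' surrogate variables (orthonormal columns). When a miRNA residual matrix
#' is supplied, the retention filter keeps only SVs associated with at
#' least one miRNA at the Bonferroni level `alpha / n_mirna` (simple
#' linear-regression test per SV-miRNA pair).
#'
#' @param mrna samples x genes log2 expression matrix.
#' @param design model covariate matrix (including intercept) to
#'   residualize on; `NULL` for centering only.
#' @param n_sv number of candidate SVs; must be below both dimensions.
#' @param mirna_resid optional samples x miRNAs matrix for the retention
#'   filter.
#' @param alpha family-wise error rate of the retention filter.
#' @return samples x k matrix of retained SVs with attributes
#'   `"n_candidates"` and `"selection"` (per-candidate minimum p and
#'   retention flag).
#' @export
estimate_svs <- function(mrna, design = NULL, n_sv = 10,
                         mirna_resid = NULL, alpha = 0.05) {
  stopifnot(is.matrix(mrna))
  if (n_sv >= min(dim(mrna)))
    stop("n_sv must be smaller than both matrix dimensions")
  R <- if (is.null(design)) scale(mrna, scale = FALSE)
  else qr.resid(qr(as.matrix(design)), mrna)
  sv <- svd(R, nu = n_sv, nv = 0)$u
  rownames(sv) <- rownames(mrna)
  colnames(sv) <- paste0("SV", seq_len(n_sv))
  minp <- rep(NA_real_, n_sv)
  keep <- rep(TRUE, n_sv)
  if (!is.null(mirna_resid)) {
    m <- ncol(mirna_resid)
    thr <- bonferroni_threshold(alpha, m)
    n <- nrow(sv)
    for (k in seq_len(n_sv)) {
      r <- suppressWarnings(stats::cor(sv[, k], mirna_resid))
      tt <- abs(r) * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
      pk <- 2 * stats::pt(-tt, df = n - 2)
      minp[k] <- min(pk, na.rm = TRUE)
      keep[k] <- minp[k] < thr
    }
  }
  structure(sv[, keep, drop = FALSE], n_candidates = n_sv,
            selection = data.frame(sv = colnames(sv), min_p = minp,
                                   retained = keep))
}

#' Pairwise miRNA-mRNA coexpression scan
#'
#' For every (miRNA, mRNA) pair fits a kinship linear mixed model with the
#' mRNA log2 value as response and the miRNA value as tested covariate,
#' with the supplied fixed effects (age, sex, technical covariates,
#' imputed cell proportions) and surrogate variables; the kinship
#' eigendecomposition is computed once and reused across all pairs.
#' P-values are Benjamini-Hochberg adjusted over the whole table. Because
#' miRNA abundance is on the Ct scale, the expression-scale sign is the
#' negative of the fitted slope.
#'
#' @param mirna samples x miRNAs matrix (Ct or residual scale).
#' @param mrna samples x mRNAs log2 matrix.
#' @param X fixed-effect design matrix (including intercept).
#' @param K kinship matrix or eigendecomposition.
#' @param svs optional surrogate-variable matrix appended to the design.
#' @param fdr_threshold significance threshold on the adjusted p-values.
#' @return data.frame of class `coexpression_table`: `mirna`, `mrna`,
#'   `beta`, `se`, `p`, `fdr`, `expr_sign`, `significant`.
#' @export
coexpression_scan <- function(mirna, mrna, X, K, svs = NULL,
                              fdr_threshold = 0.05) {
  if (!identical(rownames(mirna), rownames(mrna)))
    stop("miRNA and mRNA matrices are not sample-aligned")
  E <- kinship_eigen(.subset_kinship(K, rownames(mirna)))
  ord <- match(E$ids, rownames(mirna))
  Xc <- as.matrix(X)[ord, , drop = FALSE]
  if (!is.null(svs)) Xc <- cbind(Xc, as.matrix(svs)[ord, , drop = FALSE])
  d <- .eigen_values(E)
  tX <- .rotate(E, Xc)
  tMir <- .rotate(E, as.matrix(mirna)[ord, , drop = FALSE])
  tMrna <- .rotate(E, as.matrix(mrna)[ord, , drop = FALSE])
  nmir <- ncol(mirna); nmr <- ncol(mrna)
  res <- vector("list", nmir * nmr)
  idx <- 0L
  df <- nrow(tX) - ncol(tX) - 1L
  for (j in seq_len(nmir)) {
    Xj <- cbind(tX, mir = tMir[, j])
    for (g in seq_len(nmr)) {
      fit <- .reml_profile(tMrna[, g], Xj, d)
      k <- ncol(Xj)
      covb <- fit$sigma2 * chol2inv(fit$ch)
      se <- sqrt(covb[k, k])
      tval <- fit$beta[k] / se
      idx <- idx + 1L
      res[[idx]] <- c(j, g, fit$beta[[k]], se, tval,
                      2 * stats::pnorm(-abs(tval)))
    }
  }
  tab <- do.call(rbind, res)
  out <- data.frame(mirna = colnames(mirna)[tab[, 1]],
                    mrna = colnames(mrna)[tab[, 2]],
                    beta = tab[, 3], se = tab[, 4], t = tab[, 5],
                    p = pmax(tab[, 6], .Machine$double.xmin),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p)
  out$expr_sign <- -sign(out$beta)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  structure(out, fdr_threshold = fdr_threshold,
            class = c("coexpression_table", "data.frame"))
}

#' @export
print.coexpression_table <- function(x, n = 10, ...) {
  cat(sprintf("miRNA-mRNA coexpression: %d pairs, %d significant at FDR < %g\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold")))
  print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1
#' (delegates to `stats::p.adjust` after validation).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when sampling `n` items without replacement from a
#' population of `N` containing `K` successes; computed on the log scale
#' internally for numerical safety, so values far below 1e-16 are exact.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n sample size.
#' @param k observed successes in the sample.
#' @return tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment by one-sided Fisher exact tests
#'
#' For each category, tests over-representation of the hit set against the
#' background on the 2x2 table (hit / non-hit x in / out of category) with
#' a one-sided Fisher exact test, then Benjamini-Hochberg adjusts across
#' categories.
#'
#' @param hit_set character vector of hit ids (must be within the
#'   background).
#' @param background character vector of all measured ids.
#' @param categories named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame of class `enrichment_result`: `category`, `N`, `K`,
#'   `n`, `k`, `odds_ratio`, `p`, `fdr`.
#' @export
fisher_enrichment <- function(hit_set, background, categories) {
  hit_set <- unique(hit_set); background <- unique(background)
  if (!all(hit_set %in% background))
    stop("hit set contains ids outside the background")
  if (!length(categories)) stop("no categories supplied")
  N <- length(background); n <- length(hit_set)
  rows <- lapply(names(categories), function(nm) {
    set <- intersect(categories[[nm]], background)
    K <- length(set)
    k <- length(intersect(hit_set, set))
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(category = nm, N = N, K = K, n = n, k = k,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
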
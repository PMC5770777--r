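#' Validate a pedigree table
#'
#' A pedigree is a data.frame with columns `pedigree_id`, `individual_id`,
#' `father_id`, `mother_id` and `sex` (`"male"`/`"female"`); the founder
#' marker for unknown parents is `"0"`. Individual ids must be unique,
#' parents must belong to the same pedigree (or be founders), fathers must
#' be male and mothers female, and the parent-child graph must be acyclic.
#'
#' @param ped pedigree data.frame.
#' @return the pedigree, invisibly; errors describe the first violation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("pedigree_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual_id in pedigree")
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    known <- p != "0"
    if (any(known & !(p %in% ped$individual_id)))
      stop(col, " refers to unknown individual(s): ",
           paste(utils::head(p[known & !(p %in% ped$individual_id)], 3),
                 collapse = ", "))
    same <- ped$pedigree_id[idx[p[known]]] == ped$pedigree_id[known]
    if (any(!same)) stop(col, " crosses pedigree boundaries")
  }
  fa <- ped$father_id; mo <- ped$mother_id
  if (any(fa != "0" & ped$sex[idx[fa]] != "male"))
    stop("a father is not male")
  if (any(mo != "0" & ped$sex[idx[mo]] != "female"))
    stop("a mother is not female")
  .pedigree_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order (parents before children); errors on cycles.
.pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  fa <- ifelse(ped$father_id == "0", NA_integer_, idx[ped$father_id])
  mo <- ifelse(ped$mother_id == "0", NA_integer_, idx[ped$mother_id])
  depth <- rep(NA_integer_, n)
  visiting <- rep(FALSE, n)
  dfs <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    if (visiting[i]) stop("pedigree contains a cycle at individual ",
                          ped$individual_id[i])
    visiting[i] <<- TRUE
    d <- 0L
    if (!is.na(fa[i])) d <- max(d, dfs(fa[i]) + 1L)
    if (!is.na(mo[i])) d <- max(d, dfs(mo[i]) + 1L)
    visiting[i] <<- FALSE
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) dfs(i)
  order(depth)
}

#' Expected additive relationship matrix from a pedigree
#'
#' Computes kinship coefficients by the standard recursion --
#' phi(i,i) = (1 + phi(father_i, mother_i)) / 2 and
#' phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2 with founders
#' unrelated -- and returns the relationship matrix 2*phi, so that the
#' polygenic covariance is sigma2_A times this matrix. The result carries a
#' `"blocks"` attribute (the pedigree id of each individual) that
#' [kinship_eigen()] exploits for block-wise eigendecomposition.
#'
#' @param ped validated pedigree data.frame.
#' @return symmetric matrix of class `kinship_matrix` with individual ids as
#'   dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  ids <- ped$individual_id
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- stats::setNames(seq_len(n), ids)
  # individuals in different pedigrees are unrelated, so the recursion runs
  # block-wise per pedigree (linear in sample size for small families)
  for (fid in unique(ped$pedigree_id)) {
    sub <- ped[ped$pedigree_id == fid, , drop = FALSE]
    m <- nrow(sub)
    Kb <- matrix(0, m, m)
    ord <- .pedigree_order(sub)
    idx <- stats::setNames(seq_len(m), sub$individual_id)
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      f <- sub$father_id[i]; mo <- sub$mother_id[i]
      fi <- if (f == "0") 0L else idx[[f]]
      mi <- if (mo == "0") 0L else idx[[mo]]
      phi_fm <- if (fi && mi) Kb[fi, mi] / 2 else 0  # Kb holds 2*phi
      Kb[i, i] <- 1 + phi_fm
      if (ii > 1L) {
        for (jj in seq_len(ii - 1L)) {
          j <- ord[jj]
          v <- 0
          if (fi) v <- v + Kb[fi, j]
          if (mi) v <- v + Kb[mi, j]
          Kb[i, j] <- Kb[j, i] <- v / 2
        }
      }
    }
    K[pos[sub$individual_id], pos[sub$individual_id]] <- Kb
  }
  structure(K, blocks = stats::setNames(ped$pedigree_id, ids),
            class = c("kinship_matrix", "matrix", "array"))
}

#' Eigendecomposition of a relationship matrix
#'
#' When the matrix carries a `"blocks"` attribute (pedigree membership),
#' the decomposition is done block by block, which makes mixed-model fits on
#' thousands of individuals from small families essentially linear in sample
#' size. Negative eigenvalues beyond `-tol` trigger a warning and are
#' clipped to zero, enforcing positive semidefiniteness.
#'
#' @param K relationship matrix (e.g. from [kinship_from_pedigree()]).
#' @param tol clipping tolerance for negative eigenvalues.
#' @return object of class `kinship_eigen`: list of per-block
#'   `(ids, vectors, values)` plus the sample id order.
#' @export
kinship_eigen <- function(K, tol = 1e-8) {
  if (inherits(K, "kinship_eigen")) return(K)
  ids <- rownames(K)
  stopifnot(!is.null(ids))
  blocks <- attr(K, "blocks")
  groups <- if (is.null(blocks)) list(ids) else split(ids, blocks[ids])
  res <- lapply(groups, function(g) {
    sub <- K[g, g, drop = FALSE]
    e <- eigen(sub, symmetric = TRUE)
    if (any(e$values < -tol))
      warning("relationship matrix not PSD; clipping ",
              sum(e$values < -tol), " negative eigenvalue(s)")
    e$values <- pmax(e$values, 0)
    list(ids = g, vectors = e$vectors, values = e$values)
  })
  structure(list(blocks = res, ids = unlist(lapply(res, `[[`, "ids"),
                                            use.names = FALSE)),
            class = "kinship_eigen")
}

# Subset a kinship matrix to the given ids, preserving block structure.
.subset_kinship <- function(K, ids) {
  if (inherits(K, "kinship_eigen")) {
    if (!setequal(K$ids, ids))
      stop("precomputed kinship eigendecomposition does not match the ",
           "samples; pass the kinship matrix itself")
    return(K)
  }
  if (!all(ids %in% rownames(K)))
    stop("samples missing from kinship matrix: ",
         paste(utils::head(setdiff(ids, rownames(K)), 5), collapse = ", "))
  blocks <- attr(K, "blocks")
  K <- K[ids, ids, drop = FALSE]
  if (!is.null(blocks)) attr(K, "blocks") <- blocks[ids]
  class(K) <- c("kinship_matrix", "matrix", "array")
  K
}

# Rotate rows of a matrix/vector by t(U) block-wise.
.rotate <- function(E, M) {
  M <- as.matrix(M)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  pos <- 0L
  rn <- rownames(M)
  for (b in E$blocks) {
    ii <- if (is.null(rn)) (pos + 1L):(pos + length(b$ids)) else
      match(b$ids, rn)
    out[(pos + 1L):(pos + length(b$ids)), ] <-
      crossprod(b$vectors, M[ii, , drop = FALSE])
    pos <- pos + length(b$ids)
  }
  rownames(out) <- E$ids
  out
}

.eigen_values <- function(E) unlist(lapply(E$blocks, `[[`, "values"),
                                    use.names = FALSE)

# Profile REML objective pieces for rotated data. Returns the fit at a given
# heritability ratio h2 (share of total variance attributed to the polygenic
# component).
.gls_at <- function(h2, ty, tX, d) {
  w <- h2 * d + (1 - h2)
  sw <- 1 / w
  Xw <- tX * sw
  XtWX <- crossprod(tX, Xw)
  XtWy <- crossprod(Xw, ty)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ty - tX %*% beta
  rss <- sum(r * r * sw)
  n <- length(ty); p <- ncol(tX)
  sigma2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma2) + sum(log(w)) +
                  2 * sum(log(diag(ch))) + (n - p))
  list(h2 = h2, beta = drop(beta), sigma2 = sigma2, loglik = ll,
       XtWX = XtWX, ch = ch)
}

# Core profile-REML optimizer over h2 in [0, 1 - 1e-6]: coarse grid then
# bounded golden-section refinement; ties broken toward 0.
.reml_profile <- function(ty, tX, d, grid_n = 21L, tol = 1e-9) {
  upper <- 1 - 1e-6
  hs <- seq(0, upper, length.out = grid_n)
  lls <- vapply(hs, function(h) .gls_at(h, ty, tX, d)$loglik, numeric(1))
  i <- which.max(lls)
  lo <- hs[max(1L, i - 1L)]; hi <- hs[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(h) .gls_at(h, ty, tX, d)$loglik,
                         lower = lo, upper = hi, maximum = TRUE, tol = tol)
  h2 <- opt$maximum; ll <- opt$objective
  at0 <- .gls_at(0, ty, tX, d)
  if (at0$loglik >= ll - 1e-10) { h2 <- 0; ll <- at0$loglik }
  fit <- .gls_at(h2, ty, tX, d)
  fit$loglik <- ll
  fit
}

#' Fit a single-random-effect linear mixed model by profile REML
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigma2_A * K)` and
#' `e ~ N(0, sigma2_E * I)`. The relationship matrix is eigendecomposed once
#' (`K = U D U'`), the data are rotated by `U'`, and the restricted
#' likelihood is profiled over the heritability ratio
#' `h2 = sigma2_A / (sigma2_A + sigma2_E)` on `[0, 1)` (coarse grid plus
#' golden-section refinement; ties broken toward 0, i.e. toward the simpler
#' independent-errors model). Fixed effects and the total variance have
#' closed GLS forms at each candidate `h2`. Standard errors come from the
#' GLS covariance at the optimum; p-values use the normal approximation to
#' the Wald statistic (t statistics with `n - p` residual df are also
#' reported).
#'
#' @param y numeric response vector (named by sample id, or aligned with K).
#' @param X fixed-effect design matrix (including intercept).
#' @param K `kinship_matrix`, plain relationship matrix, or a precomputed
#'   [kinship_eigen()] object (reuse it when scanning many responses).
#' @return object of class `mir_lmm` with elements `beta`, `se`, `t`,
#'   `wald_p`, `sigma2_A`, `sigma2_E`, `h2`, `h2_se`, `partial_r2`,
#'   `reml_loglik`, `df_residual`, `n`.
#' @export
reml_fit <- function(y, X, K) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  E <- kinship_eigen(K)
  y <- as.matrix(y)
  if (!is.null(rownames(y)) && !identical(rownames(y), E$ids)) {
    if (!all(E$ids %in% rownames(y)))
      stop("response ids do not cover the kinship ids")
    y <- y[E$ids, , drop = FALSE]
  }
  if (!is.null(rownames(X)) && !identical(rownames(X), E$ids))
    X <- X[E$ids, , drop = FALSE]
  if (nrow(y) != length(E$ids) || nrow(X) != nrow(y))
    stop("dimension mismatch between y, X and the kinship matrix")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping aliased column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  d <- .eigen_values(E)
  flat <- diff(range(d)) < 1e-8
  if (flat)
    warning("relationship matrix is proportional to identity; ",
            "sigma2_A and sigma2_E are not separately identifiable ",
            "(likelihood flat in h2)")
  ty <- .rotate(E, y)
  tX <- .rotate(E, X)
  fit <- .reml_profile(ty, tX, d)
  p <- ncol(tX); n <- nrow(ty)
  covb <- fit$sigma2 * chol2inv(fit$ch)
  se <- sqrt(diag(covb))
  tval <- fit$beta / se
  df <- n - p
  wald_p <- 2 * stats::pnorm(-abs(tval))
  # SE of h2 from the curvature of the profile REML log-likelihood
  h2_se <- NA_real_
  if (!flat && fit$h2 > 1e-6 && fit$h2 < 1 - 1e-4) {
    eps <- 1e-4
    ll <- function(h) .gls_at(h, ty, tX, d)$loglik
    d2 <- (ll(fit$h2 + eps) - 2 * fit$loglik + ll(fit$h2 - eps)) / eps^2
    if (is.finite(d2) && d2 < 0) h2_se <- sqrt(-1 / d2)
  }
  structure(list(
    beta = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t = stats::setNames(tval, colnames(X)),
    wald_p = stats::setNames(pmin(pmax(wald_p, .Machine$double.xmin), 1),
                             colnames(X)),
    sigma2_A = fit$h2 * fit$sigma2,
    sigma2_E = (1 - fit$h2) * fit$sigma2,
    h2 = fit$h2, h2_se = h2_se,
    partial_r2 = stats::setNames(tval^2 / (tval^2 + df), colnames(X)),
    reml_loglik = fit$loglik, df_residual = df, n = n,
    identifiable = !flat), class = "mir_lmm")
}

#' @export
print.mir_lmm <- function(x, ...) {
  cat("Kinship linear mixed model (profile REML)\n")
  cat(sprintf("  n = %d, residual df = %d\n", x$n, x$df_residual))
  cat(sprintf("  sigma2_A = %.4g, sigma2_E = %.4g, h2 = %.4f%s\n",
              x$sigma2_A, x$sigma2_E, x$h2,
              if (is.na(x$h2_se)) "" else sprintf(" (SE %.4f)", x$h2_se)))
  cat(sprintf("  REML log-likelihood: %.4f\n", x$reml_loglik))
  print(summary(x))
  invisible(x)
}

#' @export
summary.mir_lmm <- function(object, ...) {
  data.frame(term = names(object$beta), beta = object$beta, se = object$se,
             t = object$t, p = object$wald_p,
             partial_r2 = object$partial_r2, row.names = NULL)
}

#' @export
coef.mir_lmm <- function(object, ...) object$beta

#' Partial r-squared of one covariate in a mixed-model fit
#'
#' Computed as `t^2 / (t^2 + df)` where `t` is the Wald statistic of the
#' covariate and `df` the residual degrees of freedom; equal to the squared
#' partial correlation between response and covariate given the remaining
#' design.
#'
#' @param fit `mir_lmm` object.
#' @param covariate covariate name present in the fit.
#' @return fraction in `[0, 1]`.
#' @export
partial_r2 <- function(fit, covariate) {
  stopifnot(inherits(fit, "mir_lmm"))
  if (!covariate %in% names(fit$t))
    stop("covariate not in fit: ", covariate)
  t2 <- fit$t[[covariate]]^2
  t2 / (t2 + fit$df_residual)
}

#' Narrow-sense heritability of a quantitative trait in a pedigree
#'
#' Convenience wrapper around [reml_fit()]: the trait is the response,
#' covariates enter as fixed effects, and the polygenic covariance is the
#' pedigree relationship matrix. Returns `h2 = sigma2_A /
#' (sigma2_A + sigma2_E)` with a curvature-based standard error.
#'
#' @param y trait vector.
#' @param covariates fixed-effect design matrix (an intercept is added if
#'   absent); `NULL` for intercept only.
#' @param ped pedigree data.frame, or a precomputed kinship matrix /
#'   eigendecomposition.
#' @return list with `h2`, `h2_se`, and the full `fit`.
#' @export
heritability <- function(y, covariates = NULL, ped) {
  K <- if (is.data.frame(ped)) kinship_from_pedigree(ped) else ped
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1, dimnames = list(names(y),
                                                                "(Intercept)"))
  else {
    covariates <- as.matrix(covariates)
    if (!any(apply(covariates, 2, function(c) all(c == c[1]))))
      covariates <- cbind(`(Intercept)` = 1, covariates)
    covariates
  }
  fit <- reml_fit(y, X, K)
  list(h2 = fit$h2, h2_se = fit$h2_se, fit = fit)
}
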
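#' Split samples into discovery and replication sets by whole pedigrees
#'
#' Every pedigree is assigned wholly to one set so the two sets share no
#' relatedness. Assignment is greedy largest-first: pedigrees are sorted by
#' decreasing size (ties shuffled by `seed`) and each goes to the set with
#' the larger remaining deficit relative to its target share.
#'
#' @param ped pedigree data.frame.
#' @param ratio target fraction of individuals in the discovery set.
#' @param seed RNG seed for tie shuffling.
#' @return data.frame (`individual_id`, `pedigree_id`,
#'   `set` in `{"discovery", "replication"}`).
#' @export
split_by_pedigree <- function(ped, ratio = 0.5, seed = 1) {
  # only membership matters here, so a QC-subset pedigree (possibly missing
  # referenced parents) is acceptable
  stopifnot(all(c("pedigree_id", "individual_id") %in% names(ped)))
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual_id in pedigree")
  sizes <- table(ped$pedigree_id)
  if (length(sizes) < 2)
    stop("cannot split: a single pedigree covers all samples")
  n <- nrow(ped)
  ord <- with_seed(seed, {
    shuffled <- sample(names(sizes))
    shuffled[order(sizes[shuffled], decreasing = TRUE)]
  })
  target <- c(discovery = ratio * n, replication = (1 - ratio) * n)
  count <- c(discovery = 0, replication = 0)
  assign_to <- character(length(ord))
  names(assign_to) <- ord
  for (fid in ord) {
    deficit <- target - count
    set <- names(which.max(deficit))
    assign_to[fid] <- set
    count[set] <- count[set] + sizes[[fid]]
  }
  data.frame(individual_id = ped$individual_id,
             pedigree_id = ped$pedigree_id,
             set = unname(assign_to[ped$pedigree_id]),
             stringsAsFactors = FALSE)
}

# Pedigree-blocked fold assignment: whole pedigrees per fold, greedy
# largest-first balancing of fold sizes.
.pedigree_folds <- function(pedigree_id, folds, seed) {
  sizes <- table(pedigree_id)
  ord <- with_seed(seed, {
    shuffled <- sample(names(sizes))
    shuffled[order(sizes[shuffled], decreasing = TRUE)]
  })
  fold_of <- stats::setNames(integer(length(ord)), ord)
  count <- numeric(folds)
  for (fid in ord) {
    f <- which.min(count)
    fold_of[fid] <- f
    count[f] <- count[f] + sizes[[fid]]
  }
  unname(fold_of[as.character(pedigree_id)])
}

#' Train the elastic-net miRNA age clock
#'
#' Regresses chronological age on standardized miRNA residuals with the
#' elastic-net penalty, using glmnet's exact parameterization: loss
#' `(2n)^-1 ||age - b0 - X b||^2`, L1 weight `lambda * alpha`, and (because
#' glmnet computes on the internally y-standardized scale) ridge weight
#' `lambda * (1-alpha) / sd_n(age)` on the original scale; the intercept is
#' unpenalized and predictors are not re-standardized internally. When
#' `lambda` is `NULL` the penalty is chosen by
#' k-fold cross-validation minimizing mean squared error, with folds that
#' keep whole pedigrees together so family structure cannot leak across
#' folds; pass a fixed `lambda` (e.g. 0.2) to pin the penalty instead.
#'
#' @param resid standardized residual matrix (training samples x miRNAs;
#'   columns must have mean ~0 and SD ~1, see [standardized_residuals()]).
#' @param ages chronological ages (years) of the training samples.
#' @param alpha_mix elastic-net mixing parameter in `[0, 1]`.
#' @param lambda fixed penalty, or `NULL` for CV selection.
#' @param folds number of CV folds.
#' @param seed RNG seed (fold assignment).
#' @param pedigree_id optional pedigree id per training sample; when given,
#'   CV folds are pedigree-blocked.
#' @return object of class `mirna_clock`: sparse named `coefficients`
#'   (years per SD; zero entries omitted), `intercept` (years),
#'   `alpha`, `lambda`, `n_train`, `cv` (lambda/mean/sd curve or NULL).
#' @export
train_clock <- function(resid, ages, alpha_mix = 0.5, lambda = NULL,
                        folds = 10, seed = 1, pedigree_id = NULL) {
  stopifnot(is.matrix(resid), nrow(resid) == length(ages))
  if (nrow(resid) <= folds) stop("need more training samples than folds")
  mu <- colMeans(resid); sdv <- apply(resid, 2, stats::sd)
  if (max(abs(mu)) > 0.2 || max(abs(sdv - 1)) > 0.2)
    stop("input is not standardized (per-column mean 0, SD 1); ",
         "use standardized_residuals()")
  if (!is.null(lambda) && length(lambda) == 0) stop("empty lambda grid")
  cv <- NULL
  if (is.null(lambda)) {
    foldid <- if (is.null(pedigree_id))
      with_seed(seed, sample(rep_len(seq_len(folds), nrow(resid))))
    else .pedigree_folds(pedigree_id, folds, seed)
    cvfit <- glmnet::cv.glmnet(resid, ages, alpha = alpha_mix,
                               foldid = foldid, standardize = FALSE)
    lambda <- cvfit$lambda.min
    cv <- data.frame(lambda = cvfit$lambda, mse = cvfit$cvm,
                     sd = cvfit$cvsd)
  }
  fit <- glmnet::glmnet(resid, ages, alpha = alpha_mix,
                        standardize = FALSE, thresh = 1e-12)
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = resid,
                              y = ages, alpha = alpha_mix,
                              standardize = FALSE, thresh = 1e-12))[, 1]
  beta <- cf[-1]
  beta <- beta[beta != 0]
  structure(list(coefficients = beta, intercept = cf[[1]],
                 alpha = alpha_mix, lambda = lambda,
                 n_train = nrow(resid), folds = folds, cv = cv),
            class = "mirna_clock")
}

#' @export
print.mirna_clock <- function(x, ...) {
  cat("miRNA age clock (elastic net)\n")
  cat(sprintf("  %d miRNAs selected; alpha = %g, lambda = %.4g (%s)\n",
              length(x$coefficients), x$alpha, x$lambda,
              if (is.null(x$cv)) "fixed" else
                sprintf("%d-fold CV", x$folds)))
  cat(sprintf("  intercept = %.2f years; trained on n = %d\n",
              x$intercept, x$n_train))
  invisible(x)
}

#' @export
coef.mirna_clock <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' Predict miRNA age
#'
#' Applies a trained clock to a standardized residual matrix:
#' `intercept + sum_j beta_j x_j`. If chronological ages are supplied the
#' Pearson correlation of predictions with age is attached as attribute
#' `"cor"`.
#'
#' @param model `mirna_clock` object.
#' @param resid standardized residual matrix containing every model miRNA.
#' @param ages optional chronological ages.
#' @return named vector of predicted ages (years).
#' @export
predict_age <- function(model, resid, ages = NULL) {
  stopifnot(inherits(model, "mirna_clock"))
  sel <- names(model$coefficients)
  missing <- setdiff(sel, colnames(resid))
  if (length(missing))
    stop("model miRNA(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  pred <- drop(model$intercept +
                 resid[, sel, drop = FALSE] %*% model$coefficients)
  names(pred) <- rownames(resid)
  if (!is.null(ages)) attr(pred, "cor") <- stats::cor(pred, ages)
  pred
}

#' @export
predict.mirna_clock <- function(object, newdata, ages = NULL, ...)
  predict_age(object, newdata, ages)

#' Delta age: predicted minus chronological age
#'
#' @param predicted predicted ("miRNA") ages, named by sample.
#' @param chronological chronological ages, aligned with `predicted` (or
#'   named, in which case names must match).
#' @return data.frame of class `delta_age_table` (`sample_id`,
#'   `chronological_age`, `mirna_age`, `delta_age`); attribute
#'   `"cor_with_mirna_age"` carries the correlation of delta age with
#'   predicted age (diagnostic).
#' @export
delta_age <- function(predicted, chronological) {
  if (!is.null(names(predicted)) && !is.null(names(chronological))) {
    if (!setequal(names(predicted), names(chronological)))
      stop("sample ids of predicted and chronological ages do not match")
    chronological <- chronological[names(predicted)]
  } else if (length(predicted) != length(chronological)) {
    stop("predicted and chronological ages differ in length")
  }
  d <- as.numeric(predicted) - as.numeric(chronological)
  out <- data.frame(
    sample_id = if (is.null(names(predicted)))
      seq_along(predicted) else names(predicted),
    chronological_age = as.numeric(chronological),
    mirna_age = as.numeric(predicted),
    delta_age = d, stringsAsFactors = FALSE)
  diag_cor <- if (length(d) > 2 && stats::sd(d) > 0 &&
                    stats::sd(as.numeric(predicted)) > 0)
    stats::cor(d, as.numeric(predicted)) else NA_real_
  structure(out, cor_with_mirna_age = diag_cor,
            class = c("delta_age_table", "data.frame"))
}

#' Serialize a clock model to a plain-text key-value file
#'
#' Header lines (`# key: value`) store intercept, alpha, lambda and
#' training size; the body lists one `miRNA<TAB>coefficient` per line.
#'
#' @param model `mirna_clock` object.
#' @param path file path.
#' @return `read_clock` returns a `mirna_clock` object.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "mirna_clock"))
  hdr <- sprintf("# %s: %.12g",
                 c("intercept", "alpha", "lambda", "n_train"),
                 c(model$intercept, model$alpha, model$lambda,
                   model$n_train))
  body <- sprintf("%s\t%.12g", names(model$coefficients),
                  model$coefficients)
  writeLines(c(hdr, "mirna\tcoefficient", body), path)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  gethdr <- function(key) {
    l <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ": *"), "", l))
  }
  body <- lines[!grepl("^#", lines)][-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  beta <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                          vapply(parts, `[`, "", 1))
  structure(list(coefficients = beta, intercept = gethdr("intercept"),
                 alpha = gethdr("alpha"), lambda = gethdr("lambda"),
                 n_train = gethdr("n_train"), folds = NA, cv = NULL),
            class = "mirna_clock")
}
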
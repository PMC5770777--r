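#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default,
#' Breslow optional) via `survival::coxph`, returning a tidy per-covariate
#' table of log hazard ratios, hazard ratios with 95% CIs, and Wald
#' p-values. Monotone likelihood (perfect separation) is reported as an
#' error rather than returned as a huge estimate.
#'
#' @param time follow-up times (years), non-negative.
#' @param event event indicators in `{0, 1}`; at least one event required.
#' @param covariates numeric matrix or data.frame of covariates.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `mir_cox` with a per-covariate `table`
#'   (`log_hr`, `se`, `hr`, `ci_lo`, `ci_hi`, `z`, `p`), `ties_method`,
#'   `n`, `n_events`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (any(time < 0)) stop("negative follow-up times")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("no events: cannot fit a Cox model")
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("covariates must be finite")
  df <- data.frame(time = time, event = event, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("monotone partial likelihood (perfect separation); ",
             "estimate diverges", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- b / se
  zcrit <- stats::qnorm(0.975)
  tab <- data.frame(term = names(b), log_hr = unname(b), se = unname(se),
                    hr = exp(unname(b)),
                    ci_lo = exp(unname(b - zcrit * se)),
                    ci_hi = exp(unname(b + zcrit * se)),
                    z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, ties_method = ties, n = length(time),
                 n_events = sum(event), loglik = fit$loglik[2],
                 coxph = fit), class = "mir_cox")
}

#' @export
print.mir_cox <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d\n",
              x$ties_method, x$n, x$n_events))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
summary.mir_cox <- function(object, ...) object$table

#' @export
coef.mir_cox <- function(object, ...)
  stats::setNames(object$table$log_hr, object$table$term)

#' Kaplan-Meier curves by group
#'
#' Product-limit survival estimates per group. An all-censored group gives
#' a curve constant at 1 (not an error).
#'
#' @param time follow-up times.
#' @param event event indicators in `{0, 1}`.
#' @param group group labels (e.g. delta-age tertiles).
#' @return data.frame of class `surv_curves`: `group`, `time`, `surv`,
#'   `n_risk`, `n_event`.
#' @export
km_by_groups <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0)) stop("empty group(s)")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (is.null(fit$strata)) {
    strata <- rep(levels(group)[1], length(fit$time))
  } else {
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  structure(data.frame(group = strata, time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE),
            class = c("surv_curves", "data.frame"))
}

#' Cut delta age into tertiles
#'
#' Boundaries are the 1/3 and 2/3 sample quantiles; intervals are closed on
#' the right, so ties at a boundary fall in the lower tertile.
#'
#' @param delta numeric delta-age values.
#' @return factor with levels `T1 < T2 < T3`.
#' @export
delta_age_tertiles <- function(delta) {
  q <- stats::quantile(delta, c(1 / 3, 2 / 3), names = FALSE)
  cut(delta, breaks = c(-Inf, q, Inf), labels = c("T1", "T2", "T3"),
      right = TRUE)
}

#' Mixed-model association of delta age with a trait
#'
#' Fits a kinship linear mixed model with delta age as the response and
#' the trait (continuous, or 0/1 for prevalent disease) as the tested
#' covariate, adjusted for chronological age, sex and BMI (BMI is dropped
#' from the adjustment when it is itself the trait). Treatment-based
#' sample exclusions are applied per trait before fitting: hypertension is
#' tested in participants not on antihypertensive treatment, diabetes in
#' those not on antidiabetic treatment, continuous cardiometabolic traits
#' in those free of antihypertensive, lipid and diabetes treatment, and
#' prevalent CHD in everyone.
#'
#' @param delta `delta_age_table` (or a named delta-age vector).
#' @param phen phenotype table with the trait, adjustments and `rx_*`
#'   treatment flags.
#' @param K kinship matrix or eigendecomposition covering the samples.
#' @param trait trait column name.
#' @param adjust adjustment covariates (default age, sex, BMI).
#' @param exclusion `"auto"` for the per-trait rules above, `"none"`, or a
#'   logical vector (TRUE = keep) aligned with `phen`.
#' @return one-row data.frame: trait, n, beta/se/t/p for the trait and for
#'   age.
#' @export
trait_assoc <- function(delta, phen, K, trait,
                        adjust = c("age", "sex", "bmi"),
                        exclusion = "auto") {
  if (inherits(delta, "delta_age_table"))
    delta <- stats::setNames(delta$delta_age, delta$sample_id)
  if (!trait %in% names(phen)) stop("trait not in phenotype table: ", trait)
  keep <- rep(TRUE, nrow(phen))
  if (is.logical(exclusion)) {
    keep <- exclusion
  } else if (identical(exclusion, "auto")) {
    cont <- c("sbp", "dbp", "glucose", "bmi", "total_cholesterol", "hdl",
              "triglycerides")
    keep <- switch(trait,
                   chd = keep,
                   hypertension = phen$rx_htn == 0,
                   diabetes = phen$rx_dm == 0,
                   if (trait %in% cont)
                     phen$rx_htn == 0 & phen$rx_dm == 0 & phen$rx_lipid == 0
                   else keep)
  }
  adjust <- setdiff(adjust, trait)  # never adjust a trait for itself
  phen_k <- phen[keep & phen$sample_id %in% names(delta), ]
  if (!nrow(phen_k))
    stop("no samples remain after exclusions (started with ", nrow(phen),
         ")")
  y <- delta[phen_k$sample_id]
  X <- cbind(`(Intercept)` = 1, .covariate_design(phen_k, adjust)[, -1,
                                                                  drop = FALSE],
             trait = phen_k[[trait]])
  rownames(X) <- phen_k$sample_id
  fit <- reml_fit(y, X, .subset_kinship(K, phen_k$sample_id))
  data.frame(trait = trait, n = length(y),
             beta_age = if ("age" %in% names(fit$beta))
               fit$beta[["age"]] else NA_real_,
             t_age = if ("age" %in% names(fit$t))
               fit$t[["age"]] else NA_real_,
             p_age = if ("age" %in% names(fit$wald_p))
               fit$wald_p[["age"]] else NA_real_,
             beta = fit$beta[["trait"]], se = fit$se[["trait"]],
             t = fit$t[["trait"]], p = fit$wald_p[["trait"]],
             stringsAsFactors = FALSE)
}

#' Delta-age association table over a panel of traits
#'
#' Runs [trait_assoc()] for each trait and flags significance at the
#' Bonferroni threshold `alpha / n_traits`.
#'
#' @inheritParams trait_assoc
#' @param traits character vector of trait names.
#' @param alpha family-wise error rate.
#' @return data.frame with one row per trait plus `significant`.
#' @export
trait_assoc_table <- function(delta, phen, K,
                              traits = c("chd", "hypertension", "diabetes",
                                         "total_cholesterol", "hdl",
                                         "triglycerides", "sbp", "dbp",
                                         "glucose", "bmi"),
                              adjust = c("age", "sex", "bmi"),
                              alpha = 0.05) {
  rows <- lapply(traits, function(tr)
    trait_assoc(delta, phen, K, tr, adjust = adjust))
  out <- do.call(rbind, rows)
  thr <- bonferroni_threshold(alpha, length(traits))
  out$significant <- out$p < thr
  structure(out, threshold = thr, class = c("trait_assoc_table",
                                            "data.frame"))
}
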
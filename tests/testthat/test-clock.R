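# Standardize columns so that sum(x^2)/n = 1, the scale on which the
# elastic-net penalty is defined.
std_n <- function(X) {
  X <- scale(X, scale = FALSE)
  sweep(X, 2, sqrt(colMeans(X^2)), `/`)
}

test_that("pedigree split keeps families intact and balances sizes", {
  ped <- simulate_pedigrees(sim_params(n_families = 40, rng_seed = 21))
  sp <- split_by_pedigree(ped, seed = 1)
  expect_setequal(sp$individual_id, ped$individual_id)
  tab <- table(sp$pedigree_id, sp$set)
  expect_true(all(rowSums(tab > 0) == 1))  # no pedigree spans sets
  expect_lt(abs(sum(sp$set == "discovery") / nrow(sp) - 0.5), 0.05)
  # deterministic given the seed
  sp2 <- split_by_pedigree(ped, seed = 1)
  expect_identical(sp, sp2)
})

test_that("all-singleton pedigrees split to within one individual", {
  ped <- data.frame(pedigree_id = sprintf("P%02d", 1:11),
                    individual_id = sprintf("I%02d", 1:11),
                    father_id = "0", mother_id = "0",
                    sex = rep(c("male", "female"), length.out = 11))
  sp <- split_by_pedigree(ped, ratio = 0.5, seed = 3)
  expect_lte(abs(sum(sp$set == "discovery") -
                   sum(sp$set == "replication")), 1)
})

test_that("greedy largest-first assignment balances {4,3,2,1} to 5/5", {
  ped <- data.frame(
    pedigree_id = rep(c("A", "B", "C", "D"), times = c(4, 3, 2, 1)),
    individual_id = sprintf("I%02d", 1:10),
    father_id = "0", mother_id = "0",
    sex = "male")
  sp <- split_by_pedigree(ped, ratio = 0.5, seed = 1)
  expect_equal(sum(sp$set == "discovery"), 5)
  expect_equal(sum(sp$set == "replication"), 5)
})

test_that("a single pedigree cannot be split", {
  ped <- data.frame(pedigree_id = "P1",
                    individual_id = c("a", "b"),
                    father_id = "0", mother_id = "0",
                    sex = c("male", "female"))
  expect_error(split_by_pedigree(ped), "single pedigree")
})

test_that("penalties at or beyond lambda_max zero every coefficient", {
  set.seed(31)
  n <- 200; p <- 10
  X <- std_n(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("m%02d", 1:p)
  ages <- rnorm(n, 55, 10)
  alpha <- 0.5
  lam_max <- max(abs(crossprod(X, ages - mean(ages)) / n)) / alpha
  ck <- train_clock(X, ages, alpha_mix = alpha, lambda = lam_max * 1.01)
  expect_length(ck$coefficients, 0)
  pred <- predict_age(ck, X)
  expect_equal(unname(pred), rep(mean(ages), n), tolerance = 1e-8)
})

test_that("the unpenalized fit equals ordinary least squares", {
  set.seed(32)
  n <- 150; p <- 8
  X <- std_n(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("m%02d", 1:p)
  ages <- 50 + X %*% rnorm(p, 0, 3) + rnorm(n, 0, 4)
  ck <- train_clock(X, as.numeric(ages), lambda = 0)
  ols <- coef(lm(ages ~ X))
  got <- rep(0, p); names(got) <- colnames(X)
  got[names(ck$coefficients)] <- ck$coefficients
  expect_equal(unname(got), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(ck$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("a single active predictor obeys the soft-threshold closed form", {
  set.seed(33)
  n <- 200
  x <- std_n(matrix(rnorm(n), n, 1))[, 1]
  y <- 50 + 0.8 * x + rnorm(n, 0, 1)
  # second predictor orthogonal to both x and y so it stays inactive
  z <- resid(lm(rnorm(n) ~ x + y))
  z <- z / sqrt(mean(z^2))
  X <- cbind(m1 = x, m2 = z)
  st <- function(v, g) sign(v) * pmax(abs(v) - g, 0)
  for (lam in c(0.05, 0.2, 0.5)) {
    ck <- train_clock(X, y, alpha_mix = 1, lambda = lam)
    expected <- st(mean(x * (y - mean(y))), lam)
    got <- if ("m1" %in% names(ck$coefficients))
      ck$coefficients[["m1"]] else 0
    expect_equal(got, expected, tolerance = 1e-6)
    expect_false("m2" %in% names(ck$coefficients))
  }
})

test_that("solutions satisfy the elastic-net KKT conditions along a path", {
  set.seed(34)
  n <- 120; p <- 15
  X <- std_n(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("m%02d", 1:p)
  ages <- 50 + X %*% c(rnorm(5, 0, 2), rep(0, 10)) + rnorm(n, 0, 3)
  ages <- as.numeric(ages)
  alpha <- 0.5
  # glmnet computes on the internally y-standardized scale, so the ridge
  # part of the penalty carries a 1/sd_n(y) factor on the original scale
  sdy <- sd(ages) * sqrt((n - 1) / n)
  for (lam in c(0.05, 0.3, 1)) {
    ck <- train_clock(X, ages, alpha_mix = alpha, lambda = lam)
    beta <- rep(0, p); names(beta) <- colnames(X)
    beta[names(ck$coefficients)] <- ck$coefficients
    r <- ages - ck$intercept - X %*% beta
    grad <- crossprod(X, r) / n - lam * (1 - alpha) * beta / sdy
    active <- beta != 0
    if (any(active))
      expect_lt(max(abs(grad[active] - lam * alpha * sign(beta[active]))),
                1e-6)
    if (any(!active))
      expect_lt(max(abs(grad[!active])), lam * alpha + 1e-6)
  }
})

test_that("cross-validated training on family data respects pedigrees and predicts held-out age", {
  co <- small_cohort()
  qc <- qc_filter(co$ct, min_expressed_frac = 0.9)
  phen <- co$phen[match(rownames(qc$ct), co$phen$sample_id), ]
  resid <- standardized_residuals(qc$ct, phen)
  sp <- split_by_pedigree(co$ped[co$ped$individual_id %in%
                                   rownames(qc$ct), ], seed = 7)
  disc <- sp$individual_id[sp$set == "discovery"]
  repl <- sp$individual_id[sp$set == "replication"]
  mu <- colMeans(resid[disc, ]); sdv <- apply(resid[disc, ], 2, sd)
  tr <- scale(resid[disc, ], mu, sdv)
  te <- scale(resid[repl, ], mu, sdv)
  ages <- stats::setNames(phen$age, phen$sample_id)
  ck <- train_clock(tr, ages[disc], seed = 5,
                    pedigree_id = sp$pedigree_id[sp$set == "discovery"])
  expect_gt(length(ck$coefficients), 0)
  expect_false(is.null(ck$cv))
  pd <- predict_age(ck, tr, ages[disc])
  pr <- predict_age(ck, te, ages[repl])
  expect_gt(attr(pr, "cor"), 0.3)
  # in-sample optimism: training correlation at least matches held-out
  expect_gte(attr(pd, "cor"), attr(pr, "cor") - 0.02)
  # predictions depend only on the stored model and the input matrix
  ck2 <- read_clock(write_clock(ck, tempfile()))
  expect_equal(unname(predict_age(ck2, te)), unname(pr),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(predict_age(ck, te[, -match(names(ck$coefficients)[1],
                                           colnames(te))]),
               names(ck$coefficients)[1])
})

test_that("non-standardized input and bad folds are rejected", {
  set.seed(36)
  X <- matrix(rnorm(50 * 4, 20, 3), 50, 4)
  colnames(X) <- sprintf("m%d", 1:4)
  expect_error(train_clock(X, rnorm(50, 55, 9)), "not standardized")
  Xs <- std_n(X)
  expect_error(train_clock(Xs[1:8, ], rnorm(8), folds = 10),
               "more training samples than folds")
})

test_that("delta age is an exact subtraction with aligned ids", {
  expect_equal(delta_age(60, 55)$delta_age, 5)
  x <- c(a = 48.2, b = 61.0)
  expect_equal(delta_age(x, x)$delta_age, c(0, 0))
  d <- delta_age(c(a = 60, b = 50), c(b = 45, a = 58))
  expect_equal(d$delta_age, c(2, 5))  # aligned by name, not position
  expect_error(delta_age(c(a = 1), c(b = 1)), "do not match")
  expect_error(delta_age(1:3, 1:2), "differ in length")
})

test_that("held-out delta age is centred near zero for an unbiased generator", {
  co <- small_cohort()
  qc <- qc_filter(co$ct, min_expressed_frac = 0.9)
  phen <- co$phen[match(rownames(qc$ct), co$phen$sample_id), ]
  resid <- standardized_residuals(qc$ct, phen)
  sp <- split_by_pedigree(co$ped[co$ped$individual_id %in%
                                   rownames(qc$ct), ], seed = 2)
  disc <- sp$individual_id[sp$set == "discovery"]
  repl <- sp$individual_id[sp$set == "replication"]
  mu <- colMeans(resid[disc, ]); sdv <- apply(resid[disc, ], 2, sd)
  ages <- stats::setNames(phen$age, phen$sample_id)
  ck <- train_clock(scale(resid[disc, ], mu, sdv), ages[disc], seed = 2)
  pr <- predict_age(ck, scale(resid[repl, ], mu, sdv))
  d <- delta_age(pr, ages[repl])
  se <- sd(d$delta_age) / sqrt(nrow(d))
  expect_lt(abs(mean(d$delta_age)), 3 * se + 1)
})

test_that("clock serialization round-trips through the text format", {
  set.seed(37)
  X <- std_n(matrix(rnorm(60 * 5), 60, 5))
  colnames(X) <- sprintf("miR-test-%d", 1:5)
  y <- 50 + X %*% rnorm(5) + rnorm(60)
  ck <- train_clock(X, as.numeric(y), lambda = 0.1)
  f <- tempfile()
  write_clock(ck, f)
  ck2 <- read_clock(f)
  expect_equal(ck2$coefficients, ck$coefficients, tolerance = 1e-10)
  expect_equal(ck2$intercept, ck$intercept, tolerance = 1e-10)
  expect_equal(ck2$lambda, ck$lambda, tolerance = 1e-10)
})
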
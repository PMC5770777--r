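make_ct <- function(values, n, m) {
  matrix(values, n, m, dimnames = list(sprintf("s%02d", seq_len(n)),
                                       sprintf("m%02d", seq_len(m))))
}

test_that("detection-limit values are marked missing then filled", {
  ct <- make_ct(20, 4, 3)
  ct[2, 1] <- 27.5
  out <- qc_filter(ct, limit = 27, min_expressed_frac = 0.5,
                   max_sample_missing_frac = 0.5)
  expect_equal(out$ct[2, 1], 27)
  expect_equal(out$report$n_values_marked_missing[["limit"]], 1)
  expect_equal(out$report$n_values_filled, 1)
})

test_that("a clean matrix passes QC untouched", {
  set.seed(1)
  ct <- make_ct(rnorm(60, 20, 1), 10, 6)
  out <- qc_filter(ct)
  expect_identical(out$ct, ct)
  expect_equal(nrow(out$report$excluded_mirnas), 0)
  expect_equal(nrow(out$report$excluded_samples), 0)
  expect_equal(out$report$n_values_filled, 0)
})

test_that("samples exceeding the missingness threshold are dropped", {
  set.seed(2)
  ct <- make_ct(rnorm(100, 20, 1), 10, 10)
  ct[1, 1:2] <- NA  # 2 of 10 = 20% > 10%
  out <- qc_filter(ct, min_expressed_frac = 0.8)
  expect_false("s01" %in% rownames(out$ct))
  expect_equal(out$report$excluded_samples$sample, "s01")
  expect_equal(out$report$n_kept_samples, 9)
})

test_that("under-expressed miRNAs are dropped and an empty panel errors", {
  set.seed(3)
  ct <- make_ct(rnorm(100, 20, 1), 10, 10)
  ct[1:6, 1] <- 30  # expressed in only 40% of samples
  out <- qc_filter(ct, min_expressed_frac = 0.95,
                   max_sample_missing_frac = 1)
  expect_true("m01" %in% out$report$excluded_mirnas$mirna)
  allhigh <- make_ct(35, 5, 3)
  expect_error(qc_filter(allhigh), "empty panel")
})

test_that("QC is idempotent and conserves sample/miRNA accounting", {
  set.seed(4)
  for (r in 1:5) {
    n <- sample(10:30, 1); m <- sample(5:15, 1)
    ct <- make_ct(rnorm(n * m, 22, 2), n, m)
    ct[sample(n * m, round(0.05 * n * m))] <- NA
    ct[sample(n * m, 3)] <- runif(3, 27, 32)
    out1 <- qc_filter(ct, min_expressed_frac = 0.5,
                      max_sample_missing_frac = 0.3)
    rep1 <- out1$report
    expect_equal(rep1$n_kept_mirnas + nrow(rep1$excluded_mirnas),
                 rep1$n_input_mirnas)
    expect_equal(rep1$n_kept_samples + nrow(rep1$excluded_samples),
                 rep1$n_input_samples)
    out2 <- qc_filter(out1$ct, min_expressed_frac = 0.5,
                      max_sample_missing_frac = 0.3)
    expect_identical(out2$ct, out1$ct)
  }
})

test_that("outliers are flagged against post-masking statistics", {
  set.seed(5)
  ct <- make_ct(rnorm(300, 20, 0.5), 30, 10)
  # 20 SD below the mean (the rule is two-sided): large enough that the
  # outlier's own inflation of the column SD cannot hide it at 5 SD, and
  # below the detection limit so the limit rule cannot claim it first
  ct[5, 3] <- 20 - 0.5 * 20
  out <- qc_filter(ct, outlier_sd = 5, min_expressed_frac = 0.5)
  expect_equal(out$report$n_values_marked_missing[["outlier"]], 1)
  expect_equal(out$ct[5, 3], 27)  # filled with the limit
})

test_that("technical normalization removes exactly the linear covariate effects", {
  set.seed(6)
  n <- 60
  phen <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     batch = rep(1:3, each = n / 3),
                     rna_concentration = rlnorm(n, log(50), 0.3),
                     rin = rnorm(n, 8, 0.5),
                     ratio_260_280 = rnorm(n, 1.9, 0.05))
  base <- rnorm(n, 20, 1)
  ct <- cbind(m1 = base, m2 = base + 2 * (phen$batch == 2))
  rownames(ct) <- phen$sample_id
  res <- technical_normalize(ct, phen)
  # planted +2 Ct batch shift removed exactly
  gm <- tapply(res[, "m2"], phen$batch, mean)
  expect_lt(max(abs(gm - mean(gm))), 1e-10)
  # residuals orthogonal to each covariate
  expect_lt(abs(cor(res[, "m1"], phen$rin)), 1e-10)
  expect_lt(abs(cor(res[, "m2"], phen$rna_concentration)), 1e-10)
  # projection: applying twice equals applying once
  res2 <- technical_normalize(res, phen)
  expect_equal(unclass(res2), unclass(res), tolerance = 1e-12,
               ignore_attr = TRUE)
  # variance explained reported per miRNA
  ve <- attr(res, "variance_explained")
  expect_length(ve, 2)
  expect_gt(ve[["m2"]], ve[["m1"]])
})

test_that("covariate orthogonal to a miRNA leaves only centering", {
  n <- 50
  x <- rep(c(-1, 1), n / 2)
  y <- rnorm(n, 25, 1)
  y <- y - mean(y) + 25
  y <- y - x * sum(y * x) / sum(x * x)  # force exact orthogonality
  phen <- data.frame(sample_id = sprintf("s%02d", 1:n), covar = x)
  ct <- cbind(m1 = y); rownames(ct) <- phen$sample_id
  res <- technical_normalize(ct, phen, covariates = "covar")
  expect_equal(unname(res[, 1]), unname(y - mean(y)), tolerance = 1e-12)
})

test_that("standardized residuals have mean 0, SD 1 and react to the batch flag", {
  set.seed(7)
  n <- 80
  phen <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     sex = rep(c("male", "female"), n / 2),
                     batch = rep(1:4, each = n / 4),
                     rna_concentration = rlnorm(n, log(50), 0.3),
                     rin = rnorm(n, 8, 0.5),
                     ratio_260_280 = rnorm(n, 1.9, 0.05))
  ct <- make_ct(rnorm(n * 5, 21, 2), n, 5)
  rownames(ct) <- phen$sample_id
  ct[, 2] <- ct[, 2] + 1.5 * (phen$batch == 2)
  z <- standardized_residuals(ct, phen)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  expect_lt(abs(cor(z[, 1], phen$rin)), 1e-10)
  zb <- standardized_residuals(ct, phen,
                               covariates = c("sex", "batch",
                                              "rna_concentration", "rin",
                                              "ratio_260_280"))
  expect_gt(max(abs(zb[, 2] - z[, 2])), 0.01)  # batch adjustment matters
  ct0 <- ct; ct0[, 3] <- 24
  expect_error(standardized_residuals(ct0, phen), "m03")
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  set.seed(8)
  n <- 40
  phen <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     a = rnorm(n))
  phen$b <- 2 * phen$a  # aliased
  ct <- make_ct(rnorm(n * 2, 20, 1), n, 2)
  rownames(ct) <- phen$sample_id
  expect_warning(res <- technical_normalize(ct, phen, c("a", "b")),
                 "aliased")
  expect_equal(dim(res), dim(ct))
})

test_that("PLS cell imputation is exact on a noiseless mixture and null under permutation", {
  set.seed(9)
  G <- 40; C <- 3; n <- 60; ntr <- 45
  sig <- matrix(rnorm(C * G), C, G)
  P <- matrix(rgamma(n * C, 2), n, C); P <- P / rowSums(P)
  M <- P %*% sig
  rownames(M) <- sprintf("s%02d", 1:n)
  colnames(M) <- sprintf("g%02d", 1:G)
  Ptr <- P[1:ntr, ]; rownames(Ptr) <- rownames(M)[1:ntr]
  colnames(Ptr) <- sprintf("cell%d", 1:C)
  rk <- qr(scale(M[1:ntr, ], scale = FALSE))$rank
  out <- impute_cell_counts(M, Ptr, n_components = rk, seed = 2)
  expect_gt(min(out$cv_r2), 1 - 1e-6)
  expect_lt(max(abs(out$imputed - P)), 1e-6)
  # permuted training labels destroy predictability
  Pperm <- Ptr[sample(ntr), ]; rownames(Pperm) <- rownames(Ptr)
  outp <- impute_cell_counts(M, Pperm, n_components = rk, seed = 2)
  expect_lt(max(outp$cv_r2), 0.3)
  expect_error(impute_cell_counts(M, Ptr, n_components = ntr + 5),
               "exceeds the rank")
})
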
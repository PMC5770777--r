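# Small fixtures shared across test files; everything is generated in code.

# A hand-built three-generation pedigree exercising founder, sib, half-sib
# and grandparent relationships.
toy_pedigree <- function() {
  data.frame(
    pedigree_id = "P1",
    individual_id = c("gf", "gm", "dad", "mom", "mom2", "kid1", "kid2",
                      "half"),
    father_id = c("0", "0", "gf", "0", "0", "dad", "dad", "dad"),
    mother_id = c("0", "0", "gm", "0", "0", "mom", "mom", "mom2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "female", "male"),
    stringsAsFactors = FALSE)
}

# n_pairs independent full-sib pairs (no parents genotyped) with trait
# covariance 0.5 * sigma2_A between sibs; returns trait + kinship matrix.
sib_pair_data <- function(n_pairs, h2, seed = 1) {
  set.seed(seed)
  sibs <- sprintf("S%04d_%d", rep(seq_len(n_pairs), each = 2), 1:2)
  fam <- rep(seq_len(n_pairs), each = 2)
  # full sibs of non-inbred, unrelated parents: relationship 0.5
  K <- matrix(0, 2 * n_pairs, 2 * n_pairs, dimnames = list(sibs, sibs))
  diag(K) <- 1
  K[cbind(seq(1, 2 * n_pairs, 2), seq(2, 2 * n_pairs, 2))] <- 0.5
  K[cbind(seq(2, 2 * n_pairs, 2), seq(1, 2 * n_pairs, 2))] <- 0.5
  shared <- rnorm(n_pairs)[fam] * sqrt(h2 / 2)
  indep <- rnorm(2 * n_pairs) * sqrt(1 - h2 / 2)
  y <- stats::setNames(shared + indep, sibs)
  attr(K, "blocks") <- stats::setNames(sprintf("S%04d", fam), sibs)
  class(K) <- c("kinship_matrix", "matrix", "array")
  list(y = y, K = K, sibs = sibs)
}

# Family-structured data for mixed-model calibration tests: f families of
# size s, polygenic trait with the given h2, plus an optionally familial
# null covariate.
family_trait_data <- function(f = 40, s = 4, h2 = 0.6,
                              familial_x = TRUE) {
  ped <- data.frame(
    pedigree_id = rep(sprintf("F%03d", seq_len(f)), each = s),
    individual_id = sprintf("F%03d_I%d", rep(seq_len(f), each = s),
                            seq_len(s)),
    father_id = rep(c("0", "0", rep(NA, s - 2)), f),
    mother_id = rep(c("0", "0", rep(NA, s - 2)), f),
    sex = rep(c("male", "female",
                rep(c("male", "female"), length.out = s - 2)), f),
    stringsAsFactors = FALSE)
  dads <- ped$individual_id[seq(1, nrow(ped), by = s)]
  moms <- ped$individual_id[seq(2, nrow(ped), by = s)]
  ped$father_id[is.na(ped$father_id)] <- rep(dads, each = s - 2)
  ped$mother_id[is.na(ped$mother_id)] <- rep(moms, each = s - 2)
  K <- kinship_from_pedigree(ped)
  E <- kinship_eigen(K)
  n <- nrow(ped)
  fam <- rep(seq_len(f), each = s)
  # polygenic trait via family-wise chol
  g <- numeric(n)
  for (ff in seq_len(f)) {
    idx <- which(fam == ff)
    L <- chol(unclass(K)[idx, idx] + diag(1e-10, s))
    g[idx] <- drop(crossprod(L, rnorm(s))) * sqrt(h2)
  }
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  x <- if (familial_x) rnorm(f)[fam] * 0.8 + rnorm(n) * 0.6 else rnorm(n)
  list(ped = ped, K = K, E = E, y = stats::setNames(y, ped$individual_id),
       x = x, n = n)
}

# One small cohort shared (lazily) by several test files.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$co)) {
    .fixture_env$co <- simulate_cohort(
      sim_params(n_families = 80, n_mirna = 25, n_mrna = 60,
                 n_coupled_pairs = 12, rng_seed = 404))
  }
  .fixture_env$co
}
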
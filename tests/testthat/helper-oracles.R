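# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (no eigendecomposition, no Biostrings
# matching, no phyper tail).

# Dense REML log-likelihood, profiled over total variance at a given h2.
naive_reml_loglik <- function(h2, y, X, K) {
  n <- length(y); p <- ncol(X)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(sigma2) + determinant(V)$modulus +
                       determinant(XtViX)$modulus + (n - p)))
}

# Cox partial log-likelihood, no ties assumed (distinct event times).
cox_partial_loglik <- function(b, time, event, x) {
  eta <- drop(as.matrix(x) %*% b)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force sliding-window seed-site counter; mirrors the published site
# definitions by direct substring comparison at every offset.
seed_site_oracle <- function(mirna_seq, target_seq) {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  mir <- chartr("U", "T", toupper(mirna_seq))
  tgt <- chartr("U", "T", toupper(target_seq))
  core <- rc(substr(mir, 2, 7))
  m8c <- comp(substr(mir, 8, 8))
  counts <- c(`8mer` = 0L, `7mer-m8` = 0L, `7mer-A1` = 0L, `6mer` = 0L)
  L <- nchar(tgt)
  if (L < 6) return(counts)
  for (s in 1:(L - 5)) {
    if (substr(tgt, s, s + 5) != core) next
    has_m8 <- s >= 2 && substr(tgt, s - 1, s - 1) == m8c
    has_a <- s + 6 <= L && substr(tgt, s + 6, s + 6) == "A"
    type <- if (has_m8 && has_a) "8mer" else if (has_m8) "7mer-m8"
    else if (has_a) "7mer-A1" else "6mer"
    counts[type] <- counts[type] + 1L
  }
  counts
}

# Exact hypergeometric upper tail by direct combinatorial summation.
hypergeom_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
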
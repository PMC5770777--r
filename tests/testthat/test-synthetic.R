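test_that("a minimal family has the expected structure", {
  p <- sim_params(n_families = 1, family_sizes = 3, extension_prob = 0,
                  rng_seed = 1)
  ped <- simulate_pedigrees(p)
  expect_equal(nrow(ped), 3)
  founders <- ped$individual_id[ped$father_id == "0"]
  child <- ped[ped$father_id != "0", ]
  expect_length(founders, 2)
  expect_true(child$father_id %in% founders)
  expect_true(child$mother_id %in% founders)
})

test_that("the generator is deterministic given its seed", {
  p <- sim_params(n_families = 10, n_mirna = 8, n_mrna = 12,
                  n_coupled_pairs = 4, rng_seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$ped, b$ped)
  expect_identical(a$phen, b$phen)
  expect_identical(a$ct, b$ct)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$sequences$mirna_fasta, b$sequences$mirna_fasta)
  expect_identical(a$sequences$region_fasta, b$sequences$region_fasta)
  c <- simulate_cohort(sim_params(n_families = 10, n_mirna = 8,
                                  n_mrna = 12, n_coupled_pairs = 4,
                                  rng_seed = 100))
  expect_false(identical(a$ct, c$ct))
})

test_that("total cohort size stays within the family-size bounds", {
  p <- sim_params(n_families = 300, family_sizes = 3:6,
                  extension_prob = 0, rng_seed = 3)
  ped <- simulate_pedigrees(p)
  expect_gte(nrow(ped), 900)
  expect_lte(nrow(ped), 1800)
})

test_that("a single-cohort age mixture matches its configured mean", {
  p <- sim_params(n_families = 250, cohort_frac_old = 1, rng_seed = 4)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  se <- p$age_sd_old / sqrt(nrow(phen))
  expect_lt(abs(mean(phen$age) - 66), 3 * se)
  expect_true(all(phen$age > 0))
})

test_that("survival respects the follow-up horizon and the null hazard case", {
  p <- sim_params(n_families = 200, log_hr_delta = 0, rng_seed = 5)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  expect_true(all(phen$surv_time <= p$followup_years))
  expect_true(all(phen$surv_time[phen$surv_event == 1] <=
                    p$followup_years))
  expect_true(all(phen$surv_time >= 0))
  # with zero delta effect, a Cox fit on the true delta is null
  tru <- attr(phen, "truth")$delta
  cx <- cox_fit(phen$surv_time, phen$surv_event,
                cbind(delta = tru, age = phen$age))
  row <- cx$table[cx$table$term == "delta", ]
  expect_lt(abs(row$log_hr), 3 * row$se)
})

test_that("binary phenotype fields are 0/1 and treatments imply disease", {
  p <- sim_params(n_families = 60, rng_seed = 6)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  for (col in c("smoker", "chd", "hypertension", "diabetes", "rx_htn",
                "rx_dm", "rx_lipid", "surv_event"))
    expect_true(all(phen[[col]] %in% 0:1), label = col)
  expect_true(all(phen$hypertension[phen$rx_htn == 1] == 1))
})

test_that("an all-null Ct panel shows only chance age associations", {
  p <- sim_params(n_families = 150, n_mirna = 40, frac_age_affected = 0,
                  mirna_h2 = 0, n_mirna_factors = 0, program_sd = 0,
                  baseline_range = c(15, 20), near_limit_frac = 0,
                  rng_seed = 7)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  ct <- simulate_mirna_ct(ped, phen, p)
  expect_true(all(attr(ct, "truth")$beta_age == 0))
  pvals <- apply(ct, 2, function(y) cor.test(y, phen$age)$p.value)
  # fraction under 0.05 within binomial 99% bounds of the nominal level
  bound <- 2.576 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), bound + 0.5 / length(pvals))
})

test_that("a baseline above the detection limit censors the whole column", {
  p <- sim_params(n_families = 20, n_mirna = 3,
                  baseline_range = c(35, 35), near_limit_frac = 0,
                  frac_age_affected = 0, mirna_h2 = 0,
                  n_mirna_factors = 0, program_sd = 0,
                  tech_frac_range = c(0.01, 0.02), rng_seed = 8)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  ct <- simulate_mirna_ct(ped, phen, p)
  expect_true(all(is.na(ct)))
})

test_that("the planted expression-age sign convention matches the Ct scale", {
  co <- small_cohort()
  tr <- attr(co$ct, "truth")
  aff <- tr$affected
  expect_gt(mean(tr$beta_age[aff] > 0), 0.5)  # mostly declining expression
  expect_true(all(tr$beta_age[!aff] == 0))
})

test_that("phenotype mismatch is reported", {
  p <- sim_params(n_families = 5, rng_seed = 9)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  expect_error(simulate_mirna_ct(ped, phen[-1, ], p),
               "do not cover")
})

test_that("cell proportions lie on the simplex and couplings are recoverable", {
  co <- small_cohort()
  expect_lt(max(abs(rowSums(co$cells) - 1)), 1e-12)
  expect_true(all(co$coupling$mirna %in% colnames(co$ct)))
  expect_true(all(co$coupling$mrna %in% colnames(co$mrna)))
  # coupling to an unknown miRNA errors
  p <- co$params
  bad <- data.frame(mirna = "nope", mrna = colnames(co$mrna)[1],
                    strength = 1)
  expect_error(simulate_mrna_and_cells(co$ct, p, coupling = bad),
               "unknown miRNA")
})

test_that("a null mRNA generator shows only chance miRNA associations", {
  p <- sim_params(n_families = 120, n_mirna = 10, n_mrna = 40,
                  n_coupled_pairs = 1, n_mrna_factors = 0,
                  rng_seed = 10)
  ped <- simulate_pedigrees(p)
  phen <- simulate_phenotypes(ped, p)
  ct <- simulate_mirna_ct(ped, phen, p)
  nullmap <- data.frame(mirna = character(0), mrna = character(0),
                        strength = numeric(0))
  mr <- simulate_mrna_and_cells(ct, p, coupling = nullmap)
  ctf <- apply(ct, 2, function(x) ifelse(is.na(x), mean(x, na.rm = TRUE),
                                         x))
  pv <- as.vector(vapply(seq_len(ncol(mr$mrna)), function(g)
    vapply(seq_len(ncol(ctf)), function(j)
      cor.test(mr$mrna[, g], ctf[, j])$p.value, numeric(1)),
    numeric(ncol(ctf))))
  bound <- 2.576 * sqrt(0.05 * 0.95 / length(pv))
  expect_lt(abs(mean(pv < 0.05) - 0.05), bound + 0.5 / length(pv))
})

test_that("sequence simulation plants retrievable sites and is deterministic", {
  co <- small_cohort()
  sq <- co$sequences
  expect_true(!is.null(sq$planted))
  # every planted pair has at least one 8mer in the recorded 3UTR
  for (r in seq_len(min(5, nrow(sq$planted)))) {
    pl <- sq$planted[r, ]
    tgt <- sq$region_fasta[[paste0(pl$transcript, "|3UTR")]]
    rep <- seed_sites(sq$mirna_fasta[[pl$mirna]], tgt)
    expect_gte(attr(rep, "counts")[["8mer"]], 1)
  }
  sq2 <- simulate_sequences(co$params, co$coupling)
  expect_identical(sq$region_fasta, sq2$region_fasta)
})

test_that("background 6mer counts match the closed-form expectation", {
  set.seed(11)
  L <- 2000
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  n_rep <- 200
  counts <- replicate(n_rep, {
    tgt <- random_dna(L)
    total <- sum(attr(seed_sites(mir, tgt), "counts"))
    total
  })
  expected <- (L - 5) * 4^-6
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.01)
})

test_that("cohort round trip through disk preserves the matrices", {
  co <- small_cohort()
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  ct2 <- read_matrix_tsv(file.path(dir, "mirna_ct.tsv"))
  expect_equal(ct2, unclass(co$ct), tolerance = 1e-9, ignore_attr = TRUE)
  ped2 <- read_pedigree_tsv(file.path(dir, "pedigree.tsv"))
  expect_equal(ped2, co$ped)
  truth <- utils::read.delim(file.path(dir, "truth_mirna.tsv"))
  expect_equal(truth$beta_age, unname(attr(co$ct, "truth")$beta_age),
               tolerance = 1e-9)
  seqs <- read_fasta(file.path(dir, "mirna.fa"))
  expect_identical(seqs, co$sequences$mirna_fasta)
  unlink(dir, recursive = TRUE)
})
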
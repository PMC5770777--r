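# Reverse complement of a plain DNA string.
.revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Canonical seed-match sites of a miRNA in a target sequence
#'
#' The seed is miRNA positions 2-8 (5'->3'). Sites are searched on the
#' target's sense strand only: a match to the reverse complement of seed
#' positions 2-7 is the 6mer core; extending it by the complement of seed
#' position 8 upstream gives the 7mer-m8, by an A downstream (opposite
#' miRNA position 1) the 7mer-A1, and by both the 8mer. Each core
#' occurrence is classified once, as its most specific applicable type.
#' U and T are treated as equivalent; matching uses Biostrings so
#' overlapping core occurrences are all found.
#'
#' @param mirna_seq mature miRNA sequence (RNA or DNA alphabet, length >=
#'   8).
#' @param target_seq target sequence (DNA or RNA alphabet).
#' @return data.frame of class `seed_site_report`: `type` (one of
#'   `8mer`, `7mer-m8`, `7mer-A1`, `6mer`), `start`, `end` (0-based,
#'   half-open, spanning the full matched site); attribute `"counts"`
#'   carries the per-type totals.
#' @export
seed_sites <- function(mirna_seq, target_seq) {
  mir <- toupper(chartr("u", "U", mirna_seq))
  tgt <- toupper(target_seq)
  mir <- chartr("U", "T", mir); tgt <- chartr("U", "T", tgt)
  if (grepl("[^ACGT]", mir) || grepl("[^ACGT]", tgt))
    stop("sequences must be over {A, C, G, T/U}")
  if (nchar(mir) < 8) stop("miRNA sequence must be at least 8 nt")
  seed27 <- substr(mir, 2, 7)
  s8 <- substr(mir, 8, 8)
  core <- .revcomp_dna(seed27)                 # 6mer site string
  m8c <- chartr("ACGT", "TGCA", s8)            # complement of position 8
  types <- character(0); starts <- integer(0); ends <- integer(0)
  L <- nchar(tgt)
  if (L >= 6) {
    hits <- Biostrings::matchPattern(core, Biostrings::DNAString(tgt))
    for (s in Biostrings::start(hits)) {       # 1-based core start
      has_m8 <- s >= 2 && substr(tgt, s - 1, s - 1) == m8c
      has_a <- s + 6 <= L && substr(tgt, s + 6, s + 6) == "A"
      if (has_m8 && has_a) {
        types <- c(types, "8mer"); starts <- c(starts, s - 2L)
        ends <- c(ends, s + 6L)
      } else if (has_m8) {
        types <- c(types, "7mer-m8"); starts <- c(starts, s - 2L)
        ends <- c(ends, s + 5L)
      } else if (has_a) {
        types <- c(types, "7mer-A1"); starts <- c(starts, s - 1L)
        ends <- c(ends, s + 6L)
      } else {
        types <- c(types, "6mer"); starts <- c(starts, s - 1L)
        ends <- c(ends, s + 5L)
      }
    }
  }
  out <- data.frame(type = types, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  lev <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  counts <- stats::setNames(tabulate(factor(out$type, levels = lev),
                                     nbins = 4L), lev)
  structure(out, counts = counts,
            class = c("seed_site_report", "data.frame"))
}

#' Seed-site report over miRNA and transcript-region FASTA sets
#'
#' Runs [seed_sites()] for every (miRNA, region) combination. Region names
#' follow the `transcript|region` header convention.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param region_seqs named character vector of target regions
#'   (`transcript|region` names).
#' @param pairs optional data.frame (`mirna`, `mrna`) restricting the scan
#'   to given pairs (any region of the transcript).
#' @return data.frame: `mirna`, `transcript`, `region`, and per-type site
#'   counts (`n_8mer`, `n_7mer_m8`, `n_7mer_a1`, `n_6mer`).
#' @export
seed_site_report <- function(mirna_seqs, region_seqs, pairs = NULL) {
  split_names <- strsplit(names(region_seqs), "|", fixed = TRUE)
  transcripts <- vapply(split_names, `[`, "", 1)
  regions <- vapply(split_names, function(x)
    if (length(x) > 1) x[2] else "all", character(1))
  combos <- if (is.null(pairs)) {
    expand.grid(mirna = names(mirna_seqs), region_idx =
                  seq_along(region_seqs), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      ri <- which(transcripts == pairs$mrna[r])
      if (!length(ri)) return(NULL)
      data.frame(mirna = pairs$mirna[r], region_idx = ri,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(combos) || !nrow(combos)) return(NULL)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mi <- combos$mirna[i]; ri <- combos$region_idx[i]
    cnt <- attr(seed_sites(mirna_seqs[[mi]], region_seqs[[ri]]), "counts")
    data.frame(mirna = mi, transcript = transcripts[ri],
               region = regions[ri],
               n_8mer = cnt[["8mer"]], n_7mer_m8 = cnt[["7mer-m8"]],
               n_7mer_a1 = cnt[["7mer-A1"]], n_6mer = cnt[["6mer"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call predicted targets from a seed-site report
#'
#' A (miRNA, transcript) pair is a predicted target if any of its regions
#' carries at least one site of the requested types.
#'
#' @param report output of [seed_site_report()].
#' @param types site types that qualify (default: all canonical types
#'   except the bare 6mer).
#' @return data.frame of unique predicted (`mirna`, `transcript`) pairs.
#' @export
predicted_targets <- function(report,
                              types = c("8mer", "7mer-m8", "7mer-A1")) {
  cols <- c(`8mer` = "n_8mer", `7mer-m8` = "n_7mer_m8",
            `7mer-A1` = "n_7mer_a1", `6mer` = "n_6mer")[types]
  hit <- rowSums(report[, cols, drop = FALSE]) > 0
  unique(report[hit, c("mirna", "transcript")])
}
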
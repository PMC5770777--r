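#' Read or write a numeric sample-by-feature matrix as TSV
#'
#' Matrices are stored with samples as rows; the first column (`sample_id`)
#' holds sample identifiers and the header carries feature (miRNA or mRNA)
#' identifiers. Missing values are written as `NA`.
#'
#' @param x numeric matrix with rownames (sample ids) and colnames (features).
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read or write a phenotype/covariate table as TSV
#'
#' @param phen data.frame with a `sample_id` column.
#' @param path file path.
#' @return `read_phenotypes_tsv` returns a data.frame.
#' @export
write_phenotypes_tsv <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read or write a pedigree as TSV
#'
#' Columns: `pedigree_id`, `individual_id`, `father_id`, `mother_id`, `sex`;
#' the founder marker is `"0"`.
#'
#' @param ped pedigree data.frame (see [simulate_pedigrees()]).
#' @param path file path.
#' @return `read_pedigree_tsv` returns a validated pedigree data.frame.
#' @export
write_pedigree_tsv <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  ped <- utils::read.delim(path, colClasses = "character")
  validate_pedigree(ped)
  ped
}

#' Read or write a kinship matrix in long TSV format
#'
#' Long format columns: `id1`, `id2`, `value` (expected relationship, i.e.
#' twice the kinship coefficient); only the lower triangle including the
#' diagonal is stored.
#'
#' @param K kinship (relationship) matrix with dimnames.
#' @param path file path.
#' @return `read_kinship_tsv` returns a symmetric matrix.
#' @export
write_kinship_tsv <- function(K, path) {
  idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = rownames(K)[idx[, 1]], id2 = colnames(K)[idx[, 2]],
                   value = K[idx], stringsAsFactors = FALSE)
  df <- df[df$value != 0 | df$id1 == df$id2, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(c(df$id1, df$id2))
  K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  K[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$value
  K[cbind(match(df$id2, ids), match(df$id1, ids))] <- df$value
  K
}

#' Read or write FASTA sequence sets
#'
#' Thin wrappers over Biostrings; sequences are returned as a named
#' character vector so downstream seed matching works on plain strings.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
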
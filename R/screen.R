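#' Screen reads against a contaminant reference set
#'
#' A read matches a contaminant if it aligns somewhere on either strand with
#' at most `floor(max_mismatch_frac * read_length)` substitutions (no gaps:
#' the screen targets near-exact contaminant copies, by design insensitive to
#' divergent strains). Matching is seed-and-extend -- exact seeds of
#' `seed_length`, Hamming verification at each candidate diagonal -- and is
#' exact: the seed layout guarantees a clean seed within the mismatch budget,
#' with an exhaustive fallback for reads too short to guarantee it. A pair is
#' removed when either mate matches (keeps output files properly paired).
#'
#' @param reads A `read_set`.
#' @param contaminant_refs Named character vector or `DNAStringSet` of
#'   contaminant reference sequences.
#' @param max_mismatch_frac Mismatch budget as a fraction of read length
#'   (default 0.02), in `[0, 0.1)`.
#' @param seed_length Exact seed length (default 31).
#' @param pair_removal Remove the whole pair when either mate matches
#'   (default `TRUE`); otherwise both mates must match.
#' @return List with `kept` and `removed` (`read_set`s partitioning the
#'   input) and `report` (a [contamination_report()] data frame).
#' @export
screen_reads <- function(reads, contaminant_refs, max_mismatch_frac = 0.02,
                         seed_length = 31, pair_removal = TRUE) {
  if (inherits(contaminant_refs, "DNAStringSet"))
    contaminant_refs <- stats::setNames(as.character(contaminant_refs),
                                        names(contaminant_refs))
  if (length(contaminant_refs) == 0) stop("contaminant reference set is empty")
  if (is.null(names(contaminant_refs)))
    names(contaminant_refs) <- paste0("contaminant_", seq_along(contaminant_refs))
  refs <- toupper(unname(contaminant_refs))
  m1 <- cpp_screen(toupper(reads$r1), refs, as.integer(seed_length),
                   max_mismatch_frac)
  m2 <- cpp_screen(toupper(reads$r2), refs, as.integer(seed_length),
                   max_mismatch_frac)
  hit <- if (pair_removal) m1 > 0 | m2 > 0 else m1 > 0 & m2 > 0
  who <- ifelse(m1 > 0, m1, m2)
  assignments <- table(factor(names(contaminant_refs)[who[hit]],
                              levels = names(contaminant_refs)))
  report <- contamination_report(assignments, total_screened = n_pairs(reads))
  attr(report, "kept") <- sum(!hit)
  attr(report, "removed") <- sum(hit)
  list(kept = subset_read_set(reads, !hit),
       removed = subset_read_set(reads, hit),
       report = report)
}

#' Trim reads to a fixed length
#'
#' Truncates every read (and its qualities) to its first `length` bases, the
#' fixed-length trim used to discard the low-quality tail cycles of long
#' Illumina reads before assembly. Reads already shorter than `length` pass
#' unchanged. Truth origins of reverse-strand mates are shifted so they keep
#' describing the retained bases.
#'
#' @param reads A `read_set`.
#' @param length Target length in bases (default 150).
#' @return A `read_set`.
#' @export
trim_reads <- function(reads, length = 150) {
  if (length <= 0) stop("trim length must be positive")
  out <- reads
  old <- nchar(reads$r1)
  out$r1 <- substr(reads$r1, 1, length)
  out$q1 <- substr(reads$q1, 1, length)
  out$r2 <- substr(reads$r2, 1, length)
  out$q2 <- substr(reads$q2, 1, length)
  # mate 2 is reverse-strand: its kept prefix covers the end of its origin window
  shift <- pmax(nchar(reads$r2) - length, 0)
  out$origin$start2 <- reads$origin$start2 + shift
  out$read_length <- min(length, max(old))
  out
}

#' Contamination report arithmetic
#'
#' Per-contaminant read counts as percentages of the reads screened, rounded
#' to two decimals and sorted by percentage descending.
#'
#' @param assignments Named counts (table or named numeric) of reads covered
#'   per contaminant, or a character vector of per-read labels.
#' @param total_screened Total reads (or pairs) screened; must be positive
#'   and at least the sum of assignments.
#' @return Data frame of class `screen_report`: `name`, `reads_covered`,
#'   `pct_of_screened`.
#' @examples
#' contamination_report(c(bug = 393081), 5e6)  # 7.86
#' @export
contamination_report <- function(assignments, total_screened) {
  if (total_screened <= 0) stop("total_screened must be positive")
  if (is.character(assignments)) assignments <- table(assignments)
  counts <- as.numeric(assignments)
  if (sum(counts) > total_screened)
    stop("assigned reads exceed total screened")
  df <- data.frame(name = names(assignments), reads_covered = counts,
                   pct_of_screened = round(100 * counts / total_screened, 2),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$pct_of_screened, df$name), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "total_screened") <- total_screened
  class(df) <- c("screen_report", "data.frame")
  df
}

#' Write a contamination report as TSV
#' @param report A [contamination_report()].
#' @param path File path.
#' @export
write_screen_report <- function(report, path) {
  df <- data.frame(Species = report$name,
                   `pct.reads.covered` = report$pct_of_screened,
                   `No.reads.covered` = report$reads_covered,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
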
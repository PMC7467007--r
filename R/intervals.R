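#' Genomic interval sets (0-based, half-open)
#'
#' An `interval_set` is the package's light container for per-sequence genomic
#' intervals. Intervals are stored 0-based half-open (the BED convention used
#' everywhere internally; VCF output is the only 1-based surface) and are
#' normalized on construction: sorted, with overlapping or abutting intervals
#' merged per sequence. All algebra is delegated to [IRanges::IRanges-class]
#' under the hood.
#'
#' @param seqid Character vector of sequence identifiers.
#' @param start,end Integer vectors, 0-based half-open (`start < end`).
#' @return A data frame of class `interval_set` with columns `seqid`, `start`,
#'   `end`, normalized.
#' @examples
#' interval_set("chr1", c(0L, 50L), c(100L, 150L))  # merges into [0, 150)
#' @export
interval_set <- function(seqid = character(), start = integer(), end = integer()) {
  if (length(seqid) == 1 && length(start) > 1) seqid <- rep(seqid, length(start))
  stopifnot(length(seqid) == length(start), length(start) == length(end))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("interval starts must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  df <- data.frame(seqid = as.character(seqid), start = start, end = end,
                   stringsAsFactors = FALSE)
  normalize_iset(df)
}

normalize_iset <- function(df) {
  if (nrow(df) > 0) {
    parts <- lapply(split(df, df$seqid), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
      data.frame(seqid = d$seqid[1], start = IRanges::start(ir) - 1,
                 end = IRanges::end(ir), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
    df <- df[order(df$seqid, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @rdname interval_set
#' @param x Object to coerce (data frame with seqid/start/end columns, or a
#'   `GRanges`).
#' @export
as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  if (inherits(x, "GRanges")) {
    return(interval_set(as.character(GenomicRanges::seqnames(x)),
                        GenomicRanges::start(x) - 1, GenomicRanges::end(x)))
  }
  if (is.data.frame(x)) return(interval_set(x$seqid, x$start, x$end))
  stop("cannot coerce to interval_set")
}

iset_to_granges <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$seqid, IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Total length of an interval set
#'
#' @param x An `interval_set`.
#' @return Total number of bases covered (a double, since genome-scale sums can
#'   exceed integer range).
#' @export
total_length <- function(x) {
  x <- as_interval_set(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

#' Interval algebra
#'
#' Standard set operations on normalized interval sets: `merge` (union),
#' `subtract` (every base of `b` removed from `a`) and `intersect`.
#'
#' @param a,b `interval_set` objects (or coercible).
#' @param op One of `"merge"`, `"subtract"`, `"intersect"`.
#' @return A normalized `interval_set`.
#' @examples
#' a <- interval_set("s", 0L, 100L)
#' b <- interval_set("s", 40L, 60L)
#' interval_ops(a, b, "subtract")  # [0,40), [60,100)
#' @export
interval_ops <- function(a, b, op = c("merge", "subtract", "intersect")) {
  op <- match.arg(op)
  a <- as_interval_set(a)
  b <- as_interval_set(b)
  ga <- iset_to_granges(a)
  gb <- iset_to_granges(b)
  res <- switch(op,
    merge = GenomicRanges::reduce(c(ga, gb)),
    subtract = GenomicRanges::setdiff(ga, gb),
    intersect = GenomicRanges::intersect(ga, gb))
  as_interval_set(res)
}

#' @rdname interval_ops
#' @export
interval_merge <- function(a, b) interval_ops(a, b, "merge")

#' @rdname interval_ops
#' @export
interval_subtract <- function(a, b) interval_ops(a, b, "subtract")

#' @rdname interval_ops
#' @export
interval_intersect <- function(a, b) interval_ops(a, b, "intersect")

#' Membership of point positions in an interval set
#'
#' @param x An `interval_set`.
#' @param seqid,pos Vectors of sequence ids and 0-based positions.
#' @return Logical vector: is each position covered by `x`?
#' @export
positions_in_intervals <- function(x, seqid, pos) {
  x <- as_interval_set(x)
  if (length(pos) == 0) return(logical(0))
  if (nrow(x) == 0) return(rep(FALSE, length(pos)))
  g <- GenomicRanges::GRanges(as.character(seqid),
                              IRanges::IRanges(start = pos + 1, width = 1))
  # disjoint sequence names simply mean "not covered"
  suppressWarnings(GenomicRanges::countOverlaps(g, iset_to_granges(x)) > 0)
}

#' Read / write interval sets as BED
#'
#' Three-column BED (0-based half-open), via [rtracklayer::import.bed()] and
#' [rtracklayer::export.bed()].
#'
#' @param x An `interval_set`.
#' @param path File path.
#' @return `read_bed` returns an `interval_set`; `write_bed` returns `path`
#'   invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_set(x)
  rtracklayer::export.bed(iset_to_granges(x), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  as_interval_set(rtracklayer::import.bed(path))
}
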
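assembly_seqs <- function(assembly) {
  if (inherits(assembly, "sim_assembly")) return(assembly$seqs)
  if (inherits(assembly, "DNAStringSet"))
    return(stats::setNames(as.character(assembly), names(assembly)))
  if (is.character(assembly)) {
    if (is.null(names(assembly)))
      names(assembly) <- paste0("seq_", seq_along(assembly))
    return(assembly)
  }
  stop("cannot interpret assembly input")
}

# contig lengths after splitting scaffolds at runs of >= gap_run_min Ns
contig_lengths <- function(seqs, gap_run_min) {
  pat <- sprintf("N{%d,}", gap_run_min)
  unlist(lapply(seqs, function(s) {
    parts <- strsplit(gsub(pat, "\n", toupper(s)), "\n", fixed = TRUE)[[1]]
    lens <- nchar(parts)
    lens[lens > 0]
  }), use.names = FALSE)
}

nx_scan <- function(lengths, xs) {
  lengths <- sort(lengths, decreasing = TRUE)
  total <- sum(lengths)
  cum <- cumsum(lengths)
  idx <- vapply(xs, function(x) {
    if (x >= 100) return(length(lengths))
    which(cum > x / 100 * total)[1]
  }, 1L)
  data.frame(x = xs, length = lengths[idx], count = idx)
}

#' Assembly contiguity (Nx) table
#'
#' Computes, for x in 0..100 by `step`, the Nx length (the length of the
#' sequence at which the cumulative descending-sorted length first exceeds x%
#' of the total; N0 is the longest sequence and N100 the shortest) and the
#' number of sequences up to and including it -- separately for scaffolds
#' (the input sequences) and contigs (scaffolds split at runs of at least
#' `gap_run_min` Ns).
#'
#' @param assembly Assembly sequences (named character, `DNAStringSet` or
#'   `sim_assembly`).
#' @param gap_run_min Minimum N-run length splitting a scaffold into contigs.
#' @param step Step of the x grid.
#' @return Data frame of class `nx_table` (`x`, `contig_length`,
#'   `contig_count`, `scaffold_length`, `scaffold_count`) with a `totals`
#'   attribute.
#' @export
nx_table <- function(assembly, gap_run_min = 10, step = 5) {
  seqs <- assembly_seqs(assembly)
  if (length(seqs) == 0) stop("assembly is empty")
  scaf_len <- nchar(seqs)
  ctg_len <- contig_lengths(seqs, gap_run_min)
  xs <- seq(0, 100, by = step)
  sc <- nx_scan(scaf_len, xs)
  ct <- nx_scan(ctg_len, xs)
  out <- data.frame(x = xs,
                    contig_length = ct$length, contig_count = ct$count,
                    scaffold_length = sc$length, scaffold_count = sc$count)
  attr(out, "totals") <- data.frame(
    contig_length = sum(ctg_len), contig_count = length(ctg_len),
    scaffold_length = sum(scaf_len), scaffold_count = length(scaf_len))
  class(out) <- c("nx_table", "data.frame")
  out
}

#' Write an Nx table as TSV
#' @param nx An [nx_table()].
#' @param path File path.
#' @export
write_nx_table <- function(nx, path) {
  tot <- attr(nx, "totals")
  df <- data.frame(Nx = c(paste0("N", nx$x), "Total"),
                   contig_length = c(nx$contig_length, tot$contig_length),
                   contig_number = c(nx$contig_count, tot$contig_count),
                   scaffold_length = c(nx$scaffold_length, tot$scaffold_length),
                   scaffold_number = c(nx$scaffold_count, tot$scaffold_count))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-scaffold read depth from alignments
#'
#' Builds per-base depth tracks (one run-length-encoded vector per scaffold)
#' from an alignment table, for coverage-based scaffold classification.
#'
#' @param alignments Data frame with `seqid`, `start` (0-based) and `seq`
#'   columns (e.g. from [route_reads_to_assembly()]).
#' @param reference Assembly the alignments refer to (for scaffold lengths).
#' @return Named list of [S4Vectors::Rle] depth vectors.
#' @export
depth_from_alignments <- function(alignments, reference) {
  seqs <- assembly_seqs(reference)
  lens <- nchar(seqs)
  out <- stats::setNames(vector("list", length(seqs)), names(seqs))
  by_seq <- split(alignments, factor(alignments$seqid, levels = names(seqs)))
  for (nm in names(seqs)) {
    a <- by_seq[[nm]]
    if (is.null(a) || nrow(a) == 0) {
      out[[nm]] <- S4Vectors::Rle(0L, lens[[nm]])
    } else {
      ir <- IRanges::IRanges(start = a$start + 1, width = nchar(a$seq))
      out[[nm]] <- IRanges::coverage(ir, width = lens[[nm]])
    }
  }
  out
}

#' Histogram of per-base depth over an assembly
#'
#' @param depth Named list of per-scaffold depth vectors
#'   ([depth_from_alignments()]).
#' @param max_depth Pooling bound.
#' @return Data frame `depth` (1..`max_depth`), `count` (bases at that depth;
#'   depth-0 bases are not represented).
#' @export
depth_histogram <- function(depth, max_depth = 400) {
  acc <- numeric(max_depth)
  for (d in depth) {
    v <- pmin(as.integer(d), max_depth)
    t <- tabulate(v[v > 0], nbins = max_depth)
    acc <- acc + t
  }
  data.frame(depth = seq_len(max_depth), count = acc)
}

#' Find low/midpoint/high coverage cut-offs from a depth histogram
#'
#' Locates the haploid-depth and diploid-depth modes of a (typically bimodal)
#' per-base coverage histogram. The midpoint is the valley between the two
#' modes; the low and high cut-offs are where the histogram falls below
#' `boundary_frac` of the respective mode height, scanning outward. With a
#' unimodal histogram the midpoint is placed at the mode and a warning is
#' emitted. Explicit values override detection and are returned verbatim.
#'
#' @param hist Data frame `depth`, `count` (e.g. [depth_histogram()]).
#' @param low,midpoint,high Optional explicit cut-offs.
#' @param boundary_frac Mode-height fraction defining the outer boundaries.
#' @param smooth_window Moving-average window.
#' @return List of class `coverage_cutoffs`: `low`, `midpoint`, `high`.
#' @export
find_coverage_cutoffs <- function(hist, low = NULL, midpoint = NULL,
                                  high = NULL, boundary_frac = 0.1,
                                  smooth_window = 5) {
  if (!is.null(low) && !is.null(midpoint) && !is.null(high)) {
    if (!(low < midpoint && midpoint < high))
      stop("cut-offs must satisfy low < midpoint < high")
    return(structure(list(low = low, midpoint = midpoint, high = high),
                     class = "coverage_cutoffs"))
  }
  if (nrow(hist) == 0 || sum(hist$count) == 0) stop("empty depth histogram")
  y <- smooth_counts(hist$count, smooth_window)
  n <- length(y)
  is_max <- vapply(seq_len(n), function(d) {
    left <- if (d == 1) -Inf else y[d - 1]
    right <- if (d == n) -Inf else y[d + 1]
    y[d] >= left && y[d] > right
  }, TRUE)
  peaks <- which(is_max & y >= 0.05 * max(y))
  scan_boundary <- function(mode, dir) {
    d <- mode
    while (d + dir >= 1 && d + dir <= n && y[d + dir] >= boundary_frac * y[mode])
      d <- d + dir
    max(1, d + dir)
  }
  if (length(peaks) >= 2) {
    top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
    m1 <- min(top2); m2 <- max(top2)
    valley <- (m1:m2)[which.min(y[m1:m2])]
    cuts <- list(low = scan_boundary(m1, -1L), midpoint = valley,
                 high = scan_boundary(m2, +1L))
  } else {
    m <- peaks[1]
    warning("unimodal depth histogram; midpoint placed at the single mode")
    cuts <- list(low = scan_boundary(m, -1L), midpoint = m,
                 high = scan_boundary(m, +1L))
  }
  if (!is.null(low)) cuts$low <- low
  if (!is.null(midpoint)) cuts$midpoint <- midpoint
  if (!is.null(high)) cuts$high <- high
  cuts$low <- min(cuts$low, cuts$midpoint - 1)
  cuts$high <- max(cuts$high, cuts$midpoint + 1)
  structure(cuts, class = "coverage_cutoffs")
}

#' @export
print.coverage_cutoffs <- function(x, ...) {
  cat(sprintf("coverage cut-offs: low = %s, midpoint = %s, high = %s\n",
              x$low, x$midpoint, x$high))
  invisible(x)
}

#' Flag scaffolds as junk/suspect/keep from per-base coverage
#'
#' A scaffold is `junk` when at least `junk_frac` of its bases lie below the
#' low or above the high cut-off; otherwise `suspect` (candidate haplotig)
#' when at least `suspect_frac` of its bases fall in the haploid-depth band
#' `[low, midpoint)`; otherwise `keep`. Every scaffold receives exactly one
#' flag.
#'
#' @param depth Named list of per-scaffold depth vectors; every scaffold must
#'   be present.
#' @param cutoffs A [find_coverage_cutoffs()] result.
#' @param junk_frac,suspect_frac Base-fraction thresholds (default 0.8).
#' @param scaffolds Scaffold names to classify (default: all in `depth`).
#' @return Data frame `scaffold`, `flag`, `frac_outside`, `frac_haploid`,
#'   `mean_depth`.
#' @export
classify_scaffolds_by_coverage <- function(depth, cutoffs, junk_frac = 0.8,
                                           suspect_frac = 0.8,
                                           scaffolds = names(depth)) {
  missing <- setdiff(scaffolds, names(depth))
  if (length(missing) > 0)
    stop("no depth track for scaffold(s): ", paste(missing, collapse = ", "))
  rows <- lapply(scaffolds, function(nm) {
    d <- as.integer(depth[[nm]])
    f_out <- mean(d < cutoffs$low | d > cutoffs$high)
    f_hap <- mean(d >= cutoffs$low & d < cutoffs$midpoint)
    flag <- if (f_out >= junk_frac) "junk"
            else if (f_hap >= suspect_frac) "suspect"
            else "keep"
    data.frame(scaffold = nm, flag = flag, frac_outside = f_out,
               frac_haploid = f_hap, mean_depth = mean(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop flagged scaffolds from an assembly
#'
#' @param assembly Assembly sequences.
#' @param flags A [classify_scaffolds_by_coverage()] (or
#'   [flag_contaminant_scaffolds()]) result.
#' @param drop Flags to remove.
#' @return Named character vector of retained scaffolds.
#' @export
purge_scaffolds <- function(assembly, flags,
                            drop = c("junk", "suspect", "contaminant")) {
  seqs <- assembly_seqs(assembly)
  bad <- flags$scaffold[flags$flag %in% drop]
  seqs[setdiff(names(seqs), bad)]
}

#' Flag contaminant scaffolds by majority vote over annotation criteria
#'
#' Combines the available retention criteria -- gene-level taxonomic hits, GC
#' content against the host band, presence of expression and of host-specific
#' repeats -- by majority vote; missing values abstain and ties retain the
#' scaffold. The host GC band defaults to median +/- `gc_mad_mult` * MAD of
#' all scaffolds, re-estimated once on the scaffolds inside the initial band.
#'
#' @param criteria Data frame with columns `scaffold`, `gc` (fraction),
#'   `foreign_gene_hits`, `host_gene_hits` (counts), `has_expression`,
#'   `has_species_repeats` (logical). `NA`s abstain.
#' @param gc_band Optional numeric `c(lo, hi)` overriding the fitted band.
#' @param gc_mad_mult MAD multiplier for the fitted band.
#' @return Data frame `scaffold`, `flag` (`contaminant`/`keep`),
#'   `votes_contaminant`, `votes_host`, plus the band as attribute `gc_band`.
#' @export
flag_contaminant_scaffolds <- function(criteria, gc_band = NULL,
                                       gc_mad_mult = 3) {
  if (nrow(criteria) == 0) stop("empty criteria table")
  if (is.null(gc_band)) {
    fit_band <- function(gc) {
      m <- median(gc, na.rm = TRUE)
      s <- mad(gc, na.rm = TRUE)
      c(m - gc_mad_mult * s, m + gc_mad_mult * s)
    }
    band <- fit_band(criteria$gc)
    inside <- !is.na(criteria$gc) & criteria$gc >= band[1] & criteria$gc <= band[2]
    if (any(inside)) band <- fit_band(criteria$gc[inside])
    gc_band <- band
  }
  v_tax <- with(criteria, ifelse(is.na(foreign_gene_hits) | is.na(host_gene_hits) |
                                   (foreign_gene_hits + host_gene_hits) == 0, NA,
                                 ifelse(foreign_gene_hits > host_gene_hits, 1L,
                                        ifelse(foreign_gene_hits < host_gene_hits, -1L, NA))))
  v_gc <- ifelse(is.na(criteria$gc), NA,
                 ifelse(criteria$gc < gc_band[1] | criteria$gc > gc_band[2], 1L, -1L))
  v_expr <- ifelse(is.na(criteria$has_expression), NA,
                   ifelse(criteria$has_expression, -1L, 1L))
  v_rep <- ifelse(is.na(criteria$has_species_repeats), NA,
                  ifelse(criteria$has_species_repeats, -1L, 1L))
  votes <- cbind(v_tax, v_gc, v_expr, v_rep)
  n_c <- rowSums(votes == 1L, na.rm = TRUE)
  n_h <- rowSums(votes == -1L, na.rm = TRUE)
  out <- data.frame(scaffold = criteria$scaffold,
                    flag = ifelse(n_c > n_h, "contaminant", "keep"),
                    votes_contaminant = n_c, votes_host = n_h,
                    stringsAsFactors = FALSE)
  attr(out, "gc_band") <- gc_band
  out
}
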
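reference_seqs <- function(reference) {
  if (inherits(reference, "diploid_genome")) return(reference$hap_a)
  assembly_seqs(reference)
}

#' Build alignments from truth read placements
#'
#' Turns a simulated `read_set` into the alignment table consumed by
#' [pileup()]: against the diploid genome itself (haplotype A coordinates,
#' shared by both haplotypes since variants are SNVs only) or against a
#' fragmented assembly via [route_reads_to_assembly()]. Optionally removes
#' duplicate pairs -- pairs with an identical (haplotype, fragment start,
#' fragment length) signature, the truth-placement analogue of
#' duplicate-marking a BAM (default on).
#'
#' @param reads A `read_set`.
#' @param reference A `diploid_genome` or `sim_assembly`.
#' @param mapq Mapping quality to assign to every alignment.
#' @param dedup Drop duplicate pairs first (default `TRUE`).
#' @return Alignment data frame: `seqid`, `start` (0-based), `strand`, `seq`,
#'   `qual`, `mapq`.
#' @export
alignments_from_reads <- function(reads, reference, mapq = 60L, dedup = TRUE) {
  if (dedup) {
    sig <- paste(reads$origin$hap, reads$origin$seqid, reads$origin$start1,
                 reads$origin$frag)
    reads <- subset_read_set(reads, !duplicated(sig))
  }
  if (inherits(reference, "sim_assembly"))
    return(route_reads_to_assembly(reads, reference, mapq = mapq))
  host <- !is.na(reads$origin$hap)
  o <- reads$origin[host, , drop = FALSE]
  data.frame(seqid = c(o$seqid, o$seqid),
             start = c(o$start1, o$start2),
             strand = rep(c("+", "-"), each = nrow(o)),
             seq = c(reads$r1[host], reads$r2[host]),
             qual = c(reads$q1[host], reads$q2[host]),
             mapq = mapq, stringsAsFactors = FALSE)
}

#' Aggregated pileup of alignments over a reference
#'
#' Tallies, for every reference position, the A/C/G/T counts of bases passing
#' the base-quality threshold on reads passing the mapping-quality threshold
#' (the same thresholds later define callable sites; they are applied here
#' because the pileup is stored as aggregated counts rather than per-read
#' base lists). Minus-strand alignments are reverse-complemented into
#' reference orientation first.
#'
#' @param alignments Alignment data frame (`seqid`, `start` 0-based, `strand`,
#'   `seq`, `qual`, `mapq`).
#' @param reference Reference sequences (`diploid_genome` haplotype A,
#'   `sim_assembly`, named character or `DNAStringSet`).
#' @param min_base_quality,min_mapping_quality Quality thresholds (defaults
#'   10 and 20).
#' @return A list of class `pileup_set`: per-sequence 4 x L count matrices
#'   (`counts`), passing depth vectors (`depth`), the reference, and the
#'   thresholds.
#' @export
pileup <- function(alignments, reference, min_base_quality = 10,
                   min_mapping_quality = 20) {
  seqs <- reference_seqs(reference)
  lens <- nchar(seqs)
  if (nrow(alignments) > 0) {
    unknown <- setdiff(unique(alignments$seqid), names(seqs))
    if (length(unknown) > 0)
      stop("alignments reference unknown sequence(s): ",
           paste(unknown, collapse = ", "))
    minus <- alignments$strand == "-"
    if (any(minus)) {
      alignments$seq[minus] <- revcomp_chr(alignments$seq[minus])
      alignments$qual[minus] <-
        as.character(Biostrings::reverse(Biostrings::BStringSet(alignments$qual[minus])))
    }
  }
  mats <- cpp_pileup(as.integer(lens),
                     match(alignments$seqid, names(seqs)),
                     as.integer(alignments$start),
                     alignments$seq, alignments$qual,
                     as.integer(alignments$mapq),
                     as.integer(min_base_quality),
                     as.integer(min_mapping_quality))
  names(mats) <- names(seqs)
  mats <- lapply(mats, function(m) {
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
  structure(list(counts = mats,
                 depth = lapply(mats, colSums),
                 ref = seqs,
                 min_base_quality = min_base_quality,
                 min_mapping_quality = min_mapping_quality),
            class = "pileup_set")
}

#' @export
print.pileup_set <- function(x, ...) {
  cat(sprintf("pileup over %d sequence(s), %s bp; BQ >= %d, MQ >= %d\n",
              length(x$counts), format(sum(nchar(x$ref)), big.mark = ","),
              x$min_base_quality, x$min_mapping_quality))
  invisible(x)
}

#' Callable sites from a pileup
#'
#' A site is callable when at least `min_depth` reads pass both quality
#' thresholds (applied when the pileup was built); maximal runs of callable
#' sites are returned as intervals.
#'
#' @param p A [pileup()] result.
#' @param min_depth Minimum passing depth (default 4, the conventional
#'   callable-loci default; the thresholds themselves are the pileup's).
#' @return An [interval_set()].
#' @export
callable_loci <- function(p, min_depth = 4) {
  rows <- lapply(names(p$depth), function(nm) {
    ok <- p$depth[[nm]] >= min_depth
    if (!any(ok)) return(NULL)
    ir <- IRanges::IRanges(ok)  # TRUE runs
    data.frame(seqid = nm, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(interval_set())
  as_interval_set(do.call(rbind, rows))
}

BASE_ROWS <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Call SNVs from a pileup with a frequency-based diploid genotyper
#'
#' For every site with at least one passing non-reference base, the most
#' frequent alternative allele is evaluated: genotype `het` when its
#' frequency lies in `[min_alt_frac, 1 - min_alt_frac]`, `hom-alt` above
#' that, `hom-ref` below. `n_alleles` records how many alleles (reference
#' included) reach `min_alt_frac`, which downstream support filtering uses as
#' the bi-allelic test. This is a deliberately simple pileup genotyper: the
#' heterozygosity statistic depends on depth and support counts, which are
#' preserved; no haplotype reassembly is attempted.
#'
#' @param p A [pileup()] result.
#' @param min_alt_frac Minimum allele frequency for an allele to be
#'   considered (default 0.2).
#' @return Data frame of calls: `seqid`, `pos` (0-based), `ref`, `alt`, `dp`,
#'   `rd` (ref-supporting depth), `ad` (alt-supporting depth), `genotype`,
#'   `n_alleles`.
#' @export
call_snvs <- function(p, min_alt_frac = 0.2) {
  out <- lapply(names(p$counts), function(nm) {
    m <- p$counts[[nm]]
    dp <- colSums(m)
    refc <- strsplit(toupper(p$ref[[nm]]), "", fixed = TRUE)[[1]]
    ref_row <- unname(BASE_ROWS[refc])           # NA at N positions
    pos_all <- seq_along(dp)
    valid <- !is.na(ref_row) & dp > 0
    rd <- rep(0L, length(dp))
    rd[valid] <- m[cbind(ref_row[valid], pos_all[valid])]
    cand <- which(valid & dp > rd)               # >= 1 non-ref passing base
    if (length(cand) == 0) return(NULL)
    sub <- m[, cand, drop = FALSE]
    sub[cbind(ref_row[cand], seq_along(cand))] <- -1L  # exclude ref from alt max
    alt_row <- max.col(t(sub), ties.method = "first")
    ad <- sub[cbind(alt_row, seq_along(cand))]
    dpc <- dp[cand]
    frac <- ad / dpc
    genotype <- ifelse(frac < min_alt_frac, "hom-ref",
                       ifelse(frac <= 1 - min_alt_frac, "het", "hom-alt"))
    sub[cbind(ref_row[cand], seq_along(cand))] <- rd[cand]
    n_alleles <- colSums(sub / rep(dpc, each = 4) >= min_alt_frac)
    data.frame(seqid = nm, pos = cand - 1L,
               ref = refc[cand], alt = names(BASE_ROWS)[alt_row],
               dp = as.integer(dpc), rd = as.integer(rd[cand]),
               ad = as.integer(ad),
               genotype = genotype, n_alleles = as.integer(n_alleles),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(seqid = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), dp = integer(0), rd = integer(0),
                      ad = integer(0), genotype = character(0),
                      n_alleles = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Filter SNV calls to supported sites
#'
#' Keeps calls that are bi-allelic, covered by at least `min_depth` reads
#' and, at heterozygous sites, supported by at least `min_alt_support` reads
#' for the alternative allele. Homozygous-reference calls are dropped.
#'
#' @param calls A [call_snvs()] data frame.
#' @param min_depth Minimum total depth (default 10).
#' @param min_alt_support Minimum alt-supporting reads at het sites
#'   (default 2).
#' @return Filtered calls data frame.
#' @export
filter_supported_snvs <- function(calls, min_depth = 10, min_alt_support = 2) {
  keep <- calls$dp >= min_depth &
    calls$genotype != "hom-ref" &
    calls$n_alleles <= 2 &
    (calls$genotype != "het" | (calls$ad >= min_alt_support & calls$n_alleles == 2))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask of artificially duplicated k-mers in an assembly
#'
#' Uncollapsed haplotype pairs leave k-mers that occur exactly twice in the
#' assembly while read coverage places them in the normal (heterozygous or
#' homozygous) depth band; reads split between the two copies depress
#' apparent heterozygosity there. The mask is built by (1) selecting read
#' k-mers with depth inside `depth_band`, (2) keeping those occurring exactly
#' `assembly_copies` times in the assembly (canonical counting, so both
#' strands collapse), (3) turning every exact occurrence into the interval
#' `[pos, pos + k)`, and (4) union-merging.
#'
#' @param assembly Assembly sequences.
#' @param reads Read sequences (`read_set`, character, `DNAStringSet`), or a
#'   named numeric vector of precomputed k-mer depths (names are k-mers).
#' @param k K-mer length (default 57).
#' @param depth_band Read-depth band `c(lo, hi)` (default `c(20, 200)`).
#' @param assembly_copies Required assembly occurrence count (default 2).
#' @return An [interval_set()] in assembly coordinates.
#' @export
duplicated_kmer_mask <- function(assembly, reads, k = 57,
                                 depth_band = c(20, 200), assembly_copies = 2) {
  seqs <- assembly_seqs(assembly)
  if (is.numeric(reads) && !is.null(names(reads))) {
    if (any(nchar(names(reads)) != k))
      stop("k-mer table entries do not match k")
    pos <- cpp_kmer_mask_counts(unname(seqs), names(reads), as.numeric(reads),
                                as.integer(k), depth_band[1], depth_band[2],
                                as.integer(assembly_copies))
  } else {
    pos <- cpp_kmer_mask(unname(seqs), as_char_seqs(reads), as.integer(k),
                         depth_band[1], depth_band[2],
                         as.integer(assembly_copies))
  }
  if (nrow(pos) == 0) return(interval_set())
  interval_set(names(seqs)[pos$seq], pos$start, pos$start + k)
}

#' Corrected heterozygosity rate
#'
#' The corrected SNV heterozygosity rate: supported heterozygous SNVs falling
#' in callable sites purged of the duplicated-k-mer mask, divided by the
#' length of those purged callable sites.
#'
#' @param supported_calls Calls from [filter_supported_snvs()].
#' @param callable Callable sites ([interval_set()]).
#' @param mask Optional duplicated-k-mer mask ([interval_set()]).
#' @return List of class `het_estimate`: `het_snv_count`, `callable_length`,
#'   `masked_length` (overlap of callable and mask),
#'   `corrected_callable_length`, `het_rate_pct`, `snvs_per_kb`.
#' @export
heterozygosity_rate <- function(supported_calls, callable, mask = NULL) {
  callable <- as_interval_set(callable)
  if (is.null(mask)) mask <- interval_set()
  corrected <- interval_subtract(callable, mask)
  len <- total_length(corrected)
  if (len == 0) stop("no callable sites remain after masking; rate undefined")
  het <- supported_calls[supported_calls$genotype == "het", , drop = FALSE]
  inside <- positions_in_intervals(corrected, het$seqid, het$pos)
  n <- sum(inside)
  structure(list(het_snv_count = n,
                 callable_length = total_length(callable),
                 masked_length = total_length(interval_intersect(callable, mask)),
                 corrected_callable_length = len,
                 het_rate_pct = 100 * n / len,
                 snvs_per_kb = 1000 * n / len),
            class = "het_estimate")
}

#' @export
print.het_estimate <- function(x, ...) {
  cat(sprintf("heterozygosity: %s het SNVs / %s corrected callable bp = %.2f%% (%.2f SNVs/kb)\n",
              format(x$het_snv_count, big.mark = ","),
              format(x$corrected_callable_length, big.mark = ","),
              x$het_rate_pct, x$snvs_per_kb))
  invisible(x)
}

#' Heterozygosity-rate arithmetic from stored counts
#'
#' Pure arithmetic used when the het SNV count and the corrected callable
#' length are already known (e.g. recomputing a published figure): rate as a
#' percentage and SNVs per kb, rounded half-even to two decimals.
#'
#' @param het_snv_count Number of supported heterozygous SNVs.
#' @param corrected_callable_length Callable bases free of duplicated k-mers.
#' @return List with `het_rate_pct` and `snvs_per_kb`.
#' @examples
#' het_rate_from_counts(3052169, 429483187)  # 0.71%, ~7.1 SNVs/kb
#' @export
het_rate_from_counts <- function(het_snv_count, corrected_callable_length) {
  if (corrected_callable_length <= 0) stop("callable length must be positive")
  list(het_rate_pct = round(100 * het_snv_count / corrected_callable_length, 2),
       snvs_per_kb = round(1000 * het_snv_count / corrected_callable_length, 2))
}

#' Write a het-estimate report as TSV
#' @param estimate A [heterozygosity_rate()] result.
#' @param path File path.
#' @export
write_het_report <- function(estimate, path) {
  df <- data.frame(statistic = c("het_snv_count", "callable_length",
                                 "masked_length", "corrected_callable_length",
                                 "het_rate_pct", "snvs_per_kb"),
                   value = c(estimate$het_snv_count, estimate$callable_length,
                             estimate$masked_length,
                             estimate$corrected_callable_length,
                             round(estimate$het_rate_pct, 4),
                             round(estimate$snvs_per_kb, 4)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read SNV calls as a minimal VCF 4.2
#'
#' One sample, `FORMAT GT:DP:AD` with `AD` as `ref,alt` depths; positions are
#' converted to the 1-based VCF convention on write and back on read (via
#' \pkg{vcfR}).
#'
#' @param calls A calls data frame ([call_snvs()] columns).
#' @param path File path.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @param sample Sample name.
#' @return `read_snv_vcf` returns a calls data frame.
#' @export
write_snv_vcf <- function(calls, path, contig_lengths = NULL,
                          sample = "sample1") {
  header <- c("##fileformat=VCFv4.2",
              "##source=hetscope",
              if (!is.null(contig_lengths))
                sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                        as.integer(contig_lengths)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample, sep = "\t"))
  gt <- ifelse(calls$genotype == "het", "0/1",
               ifelse(calls$genotype == "hom-alt", "1/1", "0/0"))
  dp <- ifelse(is.na(calls$dp), ".", calls$dp)
  ad <- ifelse(is.na(calls$rd) | is.na(calls$ad), ".",
               paste0(calls$rd, ",", calls$ad))
  rows <- paste(calls$seqid, calls$pos + 1, ".", calls$ref, calls$alt, ".",
                "PASS", ".", "GT:DP:AD", paste(gt, dp, ad, sep = ":"),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_snv_vcf
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad2 <- strsplit(ad, ",", fixed = TRUE)
  rd <- suppressWarnings(as.integer(vapply(ad2, `[`, "", 1)))
  adn <- suppressWarnings(as.integer(vapply(ad2, function(x) x[2], "")))
  data.frame(seqid = unname(fx[, "CHROM"]), pos = as.integer(fx[, "POS"]) - 1L,
             ref = unname(fx[, "REF"]), alt = unname(fx[, "ALT"]),
             dp = unname(dp), rd = unname(rd), ad = unname(adn),
             genotype = unname(ifelse(gt == "0/1", "het",
                                      ifelse(gt == "1/1", "hom-alt", "hom-ref"))),
             stringsAsFactors = FALSE, row.names = NULL)
}
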
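#' Sequencing yield and fold coverage
#'
#' `sequencing_yield` converts read pairs to total bases; `sequencing_coverage`
#' divides yield by a genome-size estimate, rounded half-even to two decimals
#' (the precision such coverage figures are reported at).
#'
#' @param pairs Number of read pairs.
#' @param read_length Read length in bases.
#' @param yield_bases Total sequenced bases.
#' @param genome_size_bases Genome size in bases.
#' @examples
#' sequencing_coverage(sequencing_yield(338.6e6, 251), 700178345)  # 242.76
#' @export
sequencing_yield <- function(pairs, read_length) {
  pairs * 2 * read_length
}

#' @rdname sequencing_yield
#' @export
sequencing_coverage <- function(yield_bases, genome_size_bases) {
  if (genome_size_bases <= 0) stop("genome size must be positive")
  if (yield_bases <= 0) stop("yield must be positive")
  round(yield_bases / genome_size_bases, 2)
}

#' Genome annotation summary statistics
#'
#' Derived ratios from annotation counts: transcripts per gene and gene
#' density per Mb (both half-even rounded to two decimals), plus exons per
#' transcript when exon counts are available. Consumes counts (optionally
#' taken from a GFF3 via [annotation_counts_from_gff()]); no annotation is
#' performed.
#'
#' @param gene_count,transcript_count,exon_count Annotation counts
#'   (`exon_count` optional).
#' @param assembly_length Assembly length in bases.
#' @return List of class `annotation_summary`.
#' @examples
#' annotation_summary(62652, 70788, assembly_length = 606969498)
#' @export
annotation_summary <- function(gene_count, transcript_count, exon_count = NA,
                               assembly_length) {
  if (assembly_length <= 0) stop("assembly length must be positive")
  if (gene_count == 0 && transcript_count > 0)
    stop("transcripts present but gene count is zero")
  structure(list(gene_count = gene_count,
                 transcript_count = transcript_count,
                 exon_count = exon_count,
                 assembly_length = assembly_length,
                 transcripts_per_gene = round(transcript_count / gene_count, 2),
                 gene_density_per_mb = round(gene_count / (assembly_length / 1e6), 2),
                 exons_per_transcript = if (is.na(exon_count)) NA
                                        else round(exon_count / transcript_count, 2)),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("annotation: %s genes, %s transcripts (%.2f/gene), %.2f genes/Mb\n",
              format(x$gene_count, big.mark = ","),
              format(x$transcript_count, big.mark = ","),
              x$transcripts_per_gene, x$gene_density_per_mb))
  invisible(x)
}

#' Extract annotation counts from a GFF3 file
#'
#' Genes are distinct `gene` records, transcripts `mRNA` records and exons
#' `exon` records (read via \pkg{rtracklayer}).
#'
#' @param path GFF3 file path.
#' @return List with `gene_count`, `transcript_count`, `exon_count`.
#' @export
annotation_counts_from_gff <- function(path) {
  g <- rtracklayer::import(path)
  ty <- as.character(g$type)
  list(gene_count = sum(ty == "gene"),
       transcript_count = sum(ty %in% c("mRNA", "transcript")),
       exon_count = sum(ty == "exon"))
}

#' Orthogroup membership summary
#'
#' Per-species counts from an orthogroup membership table: orthogroups
#' containing at least one gene of the species (and the percentage of all
#' orthogroups, one decimal), genes assigned, and orphan genes (genes in no
#' orthogroup). A gene may belong to at most one orthogroup.
#'
#' @param memberships Data frame with columns `orthogroup`, `species`, `gene`.
#' @param total_genes Named vector: annotated gene count per species.
#' @return Data frame: `species`, `orthogroups`, `pct_orthogroups`,
#'   `genes_assigned`, `orphan_genes`; total orthogroup count as attribute
#'   `total_orthogroups`.
#' @export
orthogroup_summary <- function(memberships, total_genes) {
  key <- paste(memberships$species, memberships$gene)
  if (anyDuplicated(key))
    stop("gene assigned to more than one orthogroup: ",
         memberships$gene[duplicated(key)][1])
  total_og <- length(unique(memberships$orthogroup))
  out <- do.call(rbind, lapply(names(total_genes), function(sp) {
    m <- memberships[memberships$species == sp, , drop = FALSE]
    n_og <- length(unique(m$orthogroup))
    assigned <- nrow(m)
    data.frame(species = sp, orthogroups = n_og,
               pct_orthogroups = round(100 * n_og / total_og, 1),
               genes_assigned = assigned,
               orphan_genes = total_genes[[sp]] - assigned,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "total_orthogroups") <- total_og
  out
}

# longest perfect tandem run of any unit length 1..max_unit in seq;
# ties broken toward the shortest unit
best_tandem_run <- function(seq, max_unit = 6, min_total = 8) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  best <- NULL
  for (u in seq_len(min(max_unit, floor(n / 2)))) {
    eq <- ch[(u + 1):n] == ch[1:(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    good <- which(r$values & r$lengths >= u)
    for (g in good) {
      total <- r$lengths[g] + u
      if (total < min_total) next
      if (is.null(best) || total > best$total) {
        s <- starts[g]  # position in the lag vector = position in seq
        best <- list(unit = paste(ch[s:(s + u - 1)], collapse = ""),
                     start = s, total = total, u = u)
      }
    }
  }
  best
}

rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1, i - 1)), "")
}

motif_family <- function(unit) {
  rc <- revcomp_chr(unit)
  sort(unique(c(rotations(unit), rotations(rc))))
}

#' Locate microsatellite markers on an assembly
#'
#' For each marker, both primers are searched on both strands (exact by
#' default, optionally allowing one mismatch); a properly oriented pair
#' within `max_amplicon` defines the amplicon. Inside it the longest perfect
#' tandem run of any 1-6 bp unit is detected; the observed unit is compared
#' with the declared motif over all rotations and reverse complements, and a
#' note records a discrepancy when the families differ. The genomic context
#' is classified against gene models: `intronic` (inside a gene, no exon
#' overlap), `exonic` (amplicon within exons), `partial-exonic` (some exon
#' overlap) or `intergenic`. Markers whose primer pair is not found are
#' reported unplaced rather than raising an error.
#'
#' @param markers Data frame: `name`, `primer_f`, `primer_r`, `motif`.
#' @param assembly Assembly sequences.
#' @param gene_models Optional gene models: a `GRanges` with a `type` column
#'   or a GFF3 path.
#' @param max_amplicon Maximum amplicon span in bases.
#' @param primer_max_mismatch Mismatches allowed per primer (default 0).
#' @return Data frame of class `marker_loci`, one row per marker.
#' @export
locate_microsatellites <- function(markers, assembly, gene_models = NULL,
                                   max_amplicon = 1000,
                                   primer_max_mismatch = 0) {
  if (any(nchar(markers$primer_f) < 15 | nchar(markers$primer_r) < 15))
    stop("primers must be at least 15 bases")
  seqs <- Biostrings::DNAStringSet(assembly_seqs(assembly))
  if (is.character(gene_models)) gene_models <- rtracklayer::import(gene_models)

  find_amplicon <- function(pf, pr) {
    for (orient in 1:2) {
      left <- if (orient == 1) pf else pr
      right <- if (orient == 1) pr else pf
      hl <- Biostrings::vmatchPattern(Biostrings::DNAString(left), seqs,
                                      max.mismatch = primer_max_mismatch)
      hr <- Biostrings::vmatchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(right)), seqs,
        max.mismatch = primer_max_mismatch)
      for (i in seq_along(seqs)) {
        ls <- hl[[i]]; rs <- hr[[i]]
        if (length(ls) == 0 || length(rs) == 0) next
        for (a in seq_along(ls)) {
          ok <- IRanges::start(rs) > IRanges::end(ls)[a] &
            IRanges::end(rs) - IRanges::start(ls)[a] + 1 <= max_amplicon
          if (any(ok)) {
            b <- which(ok)[which.min(IRanges::end(rs)[ok])]
            return(list(seq = names(seqs)[i],
                        start = IRanges::start(ls)[a] - 1,     # 0-based
                        end = IRanges::end(rs)[b],
                        inner_start = IRanges::end(ls)[a],     # between primers
                        inner_end = IRanges::start(rs)[b] - 1))
          }
        }
      }
    }
    NULL
  }

  classify_context <- function(seqid, start, end) {
    if (is.null(gene_models)) return(NA_character_)
    amp <- GenomicRanges::GRanges(seqid, IRanges::IRanges(start + 1, end))
    ty <- as.character(gene_models$type)
    genes <- gene_models[ty == "gene"]
    exons <- gene_models[ty == "exon"]
    if (length(genes) == 0 || GenomicRanges::countOverlaps(amp, genes) == 0)
      return("intergenic")
    ov <- GenomicRanges::intersect(amp, GenomicRanges::reduce(exons),
                                   ignore.strand = TRUE)
    exon_bp <- sum(GenomicRanges::width(ov))
    if (exon_bp == 0) "intronic"
    else if (exon_bp == GenomicRanges::width(amp)) "exonic"
    else "partial-exonic"
  }

  rows <- lapply(seq_len(nrow(markers)), function(i) {
    mk <- markers[i, ]
    unplaced <- data.frame(marker = mk$name, scaffold = NA_character_,
                           amp_start = NA_real_, amp_end = NA_real_,
                           motif_start = NA_real_, motif_end = NA_real_,
                           motif_declared = mk$motif,
                           motif_observed = NA_character_,
                           compatible = NA, context = NA_character_,
                           placed = FALSE, note = "primer pair not found",
                           stringsAsFactors = FALSE)
    amp <- find_amplicon(toupper(mk$primer_f), toupper(mk$primer_r))
    if (is.null(amp)) return(unplaced)
    inner <- substring(as.character(seqs[[amp$seq]]), amp$inner_start + 1,
                       amp$inner_end)
    run <- best_tandem_run(inner)
    motif_obs <- if (is.null(run)) NA_character_ else run$unit
    compatible <- if (is.null(run)) NA else
      run$unit %in% motif_family(toupper(mk$motif))
    note <- if (isFALSE(compatible))
      sprintf("repeat unit seems to be (%s) instead of (%s)", motif_obs, mk$motif)
    else ""
    m_start <- if (is.null(run)) NA_real_ else amp$inner_start + run$start - 1
    m_end <- if (is.null(run)) NA_real_ else m_start + run$total
    data.frame(marker = mk$name, scaffold = amp$seq,
               amp_start = amp$start, amp_end = amp$end,
               motif_start = m_start, motif_end = m_end,
               motif_declared = mk$motif, motif_observed = motif_obs,
               compatible = compatible,
               context = classify_context(amp$seq, amp$start, amp$end),
               placed = TRUE, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marker_loci", "data.frame")
  out
}
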
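#' Simulation configuration for a synthetic diploid genome
#'
#' Bundles the parameters of the synthetic diploid genome, read set and
#' fragmented assembly. Defaults describe a heterozygous, repeat-rich marine
#' invertebrate genome sequenced with an Illumina-like paired-end library:
#' heterozygosity ~0.9% (SNVs only), ~42% of the genome in repeat families,
#' 2x251 bp pairs from ~395 bp fragments, per-base substitution error ~0.3%,
#' and a ~7.9% contaminant read admixture, scaled to a 1 Mb genome so that a
#' full analysis runs on a desktop.
#'
#' @param genome_length Haploid genome length in bases.
#' @param het_rate Fraction of sites heterozygous (SNVs only), in `[0, 0.05)`.
#' @param repeat_fraction Fraction of the genome covered by repeat-family
#'   copies, in `[0, 1)`.
#' @param n_repeat_families Number of repeat families (each 2-3 copies at
#'   95-99% identity).
#' @param duplication_fraction Fraction of the genome emitted twice in the
#'   assembly as uncollapsed haplotigs, in `[0, 1)`.
#' @param read_length Read length in bases.
#' @param fragment_mean,fragment_sd Fragment length distribution in bases.
#' @param depth Fold sequencing coverage (> 0).
#' @param error_rate Per-base substitution probability.
#' @param contaminant_fraction Fraction of read pairs drawn from contaminant
#'   genomes, in `[0, 1)`.
#' @param trim_length Fixed trim length in bases for [trim_reads()].
#' @param quality_mode `"constant"` emits Q30 throughout; `"tail"` degrades the
#'   last 40% of cycles to Q5 to exercise callable-site filters.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, het_rate = 0.009,
                       repeat_fraction = 0.42, n_repeat_families = 12,
                       duplication_fraction = 0, read_length = 251,
                       fragment_mean = 395, fragment_sd = 60, depth = 100,
                       error_rate = 0.003, contaminant_fraction = 0.0786,
                       trim_length = 150, quality_mode = c("constant", "tail"),
                       seed = 1L) {
  quality_mode <- match.arg(quality_mode)
  cfg <- list(genome_length = as.numeric(genome_length), het_rate = het_rate,
              repeat_fraction = repeat_fraction,
              n_repeat_families = as.integer(n_repeat_families),
              duplication_fraction = duplication_fraction,
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              depth = depth, error_rate = error_rate,
              contaminant_fraction = contaminant_fraction,
              trim_length = as.integer(trim_length),
              quality_mode = quality_mode, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length >= 1000,
            cfg$het_rate >= 0, cfg$het_rate < 0.05,
            cfg$repeat_fraction >= 0, cfg$repeat_fraction < 1,
            cfg$duplication_fraction >= 0, cfg$duplication_fraction < 1,
            cfg$depth > 0, cfg$read_length > 0,
            cfg$fragment_mean > 0, cfg$fragment_sd >= 0,
            cfg$error_rate >= 0, cfg$error_rate < 0.5,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1,
            cfg$trim_length > 0)
  invisible(cfg)
}

DNA_BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# substitute bases at `rate`, returning the mutated string
mutate_seq <- function(s, rate) {
  n <- nchar(s)
  nmut <- rbinom(1, n, rate)
  if (nmut == 0) return(s)
  pos <- sample.int(n, nmut)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(ch[pos], DNA_BASES4)
  ch[pos] <- DNA_BASES4[((code - 1 + sample.int(3, nmut, replace = TRUE)) %% 4) + 1]
  paste(ch, collapse = "")
}

#' Simulate a diploid genome with planted heterozygous SNVs and repeats
#'
#' Builds one chromosome (`chr1`) as an interleaving of unique sequence and
#' dispersed repeat-family copies (2-3 copies per family, mutated to 95-99%
#' identity, emulating the 2x/3x repeat structure seen in k-mer spectra of
#' partially collapsed assemblies), then plants heterozygous SNVs uniformly at
#' `het_rate` to derive the second haplotype. Both haplotypes have identical
#' length and coordinates (SNVs only, no indels).
#'
#' @param config A [sim_config()].
#' @param het_exclude_repeats If `TRUE`, no SNVs are planted inside repeat
#'   copies (default `FALSE`).
#' @return A list of class `diploid_genome` with elements `hap_a`, `hap_b`
#'   (named character vectors of sequences), `variants` (data frame `seqid`,
#'   `pos` 0-based, `a`, `b`), `repeat_intervals` (an [interval_set()]), and
#'   `config`.
#' @export
simulate_diploid_genome <- function(config, het_exclude_repeats = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$genome_length
  target <- config$repeat_fraction * G
  if (target > 0.9 * G) stop("genome_length too small to host requested repeats")

  pieces <- character(0)     # repeat copy sequences in emission order
  if (target > 0) {
    nf <- max(1L, config$n_repeat_families)
    share <- as.vector(stats::rmultinom(1, size = 1000, prob = rep(1, nf))) / 1000
    copies <- sample(2:3, nf, replace = TRUE)
    unit_len <- pmax(200, round(share * target / copies))
    if (any(unit_len > G / 4)) stop("genome_length too small to host requested repeats")
    for (f in seq_len(nf)) {
      unit <- random_dna(unit_len[f])
      div <- runif(copies[f], 0.01, 0.05)  # 95-99% identity
      pieces <- c(pieces, vapply(div, function(d) mutate_seq(unit, d), ""))
    }
    pieces <- sample(pieces)
  }
  rep_total <- sum(nchar(pieces))
  filler_total <- G - rep_total
  if (filler_total < length(pieces) + 1)
    stop("genome_length too small to host requested repeats")
  # random composition of the unique sequence between/around repeat copies
  cuts <- sort(sample.int(filler_total - 1, length(pieces)))
  filler_len <- diff(c(0, cuts, filler_total))

  segs <- character(2 * length(pieces) + 1)
  is_rep <- logical(length(segs))
  segs[seq(1, length(segs), by = 2)] <- vapply(filler_len, random_dna, "")
  if (length(pieces) > 0) {
    segs[seq(2, length(segs), by = 2)] <- pieces
    is_rep[seq(2, length(segs), by = 2)] <- TRUE
  }
  seg_len <- nchar(segs)
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len
  hap_a <- paste(segs, collapse = "")
  repeat_intervals <- if (any(is_rep)) {
    interval_set(rep("chr1", sum(is_rep)), seg_start[is_rep], seg_end[is_rep])
  } else interval_set()

  n_het <- rbinom(1, G, config$het_rate)
  pos <- sort(sample.int(G, n_het)) - 1L
  if (het_exclude_repeats && n_het > 0) {
    pos <- pos[!positions_in_intervals(repeat_intervals, rep("chr1", length(pos)), pos)]
  }
  variants <- data.frame(seqid = character(0), pos = integer(0),
                         a = character(0), b = character(0),
                         stringsAsFactors = FALSE)
  hap_b <- hap_a
  if (length(pos) > 0) {
    ch <- strsplit(hap_a, "", fixed = TRUE)[[1]]
    ref <- ch[pos + 1]
    code <- match(ref, DNA_BASES4)
    alt <- DNA_BASES4[((code - 1 + sample.int(3, length(pos), replace = TRUE)) %% 4) + 1]
    ch[pos + 1] <- alt
    hap_b <- paste(ch, collapse = "")
    variants <- data.frame(seqid = "chr1", pos = pos, a = ref, b = alt,
                           stringsAsFactors = FALSE)
  }
  structure(list(hap_a = c(chr1 = hap_a), hap_b = c(chr1 = hap_b),
                 variants = variants, repeat_intervals = repeat_intervals,
                 config = config),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("diploid genome: %d sequence(s), %s bp haploid\n",
              length(x$hap_a), format(sum(nchar(x$hap_a)), big.mark = ",")))
  cat(sprintf("  %d heterozygous SNVs (%.3f%%), repeats %s bp\n",
              nrow(x$variants),
              100 * nrow(x$variants) / sum(nchar(x$hap_a)),
              format(total_length(x$repeat_intervals), big.mark = ",")))
  invisible(x)
}

# substitution errors at `rate`, vectorized over a character vector of
# equal-length reads; multiple errors per read are applied in passes
add_read_errors <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  L <- nchar(x[1])
  total <- length(x) * L
  n_err <- rbinom(1, min(total, .Machine$integer.max), rate)
  if (n_err == 0) return(x)
  idx <- sample(total, n_err)
  read_i <- ((idx - 1) %/% L) + 1
  pos <- as.integer((idx - 1) %% L) + 1L
  while (length(read_i) > 0) {
    take <- !duplicated(read_i)
    ri <- read_i[take]; pi <- pos[take]
    cur <- substring(x[ri], pi, pi)
    code <- match(cur, DNA_BASES4)
    new <- DNA_BASES4[((code - 1 + sample.int(3, length(ri), replace = TRUE)) %% 4) + 1]
    y <- x[ri]
    substr(y, pi, pi) <- new
    x[ri] <- y
    read_i <- read_i[!take]; pos <- pos[!take]
  }
  x
}

quality_string <- function(L, mode) {
  if (mode == "tail") {
    n_hi <- floor(0.6 * L)
    paste0(strrep(rawToChar(as.raw(33 + 30)), n_hi),
           strrep(rawToChar(as.raw(33 + 5)), L - n_hi))
  } else {
    strrep(rawToChar(as.raw(33 + 30)), L)
  }
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a paired-end read set from a diploid genome
#'
#' Pairs are drawn with random fragment positions, each fragment from a
#' randomly chosen haplotype, in forward-reverse orientation. Substitution
#' errors are applied at `config$error_rate`; truth origins (haplotype,
#' sequence, 0-based start, strand per mate) are recorded for every pair.
#' Total sequenced bases approximate `depth * genome_length`.
#'
#' @param genome A [simulate_diploid_genome()] result.
#' @param config A [sim_config()]; `fragment_mean` must be >= `read_length`.
#' @return A list of class `read_set`: `id`, `r1`, `r2`, `q1`, `q2` (character
#'   vectors), `origin` (data frame `hap`, `seqid`, `start1`, `start2`,
#'   `frag`), `source` (per-pair label), `read_length`.
#' @export
simulate_reads <- function(genome, config = genome$config) {
  validate_sim_config(config)
  if (config$fragment_mean < config$read_length)
    stop("fragment_mean must be >= read_length")
  set.seed(config$seed + 1L)
  G <- config$genome_length
  L <- config$read_length
  n <- as.integer(ceiling(config$depth * G / (2 * L)))
  frag <- pmin(pmax(round(rnorm(n, config$fragment_mean, config$fragment_sd)), L), G)
  start <- floor(runif(n) * (G - frag + 1))  # 0-based fragment start
  hap <- sample(c("A", "B"), n, replace = TRUE)

  r1 <- character(n); r2 <- character(n)
  for (h in c("A", "B")) {
    sel <- hap == h
    if (!any(sel)) next
    hs <- if (h == "A") genome$hap_a[["chr1"]] else genome$hap_b[["chr1"]]
    r1[sel] <- substring(hs, start[sel] + 1, start[sel] + L)
    r2[sel] <- substring(hs, start[sel] + frag[sel] - L + 1, start[sel] + frag[sel])
  }
  r2 <- revcomp_chr(r2)
  r1 <- add_read_errors(r1, config$error_rate)
  r2 <- add_read_errors(r2, config$error_rate)
  q <- quality_string(L, config$quality_mode)

  structure(list(id = sprintf("pair%07d", seq_len(n)),
                 r1 = r1, r2 = r2,
                 q1 = rep(q, n), q2 = rep(q, n),
                 origin = data.frame(hap = hap, seqid = "chr1",
                                     start1 = start, start2 = start + frag - L,
                                     frag = frag, stringsAsFactors = FALSE),
                 source = rep("host", n),
                 read_length = L,
                 fragment_mean = config$fragment_mean,
                 fragment_sd = config$fragment_sd),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %s pairs x 2 x %d bp (%s bases)\n",
              format(length(x$r1), big.mark = ","), x$read_length,
              format(2 * length(x$r1) * x$read_length, big.mark = ",")))
  src <- table(sub(":.*", "", x$source))
  cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of read pairs in a read set
#' @param reads A `read_set`.
#' @export
n_pairs <- function(reads) length(reads$r1)

#' Subset a read set by pair index
#' @param reads A `read_set`.
#' @param idx Integer or logical index over pairs.
#' @export
subset_read_set <- function(reads, idx) {
  out <- reads
  for (f in c("id", "r1", "r2", "q1", "q2", "source")) out[[f]] <- reads[[f]][idx]
  out$origin <- reads$origin[idx, , drop = FALSE]
  rownames(out$origin) <- NULL
  out
}

#' Replace a fraction of read pairs with contaminant-derived pairs
#'
#' A binomially drawn fraction of pairs is replaced by pairs simulated from
#' the supplied contaminant genomes (multinomial mixing across contaminants,
#' proportions configurable), with `source` labels set to
#' `"contaminant:<name>"` so that screening sensitivity can be scored against
#' truth.
#'
#' @param reads A `read_set`.
#' @param contaminants Named character vector (or `DNAStringSet`) of
#'   contaminant genome sequences.
#' @param fraction Fraction of pairs to replace, in `[0, 1)`.
#' @param proportions Optional mixing weights, one per contaminant.
#' @param error_rate Per-base substitution error applied to contaminant reads.
#' @param seed Integer seed.
#' @return A `read_set` with the same number of pairs.
#' @export
inject_contaminants <- function(reads, contaminants, fraction,
                                proportions = NULL, error_rate = 0, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(reads)
  if (inherits(contaminants, "DNAStringSet"))
    contaminants <- stats::setNames(as.character(contaminants), names(contaminants))
  if (length(contaminants) == 0)
    stop("contaminant set is empty but fraction > 0")
  if (is.null(names(contaminants)) || any(!nzchar(names(contaminants))))
    stop("contaminant sequences must be named")
  set.seed(seed)
  n <- n_pairs(reads)
  n_cont <- rbinom(1, n, fraction)
  if (n_cont == 0) return(reads)
  idx <- sample.int(n, n_cont)
  who <- sample(names(contaminants), n_cont, replace = TRUE, prob = proportions)
  L <- reads$read_length
  fm <- if (!is.null(reads$fragment_mean)) reads$fragment_mean else max(2 * L, 400)
  fs <- if (!is.null(reads$fragment_sd)) reads$fragment_sd else 0.1 * fm

  out <- reads
  for (nm in unique(who)) {
    sel <- idx[who == nm]
    g <- contaminants[[nm]]
    Gc <- nchar(g)
    if (Gc < L) stop(sprintf("contaminant '%s' shorter than read length", nm))
    frag <- pmin(pmax(round(rnorm(length(sel), fm, fs)), L), Gc)
    st <- floor(runif(length(sel)) * (Gc - frag + 1))
    r1 <- add_read_errors(substring(g, st + 1, st + L), error_rate)
    r2 <- add_read_errors(revcomp_chr(substring(g, st + frag - L + 1, st + frag)),
                          error_rate)
    out$r1[sel] <- r1
    out$r2[sel] <- r2
    out$origin$hap[sel] <- NA
    out$origin$seqid[sel] <- nm
    out$origin$start1[sel] <- st
    out$origin$start2[sel] <- st + frag - L
    out$origin$frag[sel] <- frag
    out$source[sel] <- paste0("contaminant:", nm)
  }
  out
}

#' Fragment a diploid genome into a scaffolded assembly with haplotigs
#'
#' Haplotype A is cut into scaffolds with log-normal lengths and internal
#' N-gap runs; for a configurable fraction of the genome, sub-intervals of
#' primary scaffolds (30-70% of the scaffold each) are additionally emitted as
#' extra scaffolds copied from haplotype B -- the uncollapsed-haplotig
#' condition that halves local read depth and hides heterozygous sites.
#' Truth (duplicated intervals, haplotig names, a piece map from assembly to
#' genome coordinates) is returned for parameter-recovery tests.
#'
#' @param genome A [simulate_diploid_genome()] result.
#' @param config A [sim_config()]; `duplication_fraction` controls haplotig
#'   emission.
#' @param scaffold_mean_length Mean primary scaffold length (log-normal).
#' @param scaffold_sdlog Log-scale standard deviation of scaffold lengths.
#' @param gap_rate Expected N-gap runs per base within primary scaffolds.
#' @param gap_len_range Integer range of gap run lengths.
#' @param min_dup_length Minimum haplotig length in bases.
#' @return A list of class `sim_assembly`: `seqs` (named character),
#'   `piece_map` (scaffold piece to genome coordinates), `duplicated_intervals`
#'   (truth, genome coordinates), `haplotig_names`, `gap_length`.
#' @export
make_fragmented_assembly <- function(genome, config = genome$config,
                                     scaffold_mean_length = 20000,
                                     scaffold_sdlog = 0.35,
                                     gap_rate = 1 / 15000,
                                     gap_len_range = c(10L, 100L),
                                     min_dup_length = 2000) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  G <- config$genome_length
  hap_a <- genome$hap_a[["chr1"]]
  hap_b <- genome$hap_b[["chr1"]]

  lens <- integer(0)
  while (sum(lens) < G) {
    lens <- c(lens, pmax(1000L, as.integer(round(
      rlnorm(64, log(scaffold_mean_length), scaffold_sdlog)))))
  }
  over <- cumsum(lens) >= G
  lens <- lens[seq_len(which(over)[1])]
  lens[length(lens)] <- G - sum(lens[-length(lens)])
  if (lens[length(lens)] < 200) {  # fold a tiny remainder into the previous scaffold
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  scaf_end <- cumsum(lens)
  scaf_start <- scaf_end - lens
  n_scaf <- length(lens)

  # haplotig truth: sub-intervals of primary scaffolds totalling ~dup fraction
  dup <- data.frame(start = numeric(0), end = numeric(0), scaffold = integer(0))
  target <- config$duplication_fraction * G
  if (target > 0) {
    for (i in sample.int(n_scaf)) {
      done <- sum(dup$end - dup$start)
      if (done >= target) break
      f <- runif(1, 0.3, 0.7)
      w <- round(f * lens[i])
      if (w < min_dup_length) next
      # trim the final interval toward the requested total where possible
      if (done + w > target) w <- max(min_dup_length, round(target - done))
      off <- sample.int(lens[i] - w + 1, 1) - 1
      dup <- rbind(dup, data.frame(start = scaf_start[i] + off,
                                   end = scaf_start[i] + off + w,
                                   scaffold = i))
    }
    if (nrow(dup) == 0)
      stop("no scaffold large enough to host the requested duplications")
  }

  seqs <- character(0)
  piece_map <- list()
  gap_total <- 0
  for (i in seq_len(n_scaf)) {
    nm <- sprintf("scaffold_%04d", i)
    s0 <- scaf_start[i]; s1 <- scaf_end[i]
    n_gaps <- rpois(1, lens[i] * gap_rate)
    cuts <- if (n_gaps > 0 && lens[i] > 2000) {
      sort(sample(seq(500, lens[i] - 500), min(n_gaps, 5)))
    } else integer(0)
    piece_src <- cbind(c(s0, s0 + cuts), c(s0 + cuts, s1))
    gaps <- if (length(cuts) > 0) {
      sample(seq(gap_len_range[1], gap_len_range[2]), length(cuts), replace = TRUE)
    } else integer(0)
    parts <- character(0)
    scaff_pos <- 0
    for (p in seq_len(nrow(piece_src))) {
      a <- piece_src[p, 1]; b <- piece_src[p, 2]
      parts <- c(parts, substring(hap_a, a + 1, b))
      piece_map[[length(piece_map) + 1]] <-
        data.frame(scaffold = nm, scaff_start = scaff_pos, src = "A",
                   seqid = "chr1", src_start = a, src_end = b,
                   stringsAsFactors = FALSE)
      scaff_pos <- scaff_pos + (b - a)
      if (p <= length(gaps)) {
        parts <- c(parts, strrep("N", gaps[p]))
        scaff_pos <- scaff_pos + gaps[p]
        gap_total <- gap_total + gaps[p]
      }
    }
    seqs[nm] <- paste(parts, collapse = "")
  }
  haplotig_names <- character(0)
  if (nrow(dup) > 0) {
    for (j in seq_len(nrow(dup))) {
      nm <- sprintf("haplotig_%03d", j)
      seqs[nm] <- substring(hap_b, dup$start[j] + 1, dup$end[j])
      piece_map[[length(piece_map) + 1]] <-
        data.frame(scaffold = nm, scaff_start = 0, src = "B", seqid = "chr1",
                   src_start = dup$start[j], src_end = dup$end[j],
                   stringsAsFactors = FALSE)
      haplotig_names <- c(haplotig_names, nm)
    }
  }
  dup_iset <- if (nrow(dup) > 0) {
    interval_set(rep("chr1", nrow(dup)), dup$start, dup$end)
  } else interval_set()
  structure(list(seqs = seqs,
                 piece_map = do.call(rbind, piece_map),
                 duplicated_intervals = dup_iset,
                 haplotig_names = haplotig_names,
                 gap_length = gap_total,
                 config = config),
            class = "sim_assembly")
}

#' @export
print.sim_assembly <- function(x, ...) {
  cat(sprintf("simulated assembly: %d scaffolds (%d haplotigs), %s bp (%s bp N gaps)\n",
              length(x$seqs), length(x$haplotig_names),
              format(sum(nchar(x$seqs)), big.mark = ","),
              format(x$gap_length, big.mark = ",")))
  invisible(x)
}

#' Route simulated reads onto a fragmented assembly
#'
#' Converts truth read origins (genome coordinates) into assembly-coordinate
#' alignments, emulating how a mapper would place them: reads from haplotype B
#' whose origin lies inside a duplicated interval go to the haplotig scaffold,
#' everything else to the primary scaffold covering the origin (both
#' haplotypes share coordinates since variants are SNVs only). Reads whose
#' origin crosses a scaffold-piece boundary are dropped, as a mapper would
#' clip them.
#'
#' @param reads A `read_set` (contaminant pairs are skipped as unmapped).
#' @param assembly A [make_fragmented_assembly()] result.
#' @param mapq Mapping quality to assign.
#' @return An alignment data frame (`seqid`, `start` 0-based, `strand`, `seq`,
#'   `qual`, `mapq`) in assembly coordinates.
#' @export
route_reads_to_assembly <- function(reads, assembly, mapq = 60L) {
  pm <- assembly$piece_map
  pa <- pm[pm$src == "A", , drop = FALSE]
  pa <- pa[order(pa$src_start), , drop = FALSE]
  pb <- pm[pm$src == "B", , drop = FALSE]
  pb <- pb[order(pb$src_start), , drop = FALSE]
  L <- reads$read_length

  route_mate <- function(start, hap, seq, qual, strand) {
    n <- length(start)
    scaf <- character(n); pos <- numeric(n); ok <- logical(n)
    # haplotype-B reads contained in a haplotig piece route there
    if (nrow(pb) > 0) {
      isB <- !is.na(hap) & hap == "B"
      j <- findInterval(start, pb$src_start)
      contained <- isB & j >= 1 & start >= pb$src_start[pmax(j, 1)] &
        start + L <= pb$src_end[pmax(j, 1)]
      scaf[contained] <- pb$scaffold[j[contained]]
      pos[contained] <- pb$scaff_start[j[contained]] +
        (start[contained] - pb$src_start[j[contained]])
      ok[contained] <- TRUE
    }
    rest <- !ok & !is.na(hap)
    j <- findInterval(start, pa$src_start)
    contained <- rest & j >= 1 & start >= pa$src_start[pmax(j, 1)] &
      start + L <= pa$src_end[pmax(j, 1)]
    scaf[contained] <- pa$scaffold[j[contained]]
    pos[contained] <- pa$scaff_start[j[contained]] +
      (start[contained] - pa$src_start[j[contained]])
    ok[contained] <- TRUE
    data.frame(seqid = scaf, start = pos, strand = strand, seq = seq,
               qual = qual, mapq = mapq, ok = ok, stringsAsFactors = FALSE)
  }
  a1 <- route_mate(reads$origin$start1, reads$origin$hap, reads$r1, reads$q1, "+")
  a2 <- route_mate(reads$origin$start2, reads$origin$hap, reads$r2, reads$q2, "-")
  out <- rbind(a1[a1$ok, ], a2[a2$ok, ])
  out$ok <- NULL
  rownames(out) <- NULL
  out
}

#' Write simulation outputs to standard formats
#'
#' FASTA for haplotypes and assemblies, paired FASTQ (Phred+33) for reads,
#' a minimal VCF for truth variants, BED for truth intervals, and a flat
#' `key=value` file for the configuration.
#'
#' @param genome,reads,assembly,config Simulation objects.
#' @param path,r1_path,r2_path Output file paths.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(c(stats::setNames(genome$hap_a,
                                                  paste0(names(genome$hap_a), "_hapA")),
                                  stats::setNames(genome$hap_b,
                                                  paste0(names(genome$hap_b), "_hapB"))))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname sim_io
#' @export
write_assembly_fasta <- function(assembly, path) {
  seqs <- if (inherits(assembly, "sim_assembly")) assembly$seqs else assembly
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname sim_io
#' @export
write_reads_fastq <- function(reads, r1_path, r2_path) {
  s1 <- Biostrings::DNAStringSet(reads$r1)
  names(s1) <- paste0(reads$id, "/1")
  s2 <- Biostrings::DNAStringSet(reads$r2)
  names(s2) <- paste0(reads$id, "/2")
  Biostrings::writeXStringSet(s1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$q1))
  Biostrings::writeXStringSet(s2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$q2))
  invisible(c(r1_path, r2_path))
}

#' @rdname sim_io
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq", with.qualities = TRUE)
  n <- length(s1)
  structure(list(id = sub("/1$", "", names(s1)),
                 r1 = as.character(s1), r2 = as.character(s2),
                 q1 = as.character(S4Vectors::mcols(s1)$qualities),
                 q2 = as.character(S4Vectors::mcols(s2)$qualities),
                 origin = data.frame(hap = rep(NA_character_, n), seqid = NA_character_,
                                     start1 = NA_real_, start2 = NA_real_,
                                     frag = NA_real_, stringsAsFactors = FALSE),
                 source = rep("unknown", n),
                 read_length = if (n > 0) nchar(as.character(s1)[1]) else 0L),
            class = "read_set")
}

#' @rdname sim_io
#' @export
write_truth_vcf <- function(genome, path) {
  v <- genome$variants
  calls <- data.frame(seqid = v$seqid, pos = v$pos, ref = v$a, alt = v$b,
                      dp = NA_integer_, rd = NA_integer_, ad = NA_integer_,
                      genotype = "het", stringsAsFactors = FALSE)
  write_snv_vcf(calls, path,
                contig_lengths = stats::setNames(nchar(genome$hap_a),
                                                 names(genome$hap_a)))
}

#' @rdname sim_io
#' @export
write_sim_config <- function(config, path) {
  writeLines(paste0(names(config), "=", unlist(config)), path)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_sim_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- suppressWarnings(lapply(vals, function(v) {
    x <- as.numeric(v)
    if (is.na(x)) v else x
  }))
  do.call(sim_config, num[names(num) != "NA"])
}
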
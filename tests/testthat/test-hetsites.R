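ref_onechr <- function(seq) {
  structure(list(hap_a = c(chr1 = seq), hap_b = c(chr1 = seq),
                 variants = data.frame(), repeat_intervals = interval_set(),
                 config = NULL), class = "diploid_genome")
}

mk_aln <- function(seqid, start, seq, qual = strrep("?", nchar(seq)),
                   strand = "+", mapq = 60L) {
  data.frame(seqid = seqid, start = start, strand = strand, seq = seq,
             qual = qual, mapq = mapq, stringsAsFactors = FALSE)
}

test_that("pileup tallies passing bases and enforces bounds", {
  ref <- ref_onechr("ACGTACGTACGT")
  al <- do.call(rbind, lapply(1:3, function(i) mk_aln("chr1", 2, "GTACG")))
  p <- pileup(al, ref)
  expect_equal(unname(p$depth[["chr1"]][3:7]), rep(3, 5))
  expect_equal(unname(p$depth[["chr1"]][1:2]), c(0, 0))
  expect_equal(unname(p$counts[["chr1"]]["G", 3]), 3)
  # low base quality and low mapq are excluded
  p2 <- pileup(rbind(al, mk_aln("chr1", 2, "GTACG", qual = strrep("#", 5))), ref)
  expect_equal(unname(p2$depth[["chr1"]][3]), 3)
  p3 <- pileup(rbind(al, mk_aln("chr1", 2, "GTACG", mapq = 5L)), ref)
  expect_equal(unname(p3$depth[["chr1"]][3]), 3)
  # empty alignments give an empty pileup
  p0 <- pileup(al[0, ], ref)
  expect_true(all(p0$depth[["chr1"]] == 0))
  expect_error(pileup(mk_aln("chr1", 10, "ACGTACGT"), ref), "beyond")
  expect_error(pileup(mk_aln("chrX", 0, "ACGT"), ref), "unknown")
})

test_that("minus-strand alignments are reverse-complemented into reference", {
  ref <- ref_onechr("AACCGGTTAACC")
  # read sequenced as revcomp of ref[3..8] = CCGGTT -> stored AACCGG
  p <- pileup(mk_aln("chr1", 2, "AACCGG", strand = "-"), ref)
  expect_equal(unname(p$counts[["chr1"]]["C", 3]), 1)
  expect_equal(unname(p$counts[["chr1"]]["T", 8]), 1)
})

test_that("callable loci honour the depth threshold edge", {
  ref <- ref_onechr(strrep("ACGT", 25))
  al4 <- do.call(rbind, lapply(1:4, function(i) mk_aln("chr1", 10, strrep("A", 20))))
  cl4 <- callable_loci(pileup(al4, ref), min_depth = 4)
  expect_equal(total_length(cl4), 20)
  expect_equal(as.data.frame(cl4)$start, 10)
  cl3 <- callable_loci(pileup(al4[1:3, ], ref), min_depth = 4)
  expect_equal(total_length(cl3), 0)
  # uniform high coverage -> a single interval spanning the sequence
  sim <- tiny_sim(seed = 8, genome_length = 1e4, depth = 100, error_rate = 0)
  p <- pileup(alignments_from_reads(sim$reads, sim$genome), sim$genome)
  cl <- callable_loci(p)
  expect_gte(total_length(cl) / 1e4, 0.95)
  expect_lte(nrow(cl), 2)
})

test_that("the genotyper applies allele-frequency rules at exact boundaries", {
  ref <- ref_onechr(strrep("A", 60))
  reads_alt <- function(n_ref, n_alt, alt = "C") {
    rbind(
      do.call(rbind, lapply(seq_len(n_ref), function(i)
        mk_aln("chr1", 10, strrep("A", 10)))),
      do.call(rbind, lapply(seq_len(n_alt), function(i)
        mk_aln("chr1", 10, paste0(strrep("A", 5), alt, strrep("A", 4))))))
  }
  calls <- call_snvs(pileup(reads_alt(20, 20), ref))   # 50/50 at DP 40
  site <- calls[calls$pos == 15, ]
  expect_equal(site$genotype, "het")
  expect_equal(site$dp, 40L)
  expect_equal(site$ad, 20L)
  calls2 <- call_snvs(pileup(reads_alt(39, 1), ref))   # 1 of 40: below min_alt_frac
  expect_equal(calls2$genotype[calls2$pos == 15], "hom-ref")
  calls3 <- call_snvs(pileup(reads_alt(1, 39), ref))   # dominated by alt
  expect_equal(calls3$genotype[calls3$pos == 15], "hom-alt")
})

test_that("support filtering keeps DP>=10, AD>=2, bi-allelic sites only", {
  calls <- data.frame(
    seqid = "chr1", pos = 1:4, ref = "A", alt = "C",
    dp = c(10L, 9L, 50L, 12L), rd = c(8L, 4L, 20L, 12L),
    ad = c(2L, 5L, 18L, 0L),
    genotype = c("het", "het", "het", "hom-ref"),
    n_alleles = c(2L, 2L, 3L, 1L))
  kept <- filter_supported_snvs(calls)
  expect_equal(kept$pos, 1L)  # boundary kept; shallow, tri-allelic, hom-ref dropped
})

test_that("duplicated-k-mer masking follows the construction oracle", {
  set.seed(61)
  block <- rand_dna(1000)
  asm <- c(s1 = block, s2 = block)     # verbatim duplicate of a unique block
  reads <- vapply(1:500, function(i) {
    off <- sample(1000 - 100, 1)
    substring(block, off, off + 99)
  }, "")
  mask <- duplicated_kmer_mask(asm, reads, k = 57, depth_band = c(5, 500))
  expect_setequal(unique(as.data.frame(mask)$seqid), c("s1", "s2"))
  expect_gt(total_length(mask), 2 * 1000 - 4 * 57)  # edge effects only
  expect_lte(total_length(mask), 2 * 1000)
  # no repeated k-mer -> empty mask
  asm2 <- c(s1 = rand_dna(500), s2 = rand_dna(500))
  expect_equal(total_length(duplicated_kmer_mask(asm2, reads, k = 57,
                                                 depth_band = c(0, 1e6))), 0)
  # depth band excludes shallow k-mers
  tbl <- count_kmers(substring(block, 1, 200), 57)
  tbl[] <- 10
  m_in <- duplicated_kmer_mask(asm, tbl, k = 57, depth_band = c(5, 200))
  m_out <- duplicated_kmer_mask(asm, tbl, k = 57, depth_band = c(20, 200) + 15)
  expect_gt(total_length(m_in), 0)
  expect_equal(total_length(m_out), 0)
})

test_that("heterozygosity bookkeeping conserves lengths and is monotone", {
  set.seed(62)
  callable <- rand_iset(10, 5e4)
  mask <- rand_iset(6, 5e4)
  calls <- data.frame(seqid = "s", pos = sort(sample.int(5e4, 200) - 1),
                      ref = "A", alt = "C", dp = 30L, rd = 15L, ad = 15L,
                      genotype = "het", n_alleles = 2L)
  est <- heterozygosity_rate(calls, callable, mask)
  expect_equal(est$corrected_callable_length + est$masked_length,
               est$callable_length)
  expect_equal(est$het_rate_pct, 100 * est$het_snv_count /
                 est$corrected_callable_length)
  # growing the mask never grows the count or the callable length
  bigger <- interval_merge(mask, rand_iset(6, 5e4))
  est2 <- heterozygosity_rate(calls, callable, bigger)
  expect_lte(est2$het_snv_count, est$het_snv_count)
  expect_lte(est2$corrected_callable_length, est$corrected_callable_length)
  # zero het calls -> zero rate
  none <- heterozygosity_rate(calls[0, ], callable, mask)
  expect_equal(none$het_rate_pct, 0)
  # nothing callable left -> undefined rate
  expect_error(heterozygosity_rate(calls, callable, callable), "undefined")
})

test_that("pileup het-site allele balance matches the binomial oracle", {
  sim <- tiny_sim(seed = 12, genome_length = 2e4, depth = 100, error_rate = 0)
  p <- pileup(alignments_from_reads(sim$reads, sim$genome), sim$genome)
  v <- sim$genome$variants
  m <- p$counts[["chr1"]]
  fr <- vapply(seq_len(nrow(v)), function(i) {
    col <- m[, v$pos[i] + 1]
    col[[v$b[i]]] / sum(col)
  }, 0)
  expect_lt(abs(mean(fr) - 0.5), 0.02)
  expect_true(all(abs(fr - 0.5) < 3.5 * sqrt(0.25 / 100) + 0.02))
})

test_that("VCF round-trips calls exactly", {
  calls <- data.frame(
    seqid = c("chr1", "chr1", "chr2"), pos = c(4L, 99L, 0L),
    ref = c("A", "G", "T"), alt = c("C", "A", "G"),
    dp = c(30L, 12L, 44L), rd = c(15L, 10L, 1L), ad = c(15L, 2L, 43L),
    genotype = c("het", "het", "hom-alt"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, path, contig_lengths = c(chr1 = 200, chr2 = 100))
  back <- read_snv_vcf(path)
  expect_equal(back[, colnames(calls)], calls)
})
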
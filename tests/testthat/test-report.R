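test_that("coverage arithmetic reproduces published-scale figures", {
  yield <- sequencing_yield(338.6e6, 251)
  expect_equal(round(yield / 1e9, 2), 169.98)
  expect_equal(sequencing_coverage(yield, 700178345), 242.76)
  expect_equal(sequencing_coverage(3.55e9, 700178345), 5.07)
  expect_equal(sequencing_coverage(1e6, 1e6), 1)
  expect_error(sequencing_coverage(1e6, 0), "positive")
})

test_that("annotation summary derives the printed ratios", {
  s <- annotation_summary(62652, 70788, assembly_length = 606969498)
  expect_equal(s$transcripts_per_gene, 1.13)
  expect_equal(s$gene_density_per_mb, 103.22)
  t <- annotation_summary(10, 10, assembly_length = 1e6)
  expect_equal(t$transcripts_per_gene, 1)
  expect_equal(t$gene_density_per_mb, 10)
  expect_error(annotation_summary(0, 5, assembly_length = 1e6), "zero")
})

test_that("annotation counts can be read from GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tx\tgene\t1\t900\t.\t+\t.\tID=g1",
    "s1\tx\tmRNA\t1\t900\t.\t+\t.\tID=t1;Parent=g1",
    "s1\tx\texon\t1\t300\t.\t+\t.\tParent=t1",
    "s1\tx\texon\t600\t900\t.\t+\t.\tParent=t1",
    "s1\tx\tgene\t1000\t1500\t.\t-\t.\tID=g2",
    "s1\tx\tmRNA\t1000\t1500\t.\t-\t.\tID=t2;Parent=g2",
    "s1\tx\tmRNA\t1000\t1400\t.\t-\t.\tID=t3;Parent=g2",
    "s1\tx\texon\t1000\t1500\t.\t-\t.\tParent=t2"), gff)
  counts <- annotation_counts_from_gff(gff)
  expect_equal(counts$gene_count, 2)
  expect_equal(counts$transcript_count, 3)
  expect_equal(counts$exon_count, 3)
})

test_that("orthogroup summary counts coverage and orphans", {
  m <- data.frame(
    orthogroup = c("OG1", "OG1", "OG2", "OG2", "OG3"),
    species = c("focal", "outgrpA", "focal", "outgrpA", "outgrpA"),
    gene = c("p1", "r1", "p2", "r2", "r3"))
  s <- orthogroup_summary(m, c(focal = 10, outgrpA = 5))
  pc <- s[s$species == "focal", ]
  expect_equal(pc$orthogroups, 2)
  expect_equal(pc$pct_orthogroups, 66.7)
  expect_equal(pc$orphan_genes, 8)
  # absent species
  s2 <- orthogroup_summary(m, c(focal = 10, outgrpA = 5, outgrpB = 7))
  expect_equal(s2$pct_orthogroups[s2$species == "outgrpB"], 0)
  expect_equal(s2$orphan_genes[s2$species == "outgrpB"], 7)
  m_bad <- rbind(m, data.frame(orthogroup = "OG3", species = "focal", gene = "p1"))
  expect_error(orthogroup_summary(m_bad, c(focal = 10, outgrpA = 5)), "more than one")
  # published-scale arithmetic
  expect_equal(round(100 * 12061 / 12419, 1), 97.1)
  expect_equal(62652 - 23611, 39041)
})

test_that("planted microsatellites are located and classified", {
  set.seed(81)
  flank <- function(n) rand_dna(n)
  pf <- rand_dna(20); pr <- rand_dna(20)
  inner <- paste0(flank(30), strrep("TA", 12), flank(30))
  scaf <- paste0(flank(300), pf, inner, rc_chr(pr), flank(300))
  gm <- GenomicRanges::GRanges("s1",
          IRanges::IRanges(c(1, 1, 500), c(nchar(scaf), 250, nchar(scaf))),
          type = c("gene", "exon", "exon"))
  mk <- data.frame(name = "M1", primer_f = pf, primer_r = pr, motif = "TA")
  loc <- locate_microsatellites(mk, c(s1 = scaf), gm)
  expect_true(loc$placed)
  expect_equal(loc$motif_observed, "TA")
  expect_true(loc$compatible)
  expect_equal(loc$context, "intronic")
  expect_equal(loc$motif_end - loc$motif_start, 24)
  # no gene models -> intergenic elsewhere
  gm2 <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 10), type = "gene")
  expect_equal(locate_microsatellites(mk, c(s1 = scaf), gm2)$context,
               "intergenic")
  # declared unit disagreeing with the observed run is noted, not an error
  mk2 <- data.frame(name = "M2", primer_f = pf, primer_r = pr, motif = "TTAT")
  loc2 <- locate_microsatellites(mk2, c(s1 = scaf), gm)
  expect_false(loc2$compatible)
  expect_match(loc2$note, "instead of")
  # a planted (TTAT)n run is reported with its longer unit
  scaf3 <- paste0(flank(200), pf, flank(20), strrep("TTAT", 10), flank(20),
                  rc_chr(pr), flank(200))
  loc3 <- locate_microsatellites(
    data.frame(name = "M3", primer_f = pf, primer_r = pr, motif = "TTAT"),
    c(s1 = scaf3))
  expect_equal(nchar(loc3$motif_observed), 4)
  expect_true(loc3$compatible)
  # absent primer pair -> unplaced, no error
  mk4 <- data.frame(name = "M4", primer_f = strrep("ACGT", 5), primer_r = pr,
                    motif = "TA")
  loc4 <- locate_microsatellites(mk4, c(s1 = scaf))
  expect_false(loc4$placed)
  expect_error(locate_microsatellites(
    data.frame(name = "M5", primer_f = "ACGT", primer_r = pr, motif = "TA"),
    c(s1 = scaf)), "15 bases")
})

test_that("markers plant and recover cleanly across a simulated assembly", {
  set.seed(82)
  cfg <- sim_config(genome_length = 1e5, het_rate = 0, repeat_fraction = 0,
                    seed = 14)
  g <- simulate_diploid_genome(cfg)
  asm <- make_fragmented_assembly(g, cfg)
  seqs <- asm$seqs
  planted <- lapply(1:4, function(i) {
    pf <- rand_dna(20); pr <- rand_dna(20)
    unit <- sample(c("TA", "CA", "TTG"), 1)
    ins <- paste0(pf, rand_dna(15), strrep(unit, 10), rand_dna(15), rc_chr(pr))
    j <- sample(length(seqs), 1)
    seqs[[j]] <<- paste0(seqs[[j]], ins)
    data.frame(name = paste0("P", i), primer_f = pf, primer_r = pr, motif = unit)
  })
  mk <- do.call(rbind, planted)
  loc <- locate_microsatellites(mk, seqs)
  expect_true(all(loc$placed))
  expect_true(all(loc$compatible))
})
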
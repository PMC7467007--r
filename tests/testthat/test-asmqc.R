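test_that("Nx follows the sort-and-scan definition", {
  asm <- c(a = strrep("A", 10), b = strrep("C", 5), c = strrep("G", 3),
           d = strrep("T", 2))
  nx <- nx_table(asm, step = 5)
  r50 <- nx[nx$x == 50, ]
  expect_equal(r50$scaffold_length, 5)   # cumulative 15 > 10
  expect_equal(r50$scaffold_count, 2)
  expect_equal(nx$scaffold_length[nx$x == 0], 10)
  expect_equal(nx$scaffold_count[nx$x == 0], 1)
  expect_equal(nx$scaffold_length[nx$x == 100], 2)
  expect_equal(nx$scaffold_count[nx$x == 100], 4)
  tot <- attr(nx, "totals")
  expect_equal(tot$scaffold_length, 20)
  expect_equal(tot$scaffold_count, 4)

  single <- nx_table(c(s = strrep("A", 1234)))
  expect_true(all(single$scaffold_length == 1234))
  expect_true(all(single$scaffold_count == 1))
})

test_that("scaffolds split into contigs at N runs of gap_run_min", {
  asm <- c(s = paste0("ACGT", strrep("N", 10), "ACGT"))
  nx <- nx_table(asm, gap_run_min = 10)
  tot <- attr(nx, "totals")
  expect_equal(tot$contig_count, 2)
  expect_equal(tot$contig_length, 8)
  expect_equal(tot$scaffold_count, 1)
  expect_equal(tot$scaffold_length, 18)
  # a 9-N run does not split
  expect_equal(attr(nx_table(c(s = paste0("ACGT", strrep("N", 9), "ACGT")),
                             gap_run_min = 10), "totals")$contig_count, 1)
})

test_that("Nx agrees with the brute-force oracle on random length sets", {
  set.seed(51)
  for (rep in 1:5) {
    lens <- sample.int(5e4, sample(50:1000, 1), replace = TRUE)
    asm <- setNames(vapply(lens, function(l) strrep("A", l), ""),
                    paste0("s", seq_along(lens)))
    nx <- nx_table(asm, step = 10)
    for (x in c(0, 10, 50, 90, 100)) {
      want <- oracle_nx(lens, x)
      row <- nx[nx$x == x, ]
      expect_equal(row$scaffold_length, want$length, info = paste("x =", x))
      expect_equal(row$scaffold_count, want$count, info = paste("x =", x))
    }
    # monotonicity invariants
    expect_true(all(diff(nx$scaffold_length) <= 0))
    expect_true(all(diff(nx$scaffold_count) >= 0))
  }
})

test_that("explicit coverage cut-offs are returned verbatim", {
  cuts <- find_coverage_cutoffs(data.frame(depth = 1, count = 1),
                                low = 32, midpoint = 143, high = 273)
  expect_equal(unclass(cuts), list(low = 32, midpoint = 143, high = 273))
  expect_error(find_coverage_cutoffs(data.frame(depth = 1, count = 1),
                                     low = 200, midpoint = 143, high = 273),
               "low < midpoint < high")
  expect_error(find_coverage_cutoffs(data.frame(depth = integer(0),
                                                count = numeric(0))), "empty")
})

test_that("bimodal depth histograms yield ordered cut-offs; unimodal warns", {
  d <- 1:300
  bim <- data.frame(depth = d,
                    count = 4e4 * exp(-0.5 * ((d - 72) / 9)^2) +
                            8e4 * exp(-0.5 * ((d - 143) / 13)^2))
  cuts <- find_coverage_cutoffs(bim)
  expect_lt(cuts$low, 72)
  expect_gt(cuts$midpoint, 72)
  expect_lt(cuts$midpoint, 143)
  expect_gt(cuts$high, 143)
  uni <- data.frame(depth = d, count = 8e4 * exp(-0.5 * ((d - 100) / 11)^2))
  expect_warning(cuts1 <- find_coverage_cutoffs(uni), "unimodal")
  expect_equal(cuts1$midpoint, 100)
})

test_that("coverage classification flags junk and partitions completely", {
  cuts <- find_coverage_cutoffs(data.frame(depth = 1, count = 1),
                                low = 32, midpoint = 72, high = 140)
  depth <- list(deep = S4Vectors::Rle(100L, 1000),
                shallow = S4Vectors::Rle(10L, 1000),
                haploid = S4Vectors::Rle(50L, 1000))
  fl <- classify_scaffolds_by_coverage(depth, cuts)
  expect_equal(fl$flag[match(c("deep", "shallow", "haploid"), fl$scaffold)],
               c("keep", "junk", "suspect"))
  expect_equal(sort(fl$scaffold), sort(names(depth)))  # exactly one flag each
  # idempotent
  expect_identical(classify_scaffolds_by_coverage(depth, cuts), fl)
  expect_error(classify_scaffolds_by_coverage(depth, cuts,
                                              scaffolds = c("deep", "absent")),
               "absent")
})

test_that("haplotig purge recovers the haploid assembly on simulations", {
  cfg <- sim_config(genome_length = 4e5, het_rate = 0.007, repeat_fraction = 0,
                    duplication_fraction = 0.2, depth = 100, read_length = 150,
                    fragment_mean = 400, error_rate = 0.003, seed = 31)
  g <- simulate_diploid_genome(cfg)
  rs <- simulate_reads(g, cfg)
  asm <- make_fragmented_assembly(g, cfg)
  al <- alignments_from_reads(rs, asm)
  dep <- depth_from_alignments(al, asm)
  cuts <- find_coverage_cutoffs(depth_histogram(dep))
  fl <- classify_scaffolds_by_coverage(dep, cuts)
  flagged_haplotigs <- fl$flag[fl$scaffold %in% asm$haplotig_names]
  expect_gte(mean(flagged_haplotigs == "suspect"), 0.9)
  kept <- purge_scaffolds(asm, fl)
  haploid <- cfg$genome_length + asm$gap_length
  expect_lt(abs(sum(nchar(kept)) - haploid) / haploid, 0.05)
  # purge never removes much more than the duplicated fraction
  removed <- sum(nchar(asm$seqs)) - sum(nchar(kept))
  expect_lte(removed / sum(nchar(asm$seqs)),
             cfg$duplication_fraction + 0.05)
})

test_that("contaminant scaffold vote follows the majority/tie rules", {
  crit <- data.frame(
    scaffold = c("host1", "host2", "host3", "bact", "tie"),
    gc = c(0.38, 0.40, 0.37, 0.62, 0.39),
    foreign_gene_hits = c(0, 1, 0, 12, 5),
    host_gene_hits = c(9, 6, 4, 0, 1),
    has_expression = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    has_species_repeats = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  fl <- flag_contaminant_scaffolds(crit)
  expect_equal(fl$flag[fl$scaffold == "bact"], "contaminant")
  expect_equal(fl$flag[fl$scaffold == "host1"], "keep")
  expect_equal(fl$flag[fl$scaffold == "tie"], "keep")  # 2 vs 2 retains
  expect_error(flag_contaminant_scaffolds(crit[0, ]), "empty")
  # abstentions: all-NA row keeps
  crit2 <- data.frame(scaffold = "na", gc = NA, foreign_gene_hits = NA,
                      host_gene_hits = NA, has_expression = NA,
                      has_species_repeats = NA)
  expect_equal(flag_contaminant_scaffolds(crit2,
                                          gc_band = c(0.36, 0.42))$flag, "keep")
})
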
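test_that("zero heterozygosity gives identical haplotypes", {
  cfg <- sim_config(genome_length = 2e4, het_rate = 0, repeat_fraction = 0,
                    seed = 1)
  g <- simulate_diploid_genome(cfg)
  expect_identical(g$hap_a, g$hap_b)
  expect_equal(nrow(g$variants), 0)
})

test_that("planted SNV count follows the binomial oracle", {
  cfg <- sim_config(genome_length = 1e6, het_rate = 0.007, repeat_fraction = 0,
                    seed = 1)
  g <- simulate_diploid_genome(cfg)
  n <- nrow(g$variants)
  expect_lt(abs(n - 7000), 3 * sqrt(7000))
  # haplotypes differ exactly at the recorded positions
  ca <- strsplit(g$hap_a[["chr1"]], "")[[1]]
  cb <- strsplit(g$hap_b[["chr1"]], "")[[1]]
  expect_equal(which(ca != cb) - 1L, g$variants$pos)
  expect_equal(ca[g$variants$pos + 1], g$variants$a)
  expect_equal(cb[g$variants$pos + 1], g$variants$b)
})

test_that("repeat fraction lands near the request", {
  cfg <- sim_config(genome_length = 1e6, het_rate = 0, repeat_fraction = 0.5,
                    n_repeat_families = 12, seed = 2)
  g <- simulate_diploid_genome(cfg)
  got <- total_length(g$repeat_intervals)
  expect_gte(got, 450000)
  expect_lte(got, 550000)
})

test_that("read yield matches the coverage accounting", {
  sim <- tiny_sim(seed = 5, genome_length = 1e5, depth = 30)
  bases <- sum(nchar(sim$reads$r1)) + sum(nchar(sim$reads$r2))
  expect_gte(bases, 0.97 * 30 * 1e5)
  expect_lte(bases, 1.03 * 30 * 1e5)
})

test_that("error-free reads substring-match their origin haplotype", {
  sim <- tiny_sim(seed = 6, genome_length = 3e4, depth = 5, error_rate = 0)
  rs <- sim$reads; g <- sim$genome
  idx <- sample(n_pairs(rs), 50)
  for (i in idx) {
    h <- if (rs$origin$hap[i] == "A") g$hap_a[["chr1"]] else g$hap_b[["chr1"]]
    expect_identical(rs$r1[i],
                     substring(h, rs$origin$start1[i] + 1,
                               rs$origin$start1[i] + rs$read_length))
    expect_identical(rc_chr(rs$r2[i]),
                     substring(h, rs$origin$start2[i] + 1,
                               rs$origin$start2[i] + rs$read_length))
  }
})

test_that("a fixed seed reproduces byte-identical FASTQ and FASTA", {
  dir <- tempfile(); dir.create(dir)
  out <- replicate(2, {
    sim <- tiny_sim(seed = 9, genome_length = 2e4, depth = 4, error_rate = 0.01)
    r1 <- file.path(dir, paste0(basename(tempfile()), "_1.fq"))
    r2 <- sub("_1.fq", "_2.fq", r1)
    fa <- sub("_1.fq", ".fa", r1)
    write_reads_fastq(sim$reads, r1, r2)
    write_genome_fasta(sim$genome, fa)
    c(tools::md5sum(r1), tools::md5sum(r2), tools::md5sum(fa))
  })
  expect_identical(unname(out[, 1]), unname(out[, 2]))
})

test_that("contaminant injection respects fraction and mixing ratio", {
  sim <- tiny_sim(seed = 10, genome_length = 1e5, depth = 20)
  refs <- c(alpha = rand_dna(4000), beta = rand_dna(4000))
  expect_identical(inject_contaminants(sim$reads, refs, 0), sim$reads)
  expect_error(inject_contaminants(sim$reads, character(0), 0.1), "empty")
  mixed <- inject_contaminants(sim$reads, refs, 0.2, proportions = c(3, 1),
                               seed = 4)
  n <- n_pairs(mixed)
  n_cont <- sum(mixed$source != "host")
  expect_lt(abs(n_cont - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
  tab <- table(mixed$source[mixed$source != "host"])
  ratio <- tab[["contaminant:alpha"]] / tab[["contaminant:beta"]]
  expect_gt(ratio, 2)  # 3:1 within multinomial noise
  expect_lt(ratio, 4.5)
})

test_that("realized simulation rates stay within 3 sigma over many seeds", {
  for (seed in 1:20) {
    cfg <- sim_config(genome_length = 3e4, het_rate = 0.01, repeat_fraction = 0,
                      depth = 8, read_length = 100, fragment_mean = 250,
                      seed = seed)
    g <- simulate_diploid_genome(cfg)
    expect_lt(abs(nrow(g$variants) - 300), 3 * sqrt(300 * 0.99))
  }
})

test_that("assembly length accounting tracks the duplication fraction", {
  cfg0 <- sim_config(genome_length = 2e5, het_rate = 0.007, repeat_fraction = 0,
                     duplication_fraction = 0, seed = 12)
  g <- simulate_diploid_genome(cfg0)
  a0 <- make_fragmented_assembly(g, cfg0)
  expect_equal(sum(nchar(a0$seqs)), 2e5 + a0$gap_length)
  expect_equal(length(a0$haplotig_names), 0)

  cfg2 <- sim_config(genome_length = 2e5, het_rate = 0.007, repeat_fraction = 0,
                     duplication_fraction = 0.2, seed = 12)
  a2 <- make_fragmented_assembly(g, cfg2)
  tot <- sum(nchar(a2$seqs)) - a2$gap_length
  expect_gt(tot, 1.15 * 2e5)
  expect_lt(tot, 1.25 * 2e5)
  # haplotig scaffolds are exact haplotype-B copies of the truth intervals
  dup <- as.data.frame(a2$duplicated_intervals)
  expect_equal(sum(nchar(a2$seqs[a2$haplotig_names])), sum(dup$end - dup$start))
})

test_that("non-duplicated assembly sequence maps back to haplotype A", {
  cfg <- sim_config(genome_length = 1e5, het_rate = 0.005, repeat_fraction = 0,
                    duplication_fraction = 0.15, seed = 13)
  g <- simulate_diploid_genome(cfg)
  asm <- make_fragmented_assembly(g, cfg)
  pm <- asm$piece_map[asm$piece_map$src == "A", ]
  for (i in seq_len(nrow(pm))) {
    piece <- substring(asm$seqs[[pm$scaffold[i]]], pm$scaff_start[i] + 1,
                       pm$scaff_start[i] + (pm$src_end[i] - pm$src_start[i]))
    expect_identical(piece, substring(g$hap_a[["chr1"]], pm$src_start[i] + 1,
                                      pm$src_end[i]))
  }
  # every haplotype-A base is emitted exactly once across primary pieces
  expect_equal(sum(pm$src_end - pm$src_start), 1e5)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(het_rate = 0.2), "het_rate")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(
    simulate_reads(simulate_diploid_genome(sim_config(genome_length = 2e4,
                                                      fragment_mean = 120,
                                                      read_length = 150,
                                                      seed = 1))),
    "fragment_mean")
  cfg <- sim_config(genome_length = 1500, repeat_fraction = 0.85, seed = 1)
  expect_error(simulate_diploid_genome(cfg), "too small")
})

test_that("config files round-trip", {
  cfg <- sim_config(genome_length = 5e4, het_rate = 0.012, seed = 77)
  path <- tempfile()
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$genome_length, cfg$genome_length)
  expect_equal(cfg2$het_rate, cfg$het_rate)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$quality_mode, cfg$quality_mode)
})
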
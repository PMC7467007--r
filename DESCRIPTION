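Package: hetscope
Title: Genome Characterization and Corrected Heterozygosity from K-mer Spectra and Read Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale characterization of a heterozygous diploid
    genome from short-read data: canonical k-mer counting and spectrum
    histograms, a diploid negative-binomial mixture fit estimating haploid
    genome size, heterozygosity, repeat content and read error rate,
    contaminant read screening at a fixed mismatch budget with fixed-length
    trimming, assembly contiguity (Nx) statistics, coverage-based haplotig and
    junk scaffold classification, and a corrected SNV heterozygosity estimate
    in which callable sites are purged of artificially duplicated k-mers
    before the rate is computed. A bundled synthetic diploid genome and read
    generator with truth files supports parameter-recovery testing of every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
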
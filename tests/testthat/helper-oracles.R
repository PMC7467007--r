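# Brute-force oracles, independent of the package's implementation paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# dictionary-scan k-mer counter
oracle_kmer_count <- function(seqs, k, canonical = TRUE) {
  acc <- new.env()
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substring(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      if (canonical) {
        r <- rc_chr(w)
        if (r < w) w <- r
      }
      acc[[w]] <- (if (is.null(acc[[w]])) 0L else acc[[w]]) + 1L
    }
  }
  out <- unlist(as.list(acc))
  if (is.null(out)) return(setNames(integer(0), character(0)))
  out[order(names(out))]
}

# all-positions Hamming screen: does `read` match any ref on either strand
# with at most floor(frac * nchar(read)) substitutions?
oracle_screen_match <- function(read, refs, frac = 0.02) {
  budget <- floor(frac * nchar(read))
  for (r in toupper(refs)) {
    for (q in c(toupper(read), rc_chr(read))) {
      L <- nchar(q)
      if (nchar(r) < L) next
      qs <- strsplit(q, "")[[1]]
      rs <- strsplit(r, "")[[1]]
      for (off in 0:(nchar(r) - L)) {
        if (sum(qs != rs[(off + 1):(off + L)]) <= budget) return(TRUE)
      }
    }
  }
  FALSE
}

# sort-and-scan Nx oracle (frozen convention: first sequence whose cumulative
# descending length strictly exceeds x% of the total; N100 = shortest)
oracle_nx <- function(lengths, x) {
  l <- sort(lengths, decreasing = TRUE)
  total <- sum(l)
  if (x >= 100) return(list(length = l[length(l)], count = length(l)))
  cum <- 0
  for (i in seq_along(l)) {
    cum <- cum + l[i]
    if (cum > x / 100 * total) return(list(length = l[i], count = i))
  }
}

# boolean-array interval oracle over a single sequence of length n
oracle_interval_op <- function(a, b, op, n) {
  va <- rep(FALSE, n); vb <- rep(FALSE, n)
  for (i in seq_len(nrow(a))) va[(a$start[i] + 1):a$end[i]] <- TRUE
  if (nrow(b) > 0) for (i in seq_len(nrow(b))) vb[(b$start[i] + 1):b$end[i]] <- TRUE
  v <- switch(op, merge = va | vb, subtract = va & !vb, intersect = va & vb)
  if (!any(v)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

rand_iset <- function(n_iv, n, seqid = "s") {
  start <- sort(sample.int(n - 2, n_iv))
  width <- sample.int(ceiling(n / n_iv), n_iv, replace = TRUE)
  interval_set(rep(seqid, n_iv), start, pmin(start + width, n))
}

# small deterministic simulation shared across test files
tiny_sim <- function(seed = 3, genome_length = 5e4, het_rate = 0.007,
                     depth = 50, error_rate = 0, ...) {
  cfg <- sim_config(genome_length = genome_length, het_rate = het_rate,
                    repeat_fraction = 0, depth = depth, read_length = 100,
                    fragment_mean = 300, fragment_sd = 30,
                    error_rate = error_rate, seed = seed, ...)
  g <- simulate_diploid_genome(cfg)
  list(cfg = cfg, genome = g, reads = simulate_reads(g, cfg))
}
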
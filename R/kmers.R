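as_char_seqs <- function(x) {
  if (inherits(x, "read_set")) return(c(x$r1, x$r2))
  if (inherits(x, "sim_assembly")) return(unname(x$seqs))
  if (inherits(x, "diploid_genome")) return(unname(c(x$hap_a, x$hap_b)))
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString"))
    return(as.character(x))
  if (is.character(x)) return(unname(x))
  stop("cannot interpret input as DNA sequences")
}

#' Count k-mers in a set of sequences
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and its
#' reverse complement; reads come from both strands) by default. Windows
#' containing non-ACGT characters are skipped. Returns the full count table as
#' a named vector and is therefore intended for modest inputs; use
#' [kmer_histogram()] for read-scale spectra.
#'
#' @param x Sequences: character vector, `DNAStringSet`, `read_set`,
#'   `diploid_genome` or `sim_assembly`.
#' @param k Odd k-mer length in `[11, 63]` (smaller values are accepted with
#'   `strict = FALSE`, used by the enumeration examples/tests).
#' @param canonical Collapse reverse complements (default `TRUE`).
#' @param strict Enforce the odd-k, `k >= 11` convention.
#' @return Named integer vector of k-mer counts.
#' @examples
#' count_kmers("ACGTA", k = 3, canonical = FALSE, strict = FALSE)
#' @export
count_kmers <- function(x, k, canonical = TRUE, strict = TRUE) {
  seqs <- as_char_seqs(x)
  if (length(seqs) == 0) stop("no sequences supplied")
  if (strict && (k %% 2 == 0 || k < 11 || k > 63))
    stop("k must be odd and in [11, 63]")
  if (all(nchar(seqs) < k)) {
    warning("k is larger than every sequence; empty count table")
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- cpp_kmer_table(seqs, as.integer(k), canonical)
  out <- stats::setNames(tab$count, tab$kmer)
  out[order(names(out))]
}

#' K-mer spectrum histogram
#'
#' Distinct k-mers per depth, the k-mer spectrum used to read off coverage
#' peaks and fit the diploid mixture model. Depths above `max_depth` are
#' pooled into the `max_depth` bin (so the sum of `depth * count` is conserved
#' for all k-mers up to that truncation depth).
#'
#' @param x Sequences (as in [count_kmers()]) or a named count vector from
#'   [count_kmers()].
#' @param k K-mer length (required when `x` is raw sequence).
#' @param canonical Canonical counting (default `TRUE`).
#' @param max_depth Truncation depth (default 250).
#' @return A data frame of class `kmer_histogram` with columns `depth`
#'   (1..`max_depth`) and `count`, and attributes `k` and `max_depth`.
#' @export
kmer_histogram <- function(x, k = NULL, canonical = TRUE, max_depth = 250) {
  if (is.numeric(x) && !is.null(names(x))) {
    if (is.null(k)) k <- nchar(names(x)[1])
    d <- pmin(as.integer(x), max_depth)
    counts <- tabulate(d, nbins = max_depth)
  } else {
    if (is.null(k)) stop("k must be supplied when counting from sequences")
    counts <- cpp_kmer_spectrum(as_char_seqs(x), as.integer(k), canonical,
                                as.integer(max_depth))
  }
  structure(data.frame(depth = seq_len(max_depth), count = as.numeric(counts)),
            k = as.integer(k), max_depth = as.integer(max_depth),
            class = c("kmer_histogram", "data.frame"))
}

#' Read/write a k-mer histogram as TSV
#'
#' Two-column `depth<TAB>distinct_kmers` files, the de-facto k-mer histogram
#' dialect.
#'
#' @param hist A `kmer_histogram`.
#' @param path File path.
#' @param k K-mer length to attach on read (histogram files do not carry it).
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(data.frame(depth = hist$depth, distinct_kmers = hist$count),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_histogram
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(data.frame(depth = df[[1]], count = as.numeric(df[[2]])),
            k = as.integer(k), max_depth = max(df[[1]]),
            class = c("kmer_histogram", "data.frame"))
}

# centered moving average with shrinking windows at the edges (a fixed-width
# filter padded with the raw series would fabricate edge peaks next to the
# tall error bin at depth 1)
smooth_counts <- function(y, window) {
  if (window <= 1) return(y)
  n <- length(y)
  w2 <- floor(window / 2)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - w2, 1)
  hi <- pmin(seq_len(n) + w2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect coverage peaks in a k-mer spectrum
#'
#' Finds the error boundary (first local minimum after depth 1, below which
#' counts are attributed to sequencing errors), then the homozygous-unique
#' peak depth and, when present, the heterozygous peak at roughly half that
#' depth. If the global maximum itself has a companion maximum near twice its
#' depth (a spectrum dominated by the heterozygous peak), the lower peak is
#' reported as heterozygous and the higher as homozygous.
#'
#' @param hist A [kmer_histogram()].
#' @param smooth_window Width of the moving-average smoother.
#' @param min_peak_frac Local maxima below this fraction of the tallest peak
#'   are ignored.
#' @param ratio_tol Acceptable het/hom depth ratio window around 0.5 (a pair
#'   is linked when the depth ratio is within `0.5 * c(1 - ratio_tol, 1 +
#'   ratio_tol)`).
#' @return List of class `peak_set`: `hom_depth`, `het_depth` (`NA` when no
#'   heterozygous peak), `error_boundary`.
#' @export
detect_peaks <- function(hist, smooth_window = 5, min_peak_frac = 0.02,
                         ratio_tol = 0.2) {
  y <- smooth_counts(hist$count, smooth_window)
  n <- length(y)
  # error boundary: first local minimum after depth 1 (depth 1 if the spectrum
  # does not open with an error slope)
  boundary <- 1L
  if (n > 2 && y[1] > y[2]) {
    for (d in 2:(n - 1)) {
      if (y[d] <= y[d - 1] && y[d] < y[d + 1]) { boundary <- d; break }
    }
  }
  region <- seq(boundary, n)
  if (all(y[region] <= 0)) stop("no coverage peak detected beyond the error region")
  ymax <- max(y[region])
  is_max <- vapply(region, function(d) {
    left <- if (d == 1) -Inf else y[d - 1]
    right <- if (d == n) -Inf else y[d + 1]
    y[d] >= left && y[d] > right
  }, TRUE)
  peaks <- region[is_max & y[region] >= min_peak_frac * ymax]
  if (length(peaks) == 0) stop("no coverage peak detected beyond the error region")
  d_top <- peaks[which.max(y[peaks])]

  lo <- 0.5 * (1 - ratio_tol); hi <- 0.5 * (1 + ratio_tol)
  half <- peaks[peaks < d_top & peaks / d_top >= lo & peaks / d_top <= hi]
  dbl <- peaks[peaks > d_top & d_top / peaks >= lo & d_top / peaks <= hi]
  if (length(half) > 0) {
    het <- half[which.max(y[half])]
    hom <- d_top
  } else if (length(dbl) > 0) {
    het <- d_top
    hom <- dbl[which.max(y[dbl])]
  } else {
    het <- NA_integer_
    hom <- d_top
  }
  structure(list(hom_depth = as.integer(hom), het_depth = as.integer(het),
                 error_boundary = as.integer(boundary)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peaks: hom depth %d, het depth %s, error boundary %d\n",
              x$hom_depth,
              ifelse(is.na(x$het_depth), "absent", x$het_depth),
              x$error_boundary))
  invisible(x)
}

#' Fit a diploid mixture model to a k-mer spectrum
#'
#' Fits four negative-binomial components centred at depths lambda/2, lambda,
#' 3*lambda/2 and 2*lambda (heterozygous-unique, homozygous-unique and the
#' first repeat copies) with a shared overdispersion parameter, by bounded
#' nonlinear least squares on the square-root-scaled histogram, initialized
#' from [detect_peaks()]. Counts below the error boundary are treated as the
#' sequencing-error component: they are excluded from the fit and from the
#' genome-size sum, and they determine the read error rate via the fraction
#' of k-mer observations carrying at least one error,
#' `1 - (1 - e)^k = errors/total`.
#'
#' Estimates: haploid genome length `sum(depth * count beyond the boundary) /
#' lambda`; heterozygosity from the heterozygous/homozygous component weights
#' via `het = 1 - (1 - h)^(1/k)` where `h` is the fraction of genomic k-mer
#' windows overlapping a heterozygous site; repeat length as the genome
#' length not attributable to the unique components; model fit as `100 * (1 -
#' sum|obs - fitted| / sum obs)` over the fitted range.
#'
#' @param hist A [kmer_histogram()].
#' @param k K-mer length (defaults to the histogram's `k` attribute).
#' @param peaks Optional [detect_peaks()] result (detected if omitted).
#' @param smooth_window Passed to [detect_peaks()].
#' @return A list of class `spectrum_fit` with fields `genome_haploid_length`,
#'   `het_rate_pct`, `repeat_length`, `unique_length`, `repeat_pct`,
#'   `read_error_rate_pct`, `hom_depth` (fitted lambda), `model_fit_pct`, `k`,
#'   `weights`, `overdispersion`, `converged`, `peaks`.
#' @export
fit_diploid_model <- function(hist, k = attr(hist, "k"), peaks = NULL,
                              smooth_window = 5) {
  if (is.null(k) || is.na(k)) stop("k-mer length unknown; pass k explicitly")
  if (is.null(peaks)) peaks <- detect_peaks(hist, smooth_window = smooth_window)
  lam0 <- peaks$hom_depth
  boundary <- peaks$error_boundary
  max_depth <- attr(hist, "max_depth")
  if (is.null(max_depth)) max_depth <- max(hist$depth)

  fit_bins <- hist$depth >= boundary & hist$depth < max_depth  # pooled bin excluded
  d <- hist$depth[fit_bins]
  obs <- hist$count[fit_bins]

  comp_pred <- function(dd, lambda, phi, w) {
    mu <- lambda * (1:4) / 2
    pred <- 0
    for (j in 1:4) pred <- pred + w[j] * dnbinom(dd, mu = mu[j], size = mu[j] * phi)
    pred
  }
  # init: apportion distinct k-mers to the nearest component centre
  grp <- pmin(pmax(round(2 * d / lam0), 1), 4)
  w0 <- pmax(vapply(1:4, function(j) sum(obs[grp == j]), 0), 1)
  par0 <- c(lambda = lam0, phi = 5, w1 = w0[1], w2 = w0[2], w3 = w0[3], w4 = w0[4])
  lower <- c(0.7 * lam0, 0.05, 0, 0, 0, 0)
  upper <- c(1.3 * lam0, 1e5, rep(10 * sum(obs), 4))

  objective <- function(p) {
    pred <- comp_pred(d, p[1], p[2], p[3:6])
    sum((sqrt(obs) - sqrt(pmax(pred, 0)))^2)
  }
  converged <- TRUE
  fit <- tryCatch({
    df <- data.frame(d = d, y = sqrt(obs))
    m <- minpack.lm::nlsLM(
      y ~ sqrt(pmax(comp_pred(d, lambda, phi, c(w1, w2, w3, w4)), 0)),
      data = df,
      start = as.list(par0), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(m)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    o <- optim(par0, objective, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 500))
    fit <- o$par
    converged <- o$convergence == 0
    if (!converged)
      warning("mixture fit did not converge; reporting best-so-far parameters")
  }
  lambda <- unname(fit[1]); phi <- unname(fit[2]); w <- unname(fit[3:6])

  t_good <- sum(hist$depth[hist$depth >= boundary] * hist$count[hist$depth >= boundary])
  t_all <- sum(hist$depth * hist$count)
  genome_len <- t_good / lambda
  unique_len <- min(w[1] / 2 + w[2], genome_len)
  h <- if (w[1] / 2 + w[2] > 0) (w[1] / 2) / (w[1] / 2 + w[2]) else 0
  het_pct <- 100 * (1 - (1 - h)^(1 / k))
  repeat_len <- max(0, genome_len - unique_len)
  err_frac <- if (t_all > 0) (t_all - t_good) / t_all else 0
  err_pct <- 100 * (1 - (1 - err_frac)^(1 / k))
  pred <- comp_pred(d, lambda, phi, w)
  model_fit <- max(0, min(100, 100 * (1 - sum(abs(obs - pred)) / sum(obs))))

  structure(list(genome_haploid_length = genome_len,
                 het_rate_pct = het_pct,
                 repeat_length = repeat_len,
                 unique_length = genome_len - repeat_len,
                 repeat_pct = 100 * repeat_len / genome_len,
                 read_error_rate_pct = err_pct,
                 hom_depth = lambda,
                 model_fit_pct = model_fit,
                 k = as.integer(k),
                 weights = w, overdispersion = phi,
                 converged = converged, peaks = peaks),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("diploid spectrum fit (k = %d)\n", x$k))
  cat(sprintf("  Genome Haploid Length (bp)  %s\n",
              format(round(x$genome_haploid_length), big.mark = ",")))
  cat(sprintf("  Heterozygous (%%)            %.2f\n", x$het_rate_pct))
  cat(sprintf("  Genome Repeat Length (bp)   %s\n",
              format(round(x$repeat_length), big.mark = ",")))
  cat(sprintf("  Genome Unique Length (bp)   %s\n",
              format(round(x$unique_length), big.mark = ",")))
  cat(sprintf("  Genome with Repeats (%%)     %.2f\n", x$repeat_pct))
  cat(sprintf("  Read Error Rate (%%)         %.2f\n", x$read_error_rate_pct))
  cat(sprintf("  Model Fit (%%)               %.2f\n", x$model_fit_pct))
  cat(sprintf("  Coverage peak (lambda)      %.1f\n", x$hom_depth))
  invisible(x)
}

#' Write a spectrum fit report as TSV
#'
#' One property per row, mirroring the usual genome-profiling report layout.
#'
#' @param fit A `spectrum_fit`.
#' @param path File path.
#' @export
write_spectrum_fit <- function(fit, path) {
  df <- data.frame(
    property = c("Heterozygous (%)", "Genome Haploid Length (bp)",
                 "Genome Repeat Length (bp)", "Genome Unique Length (bp)",
                 "Model Fit (%)", "Read Error Rate (%)",
                 "Genome with Repeats (%)", "Coverage peak depth"),
    value = c(round(fit$het_rate_pct, 2), round(fit$genome_haploid_length),
              round(fit$repeat_length), round(fit$unique_length),
              round(fit$model_fit_pct, 2), round(fit$read_error_rate_pct, 2),
              round(fit$repeat_pct, 2), round(fit$hom_depth, 1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
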
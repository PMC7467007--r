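---
title: "Characterizing a heterozygous diploid genome from short reads"
author: "hetscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a heterozygous diploid genome from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscope)
```

## The problem

Non-model diploid genomes -- marine invertebrates are a canonical example --
tend to combine substantial heterozygosity (0.5-1.5% of sites), high repeat
content (40% and more) and, after assembly, residual *uncollapsed haplotigs*:
regions where the two haplotypes were assembled as two separate loci instead
of one. Each of these properties interferes with the others' measurement.
`hetscope` implements the desk-scale computational chain used to
characterize such a genome from a paired-end short-read library:

1. **k-mer spectrum modelling** of haploid genome size, heterozygosity,
   repeat content and read error rate;
2. **read screening** against a contaminant database and fixed-length
   trimming;
3. **assembly QC**: Nx contiguity tables, coverage-histogram cut-offs,
   haplotig/junk scaffold flagging and purging, and rule-based contaminant
   scaffold flagging;
4. the **corrected SNV heterozygosity rate**: a pileup genotyper with
   support filters over callable sites, minus the sites carrying
   *artificially duplicated* k-mers;
5. **report arithmetic**: coverage folds, annotation summaries, orthogroup
   accounting and microsatellite placement.

A synthetic diploid genome generator with full truth files
(`simulate_diploid_genome()`, `simulate_reads()`,
`make_fragmented_assembly()`) is a first-class part of the package: every
stage is validated by parameter recovery against planted truth.

## The diploid k-mer mixture model

For a diploid sequenced at per-base depth $c$ with reads of length $L$, the
unique homozygous portion of the genome produces k-mers at depth
$\lambda \approx c\,(L-k+1)/L$, while heterozygous k-mers -- windows
overlapping a heterozygous SNV, which exist in two versions, one per
haplotype -- appear at $\lambda/2$. Two-copy repeats contribute components
at $2\lambda$ (and $3\lambda/2$ for their heterozygous windows).
`fit_diploid_model()` fits

$$ f(d) \;=\; \sum_{j=1}^{4} w_j \,\mathrm{NB}\!\left(d;\ \mu_j = j\lambda/2,\
\mathrm{size} = \mu_j\phi\right) $$

to the spectrum histogram by bounded nonlinear least squares on the
square-root scale (`minpack.lm::nlsLM`, with an `optim` L-BFGS-B fallback),
initialized from `detect_peaks()`. The shared overdispersion $\phi$ keeps
the four components' variance-to-mean ratios identical, as depth sampling
affects them all equally.

From the fitted parameters:

* **Heterozygosity.** The fraction of genomic k-mer windows that overlap a
  heterozygous site is $h = \frac{w_1/2}{w_1/2 + w_2}$ (the $\lambda/2$
  component counts each het window twice, once per haplotype). Since a
  window of $k$ bases is fully homozygous with probability $(1-r)^k$ at
  per-site heterozygosity $r$, the rate is $r = 1 - (1-h)^{1/k}$.
* **Genome size.** $G = \sum_{d \ge b} d\,n_d / \lambda$, where $b$ is the
  error boundary (below). Per-base sequencing errors scale the numerator
  and the fitted $\lambda$ by the same $(1-e)^k$ factor, so the estimator
  is unaffected by the error rate to first order.
* **Error rate.** A k-mer observation is error-free with probability
  $(1-e)^k$; equating that to the observed fraction of non-error k-mer
  observations gives $e = 1 - (T_{\ge b}/T)^{1/k}$.
* **Repeats.** Repeat length is the genome length not attributable to the
  unique components, $G - (w_1/2 + w_2)$.
* **Model fit.** $100\,(1 - \sum_d |n_d - \hat f(d)| / \sum_d n_d)$ over
  the fitted range.

### Numerical choices

* The **error boundary** is the first local minimum of the (smoothed)
  spectrum after depth 1; everything below is attributed to sequencing
  errors and excluded from both the fit and the genome-size sum. The
  smoother is a centred moving average whose window shrinks at the edges --
  a fixed-width filter padded with raw values fabricates spurious edge
  minima next to the tall error bin.
* **Peak pairing**: the global maximum beyond the boundary is taken as the
  homozygous peak unless a second local maximum exists near twice its depth
  (a spectrum dominated by the heterozygous peak), in which case the lower
  peak is heterozygous. The pairing tolerance is a ±20% window around the
  exact 2:1 depth relation.
* Histogram depths above `max_depth` (default 250, matching the
  conventional plotting range) are pooled into the last bin; the pooled bin
  is excluded from the least-squares fit but retained in the genome-size
  sum, which slightly undercounts deep-repeat k-mers -- a documented,
  deliberate truncation.
* Counting is **canonical** (k-mer vs reverse complement) by default, since
  reads sample both strands.

## Read screening and trimming

`screen_reads()` removes a read pair when either mate aligns to any
contaminant reference with at most `floor(0.02 * read_length)`
substitutions, on either strand. Matching is exact seed-and-extend: with a
mismatch budget $m$, placing $m+1$ disjoint seeds guarantees one exact seed
(pigeonhole), so seed hits plus Hamming verification reproduce a full
sliding scan -- which is also the fallback for reads too short for the
guarantee. Gapped alignment is deliberately out of scope: the screen
targets near-identical contaminant copies and is insensitive to divergent
strains, which are caught later at the scaffold level
(`flag_contaminant_scaffolds()`). `trim_reads()` truncates to a fixed
prefix (default 150 bp), propagating the truncation to qualities and to
truth origins of reverse-strand mates.

## Assembly QC

`nx_table()` reports Nx lengths and counts for scaffolds and for contigs
(scaffolds split at runs of at least 10 Ns -- the common convention, since
no universal contig definition exists). The Nx convention used here is
*the first sequence, in descending length order, whose cumulative length
strictly exceeds x% of the total*; N0 is therefore the longest sequence and
N100 the shortest. The strict inequality matters only at exact ties and is
fixed by the package's oracle tests.

`find_coverage_cutoffs()` locates the haploid- and diploid-depth modes of
the per-base coverage histogram; the midpoint is the valley between them
and the low/high cut-offs sit where the histogram falls below 10% of the
respective mode height. `classify_scaffolds_by_coverage()` then flags a
scaffold `junk` when ≥80% of its bases fall outside `[low, high]` and
`suspect` (candidate haplotig) when ≥80% fall in the haploid band
`[low, midpoint)`. The 80% fractions are configurable; they are the
conventional defaults of coverage-based purging tools. Alignment-based
reassignment of haplotigs to their primary loci is a non-goal; on data
where a haplotig is emitted as its own scaffold, coverage classification
alone recovers the haploid set, and the bundled simulator reproduces
exactly that situation.

## The corrected heterozygosity rate

`pileup()` aggregates per-site A/C/G/T counts of bases with base quality
≥10 on alignments with mapping quality ≥20. The thresholds are applied when
the pileup is built (the object stores aggregated counts, not per-read
lists, so they cannot be re-applied later); `callable_loci()` adds the
depth criterion (default ≥4 passing reads) and emits maximal callable runs
as intervals. `call_snvs()` is a frequency-based diploid genotyper: the
leading alternative allele is heterozygous at frequency in `[0.2, 0.8]`,
homozygous-alternative above. It deliberately performs no haplotype
reassembly or genotype-likelihood modelling -- the statistic under test
depends on depth and allele-support counts, which are preserved.
`filter_supported_snvs()` keeps bi-allelic calls with depth ≥10 and, at het
sites, ≥2 alternative-supporting reads.

Uncollapsed haplotigs bias this rate downward twice: reads split between
the two copies halve local depth, and each copy is homozygous for its own
haplotype, so no het call can arise there -- while the sites still inflate
the callable denominator. `duplicated_kmer_mask()` identifies the affected
sites: k-mers whose read depth lies in the normal coverage band (default
20-200x) but which occur exactly twice in the assembly. Every exact
occurrence becomes an interval `[pos, pos+k)` and the union is subtracted
from the callable sites before the rate is computed
(`heterozygosity_rate()`). Within a duplicated region, the merged mask
covers every base except inter-SNV gaps shorter than k, so a small
residue of biased callable sequence survives; at realistic SNV spacing
this keeps the corrected estimate within a few percent of truth, and the
direction of the correction (corrected > uncorrected) is guaranteed.

Duplicate read pairs (identical origin signature) are dropped before
pileup by default, mirroring standard duplicate-marking. Coordinates are
0-based half-open everywhere internally; VCF output is the only 1-based
surface, and the conversions are centralized in the VCF writer/reader.

## The synthetic data generator

`sim_config()` defaults describe the empirical regime the package targets,
scaled to a 1 Mb genome: heterozygosity 0.9%, repeat fraction 42% (families
of 2-3 dispersed copies at 95-99% identity, matching the 2x/3x repeat
structure typical of spectra from partially collapsed assemblies), 2x251 bp
pairs from ~395 bp fragments, 0.3% substitution error, 100x depth, 7.86%
contaminant admixture. Base qualities are constant Q30 (with an optional
degraded-tail mode to exercise callable filters); the haplotig condition is
created by re-emitting 30-70% sub-intervals of primary scaffolds from the
second haplotype as extra scaffolds.

What the generator does *not* emulate -- and what passing recovery tests
therefore do not demonstrate -- includes: indels and structural variants,
GC-dependent coverage bias, quality-dependent error profiles, adapter
contamination, and long-read error structure. Reads whose origin crosses a
scaffold-piece boundary are dropped rather than clipped when routed onto
the fragmented assembly (about 1% at the default piece sizes); the loss
affects numerator and denominator of the rate equally.

## Problem sizes

The test-suite and acceptance-script simulations use a 1 Mb genome at 100x
(about 0.1 Gb of simulated sequence per run), with 0.2-0.6 Mb genomes for
the spectrum-shape and purging properties -- sizes at which every stage's
estimand is stable and a complete run takes minutes on a single core.
Published full-genome figures of the kind the package's arithmetic mirrors
(multi-hundred-Mb assemblies at 240x) are inputs to the report functions,
not recomputed.

## Known limitations

* The mixture uses four components; repeats of copy number ≥3 fold into
  the fourth component and the genome-size sum, so `repeat_pct` is a lower
  bound when high-order repeats dominate.
* The screen is substitution-only; a contaminant diverging by indels
  escapes it (by design, see above).
* The genotyper has no error model beyond the allele-frequency window; at
  depths below ~20x its het sensitivity degrades faster than a
  likelihood-based caller's would.
* `find_coverage_cutoffs()` assumes at most two dominant modes; assemblies
  with strong collapsed-repeat coverage classes need explicit cut-offs
  (which override detection verbatim).
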
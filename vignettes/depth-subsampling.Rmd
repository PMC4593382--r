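---
title: "Depth subsampling of RNA-seq reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth subsampling of RNA-seq reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

How many reads does a bulk RNA-seq experiment need? Any statistic computed
from a count matrix — the number of detectably expressed genes, the shape of
the expression distribution, a differential-expression call — depends on
sequencing depth, and the only trustworthy way to study that dependence is
to *re-create* shallower experiments from a deep one. `desire` implements
this as an m-out-of-n bootstrap on aligned reads: from a sample with $N$
aligned fragments, draw $\lfloor f \cdot N \rceil$ fragments uniformly
without replacement (fractions $f \in \{0.1, \dots, 0.9, 1.0\}$ by
default), repeat $R = 24$ times per depth, and write each draw as a new
alignment file. Each subsample is statistically exchangeable with a real
sequencing run of the smaller depth, because the draw acts on the whole
read population at once — drawing per gene would break the multinomial
coupling between genes that a sequencer induces.

The contrast kept alongside is *direct scaling*: multiplying a count
matrix by $f$. The ratio of scaled to raw totals is exactly $f$, but
scaling is a deterministic change of units — after CPM normalization it is
invisible, and it can never silence a gene the way a real shallower run
loses singletons. Both routes are implemented so the divergence between
them can be measured rather than asserted.

## Procedure and model

1. **Subsampling** (`subsample_alignments`, `generate_replicates`). The
   sampling unit is the fragment (read name), so paired mates and
   unmapped mates travel together. The drawn count is exact,
   $\mathrm{round}(f N)$ with round-half-even, not binomial; replicate
   $r$ uses seed `base_seed + r`, and the draw depends only on the
   fragment-id set, the fraction and the seed — never on file order.
   Per-gene counts of a subsample are then multivariate hypergeometric:
   a gene with $c$ of $N$ reads has expected subsample count $fc$, which
   the test suite checks against 200 Monte-Carlo replicates.
2. **Counting** (`count_fragments`). A minimal featureCounts-style
   summarizer: primary alignments only, junction-aware reference blocks
   (CIGAR `N` gaps excluded, deletions included), unstranded, assignment
   when the exon-union overlap of exactly one gene reaches `min_overlap`
   (default 1 base); multi-gene fragments are discarded by default or
   counted for every gene with `ambiguous_policy = "count_all"`. The
   classes assigned/ambiguous/unassigned always partition the mapped
   fragments.
3. **Normalization** (`cpm`, `rpkm`). $\mathrm{CPM}_i = 10^6 N_i /
   N_\mathrm{lib}$ with $N_\mathrm{lib} = \sum_i N_i$;
   $\mathrm{RPKM}_i$ additionally divides by the merged exon length
   $L_i$ in kb. Per sample, CPM sums to $10^6$, so its mean over a full
   annotation of $G$ genes is the constant $10^6/G$ — for $G = 23{,}648$
   genes, $42.29$ — at every depth. This identity doubles as a built-in
   self-check.
4. **Saturation analysis** (`build_saturation_curves`, `fit_gompertz`).
   A gene is expressed at threshold $\theta$ when its *raw* count
   reaches $\theta$ (grid $\{1, 10, 50, 100\}$). Expressed-gene counts
   per depth are fitted with the Gompertz function
   $f(x) = a\,e^{-b e^{-cx}}$, whose parameter $c$ is the growth rate;
   the fit uses all replicate points pooled (not per-depth medians), by
   Levenberg–Marquardt least squares.
5. **Optimal depth** (`estimate_optimal_depth`). A sample counts as
   saturated when the fitted relative slope at full depth,
   $f'(1)/a$, falls below a tolerance (default $10^{-3}$ per unit
   depth fraction — a detector default, always reported in the output).
   If no sample saturates, the library sizes themselves are only lower
   bounds: Estimator I (average depth) reports their mean, Estimator II
   (individual depth) their maximum. For the eight-sample protocol with
   library sizes 34,974,017 / 46,677,107 / 17,574,408 / 24,440,340 /
   25,900,791 / 43,454,785 / 31,426,867 / 33,517,581 and no saturating
   curve this gives bounds of 32,245,737 and 46,677,107 reads.
6. **Distribution moments** (`distribution_moments`,
   `compare_moments`). The distribution studied is across genes within
   one sample. Mean; unbiased variance; skewness $m_3/m_2^{3/2}$; and
   *plain* kurtosis $m_4/m_2^2$ (a normal distribution scores 3). Group
   comparisons run two-sample t tests (Welch by default) for all three
   alternatives; with `pool_across_depths = TRUE` the test samples are
   the per-depth medians over replicates, one value per depth fraction.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `depth_grid` | 0.1–1.0 by 0.1 | fraction of fragments | the standard ten-depth design; includes $f=1$ as a degenerate draw-all so every depth has $R$ replicates |
| `replicates` | 24 | datasets per depth | stable medians/IQRs without waste; 10 depths × 24 = 240 datasets per sample |
| `theta` | {1, 10, 50, 100} | raw reads | from permissive detection to stringent expression filtering |
| `min_overlap` | 1 | bases | featureCounts' default assignment rule |
| `saturation_tolerance` | 1e-3 | relative slope per unit $f$ | flags only clearly flat curves; reported, never silent |

## The synthetic generator

`simulate_annotation` places disjoint 1–3-exon genes (every exon long
enough to hold a read) on a few artificial chromosomes;
`simulate_reads` draws per-gene counts and places each read uniformly
within one exon, plus a configurable fraction of intergenic noise reads;
`simulate_cohort` builds two phenotype groups. Counts are drawn as
gamma-distributed gene weights (mean $\mu_i$, variance
$\phi\mu_i^2$ — the negative-binomial mixing construction) followed by a
multinomial conditioned on the exact library size: marginally the counts
are overdispersed like a negative binomial, while the library size is
exact, so a half-depth subsample of a $10^4$-read sample has exactly
5,000 fragments. The across-gene profile is log-normal; group B's
profile is a deterministic monotone remap that multiplies the
across-gene variance by `group_effect` while keeping the mean fixed, so
`group_effect = 1` makes the groups exchangeable (for null calibration)
and `group_effect < 1` reproduces a lower-variance "disease" group
whose CPM mean is unchanged — the situation in which higher moments
carry signal that mean-based tests miss.

What the generator does *not* emulate: sequencing errors, mapping
ambiguity from homology (multi-mapping is simulated only via overlapping
annotations if you build them), splice-isoform structure, GC or length
bias, and batch effects. Passing tests therefore demonstrate the
correctness of the subsampling, counting and inference machinery — not
that real libraries are free of those artifacts.

## Numerical choices and edge cases

- **Rounding the draw size.** $\mathrm{round}(fN)$ with round-half-even
  rather than floor: unbiased across fractions.
- **Scaled-route thresholding.** Scaling by $f$ is a change of units, so
  the expression threshold is scaled with it: a gene is expressed in the
  $f$-scaled matrix when its scaled value reaches $\theta f$
  (equivalently, when its full-depth count reaches $\theta$). Comparing
  the real-valued scaled entry against an integer threshold calibrated
  for full depth would conflate the unit change with a depth effect and,
  at $\theta = 1$, would paradoxically report *scaling* as losing more
  genes than true subsampling. The literal comparison is available as
  `scaled_threshold = "literal"`.
- **Gompertz initialization.** $a_0$ = max observed count (nudged 5%
  up), $c_0 = 1$, $b_0$ solved from the smallest-depth mean; a small
  multi-start grid over $c_0$ on failure; bounded below at $10^{-8}$ so
  a converged fit always satisfies $a, b, c > 0$ and is nondecreasing on
  $x \ge 0$. Constant curves return `converged = FALSE` rather than a
  garbage fit, and reported standard errors are the asymptotic
  least-squares ones.
- **Degenerate tests.** Two groups that are both numerically constant
  carry no evidence: p = 1 when their means agree, directional 0/1 when
  they differ (this also covers the CPM mean, which is constant by
  construction). Zero-variance moment vectors report NA skewness and
  kurtosis instead of NaN.
- **Pseudo-replication caveat.** Pooling per-depth medians makes the
  group-test observations highly dependent across depths (the same
  biological samples underlie every depth), so pooled p-values are
  anti-conservative and should be read as descriptive, not confirmatory.
  The calibration checks in the test suite therefore operate on
  independent draws.

## Problem sizes used by the test suite

The suite runs entirely on generated data: annotations of 30–400 genes
on 3 chromosomes, libraries of 1,000–20,000 single-end 75-bp reads,
subsampling grids of up to 10 depths × 24 replicates, 200-replicate
Monte-Carlo checks of the hypergeometric law, 100 noisy Gompertz
refits, and 2,000 null simulations for t-test calibration. These sizes
were chosen so every distributional check has enough resolution to fail
visibly while the whole suite stays quick to run; none of the scientific
conclusions depend on scaling them up.

## Known limitations

- Counting assigns whole fragments by exon-union overlap; exon-level or
  isoform-level quantification is out of scope by design.
- BAM input requires `Rsamtools`; the native path is SAM text, which is
  also what the subsampler emits.
- The Gompertz family is the only growth model offered; a logistic
  alternative would fit similarly near saturation but is not
  implemented.
- The optimal-depth estimators are deliberately simple summaries of the
  fitted curves (mean and max of per-sample requirements); no
  uncertainty is propagated from the fits into the bounds.
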
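---
title: "Models and methods in burstnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in burstnoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`burstnoise` quantifies cell-to-cell expression variability from single-cell
RNA-seq counts and relates it to promoter chromatin state (Active, PRCa,
PRCr), linear genome position, 3D promoter contacts and a Polycomb-knockout
perturbation. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Quality control and normalization

Cells are dropped when exonic reads fall below `exon_min` (default 5×10⁵) or
the mitochondrial read fraction exceeds `mito_max` (default 0.10). An
optional third criterion flags cells in which many genes look abnormally
amplified: gene *g* counts as amplified in cell *c* when its
library-size-scaled count exceeds the across-cell median by more than
`amplification_z` MADs, and the cell fails when the amplified fraction
exceeds `amplification_frac` (default 5%). The flag is off by default because
it is a robust-outlier heuristic, not a reproduction of any published rule.

Size factors use the median-of-ratios estimator (each cell's factor is the
median ratio of its counts to the per-gene geometric mean), computed by
DESeq2's reference implementation; only genes observed in every cell form
the reference, and a matrix with no such gene errors with a pointer to
shifted-log alternatives. The canonical stage order is cell QC → size
factors → expressed-gene filter; factors estimated on an already-normalized
matrix are ≈ 1 (tested). Genes with mean normalized count below `min_mean`
(default 10) are removed before any noise or kinetics computation: for
lowly expressed genes, technical noise dominates and no spike-ins are
available to deconvolve it.

## The DM noise statistic

CV² = variance/mean² depends strongly on expression level and, through
transcript-length effects on counting, on gene length. DM removes both in two
stages: order genes by log₁₀ mean and subtract a running median of log₁₀ CV²;
then order the residuals by log₁₀ gene length and subtract their running
median. The window is `window_genes = 50` genes — wide enough to be smooth,
narrow enough to track the mean-variance trend; the series is reflected at
its ends so edge windows stay centered, and sorting ties are broken by gene
id so results are deterministic. DM is location-free (a global CV² scaling
cancels) and, on a null where CV² is a deterministic function of the mean,
interior DM values are exactly zero. Gene length defaults to the annotated
span; an explicit length column overrides it, since "length" has no single
canonical definition across annotations.

## Bimodality index

Expression of a bursty gene across cells is well described by a two-state
mixture. We fit an equal-variance two-Gaussian mixture to
`log2(normalized + 1)` (mclust, model "E" — the tool this analysis
traditionally uses) and score

BI = sqrt(p(1−p)) · (μ_high − μ_low)/σ,

with π_HE = p the fraction of cells in the high-expression state. The log
base and pseudocount are a convention, not a discovery; they are recorded
here because BI is only comparable between datasets processed the same way.
BI is invariant to affine transforms of the log-expression scale (tested),
and a planted 50/50 mixture separated by 3σ gives BI = 1.5 in closed form,
which the fit recovers within 5% at n = 10,000.

## Poisson-beta burst kinetics

The two-state promoter model (switch on at rate k_on, off at k_off,
transcribe at rate s while on, all in units of the mRNA decay rate d) has
stationary counts Poisson(s·p) with p ~ Beta(k_on, k_off). Burst size is
s/k_off, burst frequency k_on. With r₁ = f₁, r₂ = f₂/f₁, r₃ = f₃/f₂ built
from the first three sample factorial moments, the moment system inverts in
closed form; the estimator is deterministic and fast, which matters because
the identifiability test refits thousands of bootstrap replicates. Decay
rates default to 1 (parameters per mRNA lifetime); supplying d rescales all
three rates multiplicatively and leaves burst size and all parameter
rankings unchanged, so decay-rate uncertainty cannot reorder classes.

Normalized counts are rounded to the nearest integer before fitting (the
model is a count law; the rounding convention is configurable and recorded).
Near-Poisson data sit on a singular boundary of the moment system where
k_on estimates diverge; solutions that are non-positive, non-finite or with
k_on > 10³ are flagged non-identifiable rather than reported.

Identifiability uses a parametric bootstrap: the statistic is a chi-square
distance on adaptive count bins (expected count ≥ 5 per bin under the fitted
law, open tail bin; bin probabilities by 64-node Gauss–Legendre quadrature on
the Beta quantile scale, which avoids the density's endpoint singularities).
Each of `n_boot = 200` replicates is simulated from the fit and *refitted*
before its statistic is computed, so estimation error is inside the null.
`gof_p` is the plain fraction of bootstrap statistics at least as large as
the observed one, and a gene is identifiable when `gof_p ≥ alpha` (0.05).
On well-specified simulations the rejection rate is ≈ α (tested); a
two-Poisson mixture far outside the family is rejected.

## Genome-position analyses

*Neighborhood test.* Genes are ranked by DM; the top and bottom 20% are
noisy/stable focal sets. For each half-width W (default grid 20 kb–0.5 Mb,
with 50 kb the headline size), DM values of genes within ±W of each focal
TSS (focal excluded) are pooled and compared by a one-tailed Wilcoxon test,
with a two-tailed test on flanking mean expression as the
expression-confounding control. The control band reassigns DM values over
fixed positions 100 times and reports the 2.5%/97.5% quantiles of the
randomized p-values. Because positions are fixed, neighbor indices are
computed once and reused across randomizations.

*Cluster calling.* Along each chromosome a 4-gene window slides one gene at
a time; windows whose TSS span exceeds (window−1)×0.5 Mb are ignored. The
score sums rolling means of consecutive DM pairs (inner genes weigh double).
The null draws `n_null = 100,000` sets of four DM values without replacement
from the genome-wide pool — one shared null, not per-chromosome, matching a
single exchangeable-null interpretation; strict inequalities against the
2.5%/97.5% quantiles call stable/noisy windows, so a constant-DM genome
calls nothing. Overlapping same-label windows merge into clusters. On an
exchangeable genome the significant-window fraction is ≈ 2q = 5%; the check
allows ±2 points because overlapping windows are positively correlated, so
the binomial standard error understates the spread. Mark enrichment in
clusters is a two-tailed Fisher's exact test per mark against the background
of all valid-DM classified genes.

## Proximity and 3D contacts

*Proximity.* The observed statistic is the median (and mean)
nearest-neighbour TSS distance from set A to set B, per chromosome. The null
resamples |A| genes from a background excluding B and excluding chromosomes
without B genes; since a pool gene's nearest-B distance is fixed, distances
are precomputed and only resampled. Empirical p-values use the add-one
convention (smallest attainable p is 1/(n+1)), avoiding p = 0 from finite
resampling.

*Contact enrichment.* Promoter–promoter contacts are first filtered to
midpoint separation ≥ 10 Mb (interchromosomal kept). A multi-gene anchor
contributes once per unordered gene pair. Observed counts (both ends in the
set) are divided by the mean count over random promoter sets matched to the
experimental set's pairwise TSS-distance distribution: distances are binned
on a half-decade log grid with an interchromosomal bin, each random set is
seeded with the experimental per-chromosome composition and refined by
greedy same-chromosome swaps until the bin histogram is within `tol = 0.05`
(L1) or `max_swaps = 200`; the Kolmogorov–Smirnov distance between
intrachromosomal distance distributions is stored per set as a matching
audit. Three independent control groups give the reported mean ± sd, and
set-to-set enrichment comparisons use one-tailed Welch t-tests on per-set
enrichments. Counting requires both ends in-set (an at-least-one-end variant
would mix in cross-class contacts and dilute class contrasts).

*Enhancer links.* Per-gene counts of promoter–enhancer contacts by enhancer
class (active / intermediate / poised). The noise association splits PRCa
genes at 0 vs ≥1 active-enhancer contacts when the count distribution is
zero-inflated (>50% zeros), otherwise at the median, and compares DM by a
two-tailed Wilcoxon test with the same test on mean expression as control.

## Condition comparison

Per-gene shifts between conditions are log₂ fold changes of mean normalized
expression with a pseudocount of 1 (the plain difference is available by
flag), and differences of DM, BI and burst frequency. DM is recomputed
within each condition because its running-median baseline is
dataset-specific. Class pairs are compared by a two-tailed Wilcoxon test on
the mean shift and one-tailed Welch t-tests on the noise/bimodality/burst
shifts (direction: the more-Polycomb class of the pair shifts lower).
Swapping condition labels negates every delta (tested).

## The synthetic-data generator

`sim_config()` defaults define a desk-scale mESC-like study: 90 cells and
1500 genes (600 Active, 300 PRCa, 200 PRCr, 400 other) — about one eighth of
a real experiment's expressed-gene count, chosen so the full pipeline runs
in about a minute on one CPU. Per-class kinetics are log-normal draws around
Active (k_on ≈ 4, k_off ≈ 6, s ≈ 120: nearly always on), PRCa (k_on ≈ 0.6:
infrequent bursts, bimodal profiles), PRCr (k_on ≈ 0.15, s ≈ 350: mostly off
with rare large bursts) and a broad "other" class. These echo the
qualitative class contrasts — they are this package's choices, documented in
the config, not measured values. Size factors are log-normal (sdlog 0.3,
geometric mean 1). The genome has 5 chromosomes with exponential TSS spacing
(mean 80 kb); PRCa genes follow PRCr genes with a configurable adjacency
boost; noisy clusters are planted by dividing k_on along consecutive runs
with s rescaled to preserve the mean (so cluster detection cannot ride on
expression level); contacts are drawn with a within-class odds boost; PRCa
active-enhancer link counts multiply k_on (again mean-preserving); and the
knockout multiplies k_on of PRC targets by 4, which automatically yields the
derepression ordering PRCr > PRCa > Active because fold change in the mean
saturates in k_on.

Every structural knob has a calibrated-null setting (adjacency 0,
assortativity 0, enhancer effect 0, clusters 0), which is what the
calibration tests exercise. What the generator does *not* emulate: technical
dropout beyond the kinetic model, cell-cycle structure, batch effects,
isoform-level length artifacts, and realistic contact distance decay. A
passing suite therefore shows the statistics are correct and calibrated
under the stated model, not that real data meet the model's assumptions.

## Numerical and interface conventions

Internal genome coordinates are 1-based inclusive; BED input/output converts
at the boundary, and TSS is the 5′ interval end (strand-aware). Promoter
anchors map to genes whose TSS lies within ±2 kb of the anchor. All
stochastic steps accept a seed and restore the caller's RNG state; the
pipeline expands one master seed into per-stage streams recorded in the
manifest, and reruns are checksum-identical. Multiple-test tables carry raw
p-values plus a Benjamini–Hochberg column, labeled.

Known limitations: the moment estimator, while unbiased enough in the
bursting regime (k_on < 1 < k_off), loses efficiency for high-frequency
genes where the law approaches Poisson; the bootstrap p has resolution
1/n_boot; the distance-matching refinement is greedy and can stall above
tolerance for very clustered promoter sets (the stored KS distances make
this visible); and with ~90 cells the per-gene mixture fit has wide
uncertainty in π_HE, so only class-level summaries should be interpreted.
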
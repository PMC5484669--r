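# burstnoise

Chromatin state shapes not just how much a gene is expressed but how
*variably* it is expressed from cell to cell. In mouse embryonic stem cells,
promoters fall into classes by their histone and RNA-polymerase-II marks:
**Active** genes (productive RNAPII, no Polycomb marks), **PRCa** genes
(Polycomb marks *plus* active RNAPII — expressed but Polycomb-bound) and
**PRCr** genes (Polycomb marks with unproductive RNAPII — repressed).
`burstnoise` is an R package for asking, from single-cell RNA-seq counts,
whether Polycomb-bound-but-active genes are noisier, burst less often, sit
together along chromosomes and in 3D contact space, and respond more strongly
to Polycomb loss — and for verifying each statistical stage against synthetic
data with known ground truth.

## What the package computes

* **Noise statistics.** Per-gene CV² and the **DM** (distance-to-median)
  statistic: the residual of log₁₀ CV² after two successive running-median
  corrections, first against log₁₀ mean expression, then against log₁₀ gene
  length. DM is a mean- and length-free noise score.
* **Burst kinetics.** The Poisson-beta stationary model of transcriptional
  bursting: counts per cell are Poisson(*s·p*) with *p* ~ Beta(*k*₍on₎,
  *k*₍off₎), parameters in units of the mRNA decay rate. The estimator
  matches the first three factorial moments in closed form; burst size is
  *s*/*k*₍off₎ and burst frequency *k*₍on₎. A parametric-bootstrap
  goodness-of-fit test flags genes whose parameters are not identifiable.
* **Bimodality.** An equal-variance two-Gaussian mixture on log counts gives
  the bimodality index `BI = sqrt(p(1-p)) · Δμ/σ` and the fraction of cells
  in the high-expression (HE) state.
* **Genome position.** Neighborhood noise tests with randomized-genome
  control bands; sliding-window (4-gene) calling of noisy/stable clusters
  against a 100,000-draw permutation null; Fisher-exact chromatin-mark
  enrichment in clusters.
* **Proximity and 3D contacts.** Nearest-neighbour TSS distance tests with
  background resampling; promoter-capture Hi-C contact enrichment against
  distance-matched random promoter sets; promoter-class contact preference;
  enhancer-contact vs noise association.
* **Condition comparison.** Per-class shifts of mean, DM, bimodality and
  burst frequency between two conditions (e.g. untreated vs
  Ring1A/B-knockout cells).
* **Synthetic data.** `simulate_dataset()` generates every pipeline input
  with planted kinetics per class, class-clustered genome layout,
  assortative contact networks, enhancer links that stabilize noise, and a
  paired knockout condition — so each stage can be tested for calibration
  and power.

## Worked example

```r
library(burstnoise)

sim  <- simulate_dataset(sim_config(seed = 1))   # 90 cells, 1500 genes
qc   <- qc_cells(sim$wt, sim$qc_table)
norm <- size_factors(qc$counts)
expr <- filter_expressed(norm, min_mean = 10)
np   <- noise_profile(expr, sim$annotation)

library(dplyr)
inner_join(np, sim$states, by = "gene_id") |>
  group_by(state) |>
  summarise(median_dm = median(dm))
#> # A tibble: 4 × 2
#>   state  median_dm
#>   <chr>      <dbl>
#> 1 Active  -0.110
#> 2 PRCa     0.213
#> 3 PRCr     0.797
#> 4 other   -0.00248
```

Polycomb-active genes come out noisier than active genes (median DM 0.21 vs
−0.11) even though the generator matched their mean expression trends — the
planted low burst frequency, not the expression level, drives the extra
cell-to-cell variation. `fit_kinetics()` recovers exactly that:

```r
fits <- fit_kinetics(expr)
inner_join(fits, sim$states, by = "gene_id") |>
  filter(identifiable) |>
  group_by(state) |>
  summarise(median_burst_freq = median(burst_freq))
#> 1 Active  3.75
#> 2 PRCa    0.868
#> 3 PRCr    0.159
#> 4 other   2.00
```

`run_pipeline()` chains every stage (QC → noise/kinetics →
clusters/proximity/contacts → knockout comparison) and writes per-stage
TSV/JSON outputs plus a manifest with seeds and checksums.

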
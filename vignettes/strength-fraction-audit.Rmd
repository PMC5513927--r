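---
title: "Auditing the within-network strength fraction for spatial confounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the within-network strength fraction for spatial confounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recurring claim in brain-network transcriptomics is that functional
networks defined from resting-state fMRI are "recapitulated" by correlated
gene expression: tissue samples belonging to the same functional network
have unusually similar expression profiles. The statistic behind such
claims is the **strength fraction (SF)**: build a complete graph over
tissue samples whose edge weights are the Pearson correlations between the
two samples' expression profiles (computed across genes), and take

$$
\mathrm{SF} \;=\;
\frac{\sum_{(i,j)\,\in\,\mathrm{Wi}} w_{ij}}
     {\sum_{(i,j)\,\in\,\mathrm{included}} w_{ij}},
$$

where Wi is the set of *within-network* edges (both endpoints carry the
same network label) and, in the original formulation, only edges with
$w_{ij} > 0$ contribute to either sum. Significance is assessed with a
label-permutation null: shuffle the sample-to-network assignment, recompute
SF, repeat.

The permutation test assumes samples are **exchangeable**. They are not:
gene expression is spatially autocorrelated (nearby tissue is more similar),
and functional networks are spatially contiguous, so their within-network
edges are systematically *short*. Under shuffling, Wi status is handed to
long out-of-network edges, which have lower weights for purely spatial
reasons. The observed SF therefore beats its null even when network
identity is irrelevant. This package implements the full audit of that
failure mode: the SF statistic and its null, three proximity corrections,
diagnostics, and a "null network" experiment, all exercisable on synthetic
data whose ground truth is known.

## The synthetic data model

Real atlas expression data cannot be redistributed, so the package generates
data with the same statistical structure:

* **Coordinates.** `n_samples` points uniform in an axis-aligned box,
  default $140 \times 170 \times 120$ mm — roughly a cortical bounding box
  in MNI-style coordinates. A uniform box rather than a cortical sheet is
  deliberate: the audit needs a spatially embedded point cloud with a
  distance metric, nothing more. Coincident points (probability zero, but
  guarded) are perturbed by $10^{-6}$ mm so no pairwise distance is zero.
* **Expression.** Each gene is an independent draw from a zero-mean
  Gaussian process over the samples with covariance
  $k(d) = \sigma^2_s \exp(-d/\lambda) + \sigma^2_n \, 1[d=0]$.
  The exponential kernel was chosen over the squared-exponential because
  the empirical weight-distance decay in microarray data is steep at short
  range and much flatter beyond roughly one length scale; a Gaussian kernel
  would make short-range edges too homogeneous. The covariance is
  factorized by Cholesky decomposition, with diagonal jitter starting at
  $10^{-8}$ and doubling on failure (giving up at $10^{-2}$).
* **Networks.** $K$ cluster centers drawn without replacement from the
  sample points; clusters grow **round-robin**, each claiming its nearest
  unclaimed sample (ties to the lowest sample index) until it reaches its
  target size. Round-robin growth keeps sizes exactly as requested and
  stops one cluster from monopolizing a region. Unclaimed samples are
  labeled `"none"`.
* **Tissue classes.** $T$ seed samples; every sample labeled by nearest
  seed (a Voronoi parcellation). This reproduces the pathology of
  label-based proximity control by construction: parcel boundaries are
  arbitrary, so some cross-parcel pairs are closer than most within-parcel
  pairs.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 500 | enough edges ($1.2\times10^5$) for stable edge-level statistics at desk scale |
| `n_genes` | 500 | sample-profile correlations estimated to $\pm\,0.04$ |
| `domain` | $140\times170\times120$ mm | MNI-like cortical bounding box |
| `lengthscale_mm` | 20 | the distance scale at which the empirical decay flattens |
| `signal_var`, `nugget_var` | 1, 1 | equal spatial signal and iid noise; gives a weight–distance correlation of roughly $-0.3$, a clearly confounded regime while keeping single-edge weights noisy |
| `n_networks`, sizes | 4 × 25 | a fifth of samples carry a network label, mirroring functional parcellations that label a minority of tissue |
| `n_tissue_parcels` | 32 | see below |

The tissue-parcel count deserves its own paragraph. Tissue-class labels in
brain atlases are gyrus-scale anatomical terms — *finer* than a functional
network, which spans many of them. The parcellation must reproduce that
scale relation: with 32 parcels over 500 samples a parcel holds ~16 samples,
smaller than a 25-sample network or cluster, so every contiguous cluster
straddles several parcels and keeps most of its within-cluster edges after
the same-tissue filter. With a much coarser parcellation (say 8 parcels) a
compact cluster can fall entirely inside one parcel, and the same-tissue
filter then deletes nearly all of its Wi edges — turning an *inadequate*
proximity control into an accidental, overwhelming one and inverting the
regime under audit. The package still exhibits the boundary pathology at
any $T \ge 2$ (and the test suite checks it at $T = 8$ explicitly).

Every generator is a pure function of its configuration and seed: stage
seeds are derived from the config seed, and the RNG state of the caller is
saved and restored.

### What the generator does not emulate

No cortical geometry (hemispheres, sulci, a 2D sheet metric), no
probe-to-gene collapsing, no between-donor variation, no heavy-tailed or
batch-structured noise. Distances are 3D Euclidean; on a folded cortex a
geodesic (2D) distance would differ, and the package deliberately does not
attempt it. Consequently, passing tests show that the *audit logic* behaves
as intended in a controlled spatially autocorrelated regime — they do not
certify any particular empirical dataset.

## The audit pipeline

1. **Edge table** (`build_edge_table`): all $n(n-1)/2$ unordered pairs with
   weight $r$, distance $d$ (mm), `wi`, `same_tissue`, and an inclusion
   mask. Genes are z-scored across samples by default before correlating
   (`standardize = TRUE`) so that gene-level mean and scale do not dominate;
   this is configurable because upstream preprocessing conventions vary.
   Weights are stored signed; the positivity cutoff is a parameter of the
   SF, not of the graph.
2. **Label-based correction** (`filter_same_tissue`): drop same-tissue
   edges. **Distance correction** (`filter_min_distance`): drop edges with
   $d < d_{\min}$; removal is strictly `<`, so a "<16 mm" condition keeps an
   edge at exactly 16 mm. The two filters commute.
3. **SF and its null** (`sf_test`): one-sided add-one p-value
   $p = (1 + \#\{\mathrm{SF}^\ast \ge \mathrm{SF}\})/(1 + B)$, ties counted
   against the observed value. An unbiased permutation p-value cannot be 0;
   output at the floor is reported as the bound $p < 1/B$. Default
   $B = 1000$.
4. **Distance sweep** (`distance_sweep`): the SF test per threshold, each
   with its own null (the edge universe changes with the filter, so nulls
   are never reused). A threshold that empties the denominator yields a
   flagged degenerate result, not an error; the sweep continues.
5. **Regression correction** (`residualize_distance`): OLS of $r$ on $d$,
   weight := residual. Two numerical facts drive the downstream behavior:
   residuals are exactly orthogonal to distance on the fitted set, and they
   sum to exactly zero there. The second fact means a *signed* SF over the
   fitted set itself is undefined (zero denominator); the audit therefore
   fits the regression over **all** edges and applies the same-tissue filter
   afterwards. The removed same-tissue edges are disproportionately short
   and sit above the fitted line, so the surviving edges sum to a negative
   total — which is how a positive Wi numerator produces a large *negative*
   signed SF with $p = 1$. With the positivity cutoff the SF stays in
   $[0,1]$ and remains "significant": the divergence between the two
   settings is the point, since nothing biological separates a weight of
   $+0.01$ from $-0.01$ after mean-centering.
6. **Null networks** (`null_network_experiment`): random center placement,
   contiguous growth to the observed network sizes (total labeled-node count
   preserved exactly), the identical SF test per set, and the fraction of
   sets significant at 0.05 and 0.001. Centers are drawn from sample
   locations so clusters are never empty; overlap with the real networks is
   allowed. SF magnitudes are not compared across sets — SF depends on the
   Wi edge count, which varies with placement.
7. **Diagnostics** (`distance_correlation_test`,
   `within_out_distance_ttest`): the weight–distance Pearson R with its
   t-distribution p-value, and the pooled two-sample t-test of Wi vs T-W
   edge distances ($df = n_1 + n_2 - 2$; Welch behind a flag). Negative t
   means Wi edges are shorter. A binned mean-weight profile is provided for
   visualization; no parametric decay curve is fit.

`run_audit()` chains all of it and writes per-stage JSON, an edge-table TSV
and a text summary; reruns with the same seed are byte-identical.

## Numerical and design choices

* Correlation matrices are checked positive semidefinite to $10^{-8}$ in
  tests; the GP covariance gets Cholesky jitter as above.
* Zero-variance sample profiles abort with the offending sample named;
  constant genes are dropped (with a warning) before z-scoring.
* `wi` means *same* network: a pair spanning two different networks is
  out-of-network (T-W), matching the within/total-minus-within dichotomy.
* Degenerate sweep thresholds and degenerate null-network sets are flagged
  and counted, never silently skipped.
* Problem sizes used in the shipped analyses: 500 samples / 500 genes for
  the standard fixture, 1000 permutations per test, 100 null-network sets,
  and 400 calibration replicates of 100 samples — sizes at which every
  reported property is stable across seeds while a full audit completes in
  a couple of minutes on one core.

## What the audit shows on the standard fixture

The shipped analysis scripts (`analysis/01` through `analysis/06`) produce,
in order: the fixture; a clearly negative weight–distance correlation that
*survives* the same-tissue filter, and Wi edges roughly 2.4× shorter than
T-W edges; a tissue-corrected SF at the permutation floor ($p < 10^{-3}$);
a monotone SF decline under distance filtering that is indistinguishable
from null beyond ~40 mm ($2\lambda$); a negative signed SF with $p = 1$
after regression correction while the positive-only variant stays
"significant"; 100/100 random size-matched cluster sets "significant" at
$p < 0.001$; and a calibrated type-I error (rate within the 99% binomial
band around 0.05) once the spatial autocorrelation is removed. Together:
the permutation test is sound under exchangeability, the label-based
correction does not restore exchangeability, and within-network SF
significance carries no information about the specific network placement.

## Known limitations

* The exponential kernel is a modeling choice; the audit's conclusions are
  about rank/threshold behavior of distance corrections and should be
  robust to kernel shape, but the package makes the kernel configurable
  rather than claiming it is estimated.
* 3D Euclidean distance understates along-sheet cortical distance; a
  surface-based metric would shift the sweep's crossover threshold without
  changing its shape.
* The permutation engine holds the inclusion mask fixed under label
  shuffling (filters depend on geometry and tissue, not labels); if a
  filter were ever defined in terms of network labels this invariant would
  have to be revisited.
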
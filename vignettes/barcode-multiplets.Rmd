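---
title: "Inferring barcode multiplets in droplet scATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring barcode multiplets in droplet scATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipletkit)
library(data.table)
```

## The problem

Droplet single-cell assays assume a one-to-one pairing of cells and
barcode sequences. Two failure modes break this assumption. First,
although bead loading is engineered to be sub-Poisson, a few percent of
droplets capture **two or more beads**, so one cell's material is tagged
with several unrelated barcodes ("bead multiplets"). Second, an
individual bead can carry **heterogeneous oligonucleotide barcodes**
introduced during bead synthesis ("complex beads"); such barcodes are
near-copies of each other, differing outside a long shared subsequence.
Either way, one cell appears as several "cells", deflating per-cell
coverage and inflating apparent cell numbers — which is particularly
damaging when counting rare events such as expanded B/T-cell clones.

`multipletkit` detects these barcode multiplets from scATAC-seq fragment
files, classifies them into the two mechanistic classes, quantifies
their association with clustering, and propagates the multiplet rate
into clonotype abundance estimates.

## Detection model

ATAC fragments are bounded by two Tn5 insertion events. For a fragment
`[start, end)` in the BED-convention fragments file, the two one-bp
insertion coordinates are `start` and `end - 1`; we assume the fragment
file has already been Tn5-shifted upstream, and apply no further +4/−5
correction. Because library amplification happens inside the droplet
before barcoded material is pooled, two barcodes from the *same* droplet
re-amplify the *same* fragments and therefore share exact insertion
coordinates at rates far above chance, whereas two true cells share
insertions only by genomic coincidence.

For barcodes $a, b$ with distinct insertion sets of sizes $n_a, n_b$ and
$s$ shared coordinates, the pair score is the (modified) Jaccard index

$$J_{ab} = \frac{s}{n_a + n_b - s} \in [0, 1].$$

This is computed over distinct coordinates; a duplicate-count-weighted
variant (numerator $\sum \min(w_a, w_b)$ over shared coordinates) is
available via `statistic = "weighted"`. Barcodes with fewer than
`min_insertions` (default 100) distinct insertions are excluded, and
pairs sharing fewer than `min_shared` (default 2 in `detect()`)
coordinates are dropped before ranking — a single shared coordinate
carries no evidence beyond coincidence.

### The knee threshold

Ranked by score, pair lists from real data separate into a short head of
genuine multiplet pairs and a long tail of coincidental overlaps. The
merge threshold $T$ is inferred as the inflection ("knee") of the curve
in $\log_{10}(\text{rank})$ vs $\log_{10}(\text{score})$ space over the
top 500,000 pairs:

1. the log-score curve is smoothed with a centered 25-rank running mean
   (curves with at most 50 points are used raw — a running mean would
   smear them wholesale);
2. the knee is the point of maximum perpendicular distance **below** the
   chord joining the first and last inspected points. The signed (rather
   than unsigned) rule matters: on a plateau-cliff-tail curve the
   *unsigned* maximum sits at the end of the upper plateau, which would
   place $T$ *on* the genuine pairs and — under the strict `score > T`
   merge rule — discard them; the below-chord maximum lands at the top
   of the tail instead;
3. when smoothing was applied, the threshold is anchored at the largest
   single-rank log-score drop within one window of the smoothed knee
   (the "cliff edge"). On a long flat tail the distance maximum
   otherwise drifts to where the tail's log-log slope matches the chord,
   several ranks *into* the noise;
4. if no point lies below the chord (e.g. geometric decay, which is
   concave in log-log coordinates), the interior unsigned maximum is
   reported with a non-positive `kneeness` quality score, flagging an
   unreliable call. `kneeness` is the chord-normalized knee distance.

An explicit `threshold` always bypasses the call. Fewer than three
scored pairs leave no knee definable; `detect()` then reports every
barcode as a singlet.

```{r knee-toy}
rank_and_knee(c(1, 1, 1, 1, 0.001, 0.0009, 0.0008, 0.0007, 0.0006, 0.0005))
```

### Grouping

Pairs strictly exceeding $T$ are merged iteratively from the strongest
pair down, appending any barcode whose score against a member exceeds
$T$ — equivalent to connected components of the above-threshold pair
graph (the package uses union-find and cross-checks against a generic
components routine in its tests). Ties are broken lexicographically
everywhere, so runs are deterministic. Each group is identified by its
lexicographically smallest member barcode.

## Classifying multiplets: rLCS

Bead multiplets join *unrelated* barcodes; complex beads join *similar*
ones. Similarity is measured by the **restricted longest common
subsequence**: the longest run of consecutive positions at which two
equal-length barcodes agree, with no shifting, insertions or deletions
(distinct from both the LCS and the Hamming distance; `N` matches
nothing). Under a null of independently drawn 16-mers, an rLCS of 6 or
more occurs in well under 0.5% of pairs:

```{r null}
null <- sample_rlcs_null(200000, seed = 1)
rlcs_exceedance(null, 6)
```

The packaged null samples uniform random 16-mers when no barcode pool is
supplied; a platform whitelist, when available, can be passed as
`barcode_pool` (whitelists are constrained — e.g. a minimum pairwise
Hamming distance — so their null is very slightly different from the
uniform one; both stay far below the 0.5% bound at the threshold).

A multiplet's mean pairwise rLCS at or above 6 calls it a
`complex_bead`, otherwise a `bead_multiplet`. The prevalence of complex
beads is summarized by the complex bead rate,

$$\text{rate} = \frac{\#\text{complex beads}}
{\#\text{singlet beads} + \#\text{beads in bead multiplets} +
\#\text{complex beads}},$$

where each heterogeneous multiplet collapses to a single (complex) bead
in both numerator and denominator while bead-multiplet members each
count as one bead. Complex beads usually have a dominant barcode, so the
per-multiplet mean pairwise percent difference of log2 unique fragments,
$|\log_2 f_a - \log_2 f_b| / \tfrac{1}{2}(\log_2 f_a + \log_2 f_b)
\times 100$ (a symmetric percent difference; the per-multiplet average
of pairwise values is what gets compared), is larger for complex beads
than for bead multiplets — `fragment_balance_test()` checks this with a
two-sided two-sample Kolmogorov–Smirnov test.

## Cohort statistics

* `imaging_multiplet_rate()` converts manually counted beads-per-droplet
  distributions into the fraction of bead barcodes residing in
  multi-bead droplets, $\sum_{b=2}^{4} b\,n_b / \sum_{b=1}^{4} b\,n_b$;
  classes above 4 beads cannot be counted reliably by imaging and fold
  into $b = 4$, making the estimate conservative.
* `cluster_association_test()` crosses multiplet membership with cluster
  labels in a $2 \times n$ table and evaluates Pearson's chi-squared
  statistic against $n - 1$ degrees of freedom (for a two-row table this
  equals the generic $(r-1)(c-1)$).
* `same_cluster_enrichment()` asks how often the two barcodes of a
  within-multiplet pair (all $\binom{k}{2}$ combinations per multiplet)
  share a cluster, against a background of label permutations over the
  full barcode set; the permuted mean converges to the label collision
  rate $\sum_c f_c^2$.

## Clonotype abundance adjustment

For V(D)J repertoires the multiplet artifact inflates clone sizes. Let
every droplet emit $m$ detectable barcodes with
$P(1),\dots,P(5) = 0.93, 0.05, 0.01, 0.005, 0.005$ (the package
default, a conservative parameterization estimated from scATAC-seq
multiplet calls). The expected fraction of barcodes residing in
multiplet droplets is then size-biased:

```{r emr}
expected_multiplet_rate()  # 100 * 0.175 / 1.105
```

Given $n$ observed barcodes of which $k$ belong to singleton clonotypes,
one multiplicity per barcode is drawn ($M$), $k$ of the drawn 1s are
reserved for the singletons ($K$), and each clonotype of observed size
$c_j \ge 2$ is deflated by drawing from $M' = M \setminus K$ **with
replacement** until the running sum reaches $c_j$; the number of draws
is the adjusted cell count $c'_j$ (so $c'_j = 1$ exactly when the first
draw already covers $c_j$, and $c'_j = c_j$ exactly when every draw is
a 1). Overshoot is absorbed by the final draw. The procedure is repeated
(100 iterations by default, iteration $i$ seeded `seed + i`) and
summarized by the clone false discovery rate — the fraction of
$c_j \ge 2$ clonotypes collapsing to one cell — and by the percentage of
cells in clones of two or more cells before vs after adjustment.
Sampling *without* replacement (global accounting of the pool) is a
possible alternative reading; with replacement is the simplest one and
the two agree closely when $|M'|$ is large relative to clone sizes, so
no second mode is offered.

### What the adjustment does and does not recover

On repertoires forward-simulated by `simulate_repertoire()` the
adjustment recovers the **total** cell count ($k + \sum_j c'_j$) to
within a few percent. It does **not** recover the true *fraction of
cells in clones of ≥ 2 cells* when true clone sizes are heavily
singleton-dominated (as real repertoires are): resampling from $M'$
corresponds to an uninformative prior over true clone sizes, while under
a singleton-dominated prior an observed 2-barcode clone is truly one
cell far more often than the first-draw rule implies. In our simulations
(2000 cells, ~24% of cells truly clonal, the default multiplicity
distribution) the adjusted percentage lands 7–9 points above the truth —
between the observed and true values. The adjustment is therefore a
*conservative anchor* for how much clonality estimates can shift under a
given multiplet rate, not an unbiased estimator of clonality, and the
corresponding consistency check in the test suite documents this gap
rather than papering over it.

## The synthetic library generator

`simulate_library()` runs the forward process the detector inverts:

| parameter | default | meaning |
|---|---|---|
| `bead_loading` | `c("1" = .954, "2" = .046)` | beads per cell-bearing droplet (from imaged loading proportions of roughly 16% empty / 80% single / 4% multi-bead droplets) |
| `complex_bead_prob` | 0.05 | beads carrying a secondary barcode |
| `complex_minor_fraction` | 0.3 | oligo share of the secondary barcode |
| `shared_run_length` | 9 | contiguous run preserved on secondary barcodes |
| `shared_fragment_rate` | 0.2 | droplet fragments duplicated onto a second member barcode |
| `fragments_per_cell` | 5000 | mean unique fragments (NB, `fragment_dispersion` = 10) |
| genome | 5 × 10 Mb | uniform insertion positions, desk-scale |
| `ambient_rate` | 0.02 | fragments re-emitted under a random barcode |

Within a droplet, fragments are split among member barcodes
multinomially (complex-bead weights `1 - minor`, `minor`), and a
`shared_fragment_rate` fraction is duplicated onto a second member
barcode, modeling pre-pooling re-amplification — the signal detection
relies on. Ambient re-emission copies whole fragments to random
barcodes, which is why chance pairs share coordinates in pairs of two.
The generator records full ground truth (droplet membership, per-barcode
class, planted pairs), so detection sensitivity and false merges are
measurable exactly.

What it deliberately does **not** emulate: sequencing errors and
read-level output, chromatin structure (peaks, cell-type-specific
accessibility), barcode whitelist structure, doublets of two real cells,
and depth-dependent detectability calibrated to any particular dataset.
Passing tests therefore demonstrate the *algorithmic* correctness and
the qualitative physics of the artifact, not performance on any real
library.

## Numerical and design choices

* **Problem sizes.** The bundled studies run at desk scale, chosen once:
  mixing control at 2 × 500 cells (~5000 fragments per cell), the
  downsampling study at 300 cells, the rLCS null at $10^6$ draws, the
  repertoire at 2000 cells with 50–100 iterations.
* **Determinism.** Every stochastic entry point takes a `seed` and
  restores the caller's RNG state; ranking ties break lexicographically.
* **Degenerate inputs.** Empty fragment files parse to empty tables;
  an empty insertion index is an error for the pair statistic; fewer
  than three pairs yield singlets-only detection; a multiplicity
  distribution degenerate at 1 makes the clonotype adjustment the exact
  identity.
* **Downsampling studies** re-run the full detection — including the
  knee — on each downsampled dataset, and compare the resulting pair
  sets against the full-depth set (subset relation and sensitivity).
* **Strictness.** Grouping uses `score > T`, mirroring the exceedance
  wording of the procedure; the report's `droplet_id` is reproducible
  from the member barcodes alone.

## Limitations

Cluster labels, cell calling, and alignment are consumed as inputs, not
reproduced. The exact form of the "modified" Jaccard statistic in the
original tooling is not restated in the sources this package follows;
the definition above is fixed, documented, and switchable to the
weighted variant. The clonotype adjustment inherits the bias discussed
above by design. Fragment files are trusted to be deduplicated and
Tn5-shifted by the upstream pipeline.
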
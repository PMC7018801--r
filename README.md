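# multipletkit

Detection and quantification of **barcode multiplets** in droplet
single-cell ATAC-seq.

Droplet assays assume one oligonucleotide barcode captures one cell's
nucleic acids. In practice a substantial fraction of cell barcodes share
a droplet with other barcodes — either because several beads were
co-encapsulated (*bead multiplets*) or because a single bead carries
heterogeneous barcode sequences from synthesis errors (*complex beads*).
Both fractionate one cell's data across several apparent cells, which
skews per-cell coverage, cell counts, and especially rare-event analyses
such as B/T-cell clonal expansion.

`multipletkit` is for analysts of 10x-style scATAC-seq (and, for the
clonotype module, V(D)J) data who want to find, classify, and correct
for these artifacts, and for methodologists who want a fully synthetic,
ground-truthed test bed for multiplet detection.

## What it computes

* **Detection.** Each ATAC fragment `[start, end)` contributes two
  one-bp Tn5 insertion coordinates, `start` and `end − 1`. Barcode pairs
  are scored with a modified Jaccard index over their distinct insertion
  sets, `J = s / (n_a + n_b − s)`; droplet-mates re-amplify identical
  fragments and score orders of magnitude above genomic coincidence. A
  knee call on the ranked log-log pair curve sets the merge threshold
  `T`, and barcodes connected by pairs with `score > T` merge into
  multiplets (connected components, deterministic tie-breaking).
* **Classification.** The restricted longest common subsequence (rLCS) —
  the longest run of positionally matching bases, no shifting or indels —
  separates complex beads (mean pairwise rLCS ≥ 6; random 16-mer pairs
  reach 6 with probability < 0.5%) from bead multiplets, with the
  complex bead rate
  `#complex / (#singlet beads + #beads in bead multiplets + #complex)`.
* **Cohort statistics.** Imaged bead-loading arithmetic
  (`Σ_{b≥2} b·n_b / Σ_{b≥1} b·n_b`), a 2×n chi-squared test of multiplet
  status against cluster labels (n − 1 df), and permutation-based
  same-cluster enrichment of multiplet pairs.
* **Clonotype adjustment.** A resampling simulation that deflates
  observed clonotype sizes under a barcode multiplicity distribution
  (default `P(m=1..5) = 0.93, 0.05, 0.01, 0.005, 0.005`, expected
  multiplet rate 15.8%), reporting multiplet-adjusted clone sizes, the
  clone false discovery rate, and the percentage of cells in clones
  before/after adjustment.
* **Synthetic data.** A forward simulator (cells → droplets → beads →
  barcodes → fragments) with complete ground truth, so every stage of
  the pipeline is testable without downloading anything.

## Worked example

```r
library(multipletkit)

lib <- simulate_library(synthetic_config(n_cells = 200, seed = 42))
det <- detect(lib$fragments, barcodes = lib$barcodes$barcode)
det
#> Multiplet assignment: 219 barcodes; 19 multiplets containing 38 barcodes; threshold T = 0.0009419
#> Knee call (knee): threshold T = 0.0009419 at rank 20, kneeness = 0.164, 18501 pairs inspected
#> Multiplet barcode percentage: 17.4% of 219 barcodes

cls <- classify_multiplets(det, lib$barcodes)
sum(cls$class == "complex_bead")
#> [1] 11
```

The 200 simulated cells emitted 219 barcodes (some droplets carried two
beads, some beads carried a secondary barcode). Detection ranked 18,501
barcode pairs; the knee call put the threshold at the top of the
coincidental-overlap tail (rank 20, score 9.4e-4), above which exactly
the 19 planted multiplets survive — 38 barcodes, i.e. 17.4% of the
library, in line with the generator's loading and complex-bead settings.
Classification by mean pairwise rLCS labels 11 of the 19 as complex
beads. From these calls the complex bead rate is

```r
complex_bead_rate(n_singlets = 181, n_barcodes_in_bead_multiplets = 16,
                  n_complex_beads = 11)
#> [1] 5.288462
```

— about 5% of beads carry detectable barcode heterogeneity, matching
the simulated `complex_bead_prob = 0.05`.

A shell-oriented front end with the same functionality ships as
`inst/scripts/mkit` (subcommands `detect`, `classify`, `clones`,
`synth`, `mix`, `stats`).

## Documentation

The methods vignette (`vignettes/barcode-multiplets.Rmd`) describes the
detection model, the knee definition, the rLCS null, the clonotype
simulation and its known bias, and exactly what the synthetic generator
does and does not emulate.
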
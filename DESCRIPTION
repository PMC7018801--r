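Package: multipletkit
Title: Detection and Quantification of Barcode Multiplets in Droplet
    Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers barcode multiplets (droplets whose contents were captured
    by more than one oligonucleotide barcode) from droplet single-cell
    ATAC-seq fragment files. Barcode pairs are scored by a modified Jaccard
    index over shared one-base-pair Tn5 insertion coordinates, a knee point
    on the ranked pair curve sets the merge threshold, and connected barcodes
    are grouped into multiplets. Multiplets are classified as complex beads
    (heterogeneous barcodes on one bead) versus bead multiplets (several
    beads in one droplet) using the restricted longest common subsequence of
    the barcode sequences, with supporting bead-loading arithmetic,
    cluster-association statistics, a multiplet-adjusted clonotype abundance
    simulation for V(D)J repertoires, and a forward simulator of synthetic
    droplet libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
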
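# Forward simulator of synthetic droplet scATAC libraries with known
# ground truth: cells -> droplets -> beads -> barcodes -> fragments.
# Multiplets arise exactly as in the real assay model: several beads
# co-encapsulated in one droplet, or a single bead carrying a secondary
# (synthesis-error) barcode that shares a long aligned run with the
# primary. Barcodes of one droplet share re-amplified identical fragments
# at a configurable rate, which is what detection exploits.

#' Configuration for the synthetic library generator
#'
#' Defaults describe a realistic droplet channel: bead loading
#' conditional on a cell-containing droplet of `P(1 bead) = 0.954`,
#' `P(2 beads) = 0.046` (the imaged 80.0% / 3.9% droplet proportions),
#' ~5% of beads complex, a 9-base preserved run on secondary barcodes, a
#' mean of 5000 unique fragments per cell over a 5 x 10 Mb synthetic
#' genome, 20% of a multi-barcode droplet's fragments duplicated across
#' its barcodes, and 2% ambient fragment reassignment.
#'
#' @param n_cells Number of cell-containing droplets.
#' @param barcode_length Barcode length in bases (default 16).
#' @param bead_loading Named probability vector over beads per droplet
#'   (names are bead counts >= 1).
#' @param complex_bead_prob Probability a bead carries a secondary
#'   barcode.
#' @param complex_minor_fraction Fraction of a complex bead's oligos
#'   carrying the secondary barcode.
#' @param shared_run_length Length of the contiguous run a secondary
#'   barcode shares with its primary (default 9).
#' @param shared_fragment_rate Probability a fragment of a multi-barcode
#'   droplet is duplicated onto a second member barcode.
#' @param fragments_per_cell Mean unique fragments per cell.
#' @param fragment_dispersion Negative-binomial size parameter of the
#'   per-cell fragment count.
#' @param fragment_length_range Min/max fragment length (bp).
#' @param n_chromosomes,chromosome_length Synthetic genome model.
#' @param ambient_rate Fraction of fragments additionally emitted under a
#'   random barcode.
#' @param n_clusters Number of cell clusters (labels inherited by all
#'   barcodes of a droplet); 0 disables labels.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cells = 500L,
                             barcode_length = 16L,
                             bead_loading = c(`1` = 0.954, `2` = 0.046),
                             complex_bead_prob = 0.05,
                             complex_minor_fraction = 0.3,
                             shared_run_length = 9L,
                             shared_fragment_rate = 0.2,
                             fragments_per_cell = 5000,
                             fragment_dispersion = 10,
                             fragment_length_range = c(100L, 400L),
                             n_chromosomes = 5L,
                             chromosome_length = 1e7,
                             ambient_rate = 0.02,
                             n_clusters = 4L,
                             seed = NULL) {
  cfg <- list(n_cells = as.integer(n_cells),
              barcode_length = as.integer(barcode_length),
              bead_loading = bead_loading,
              complex_bead_prob = complex_bead_prob,
              complex_minor_fraction = complex_minor_fraction,
              shared_run_length = as.integer(shared_run_length),
              shared_fragment_rate = shared_fragment_rate,
              fragments_per_cell = fragments_per_cell,
              fragment_dispersion = fragment_dispersion,
              fragment_length_range = as.integer(fragment_length_range),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              ambient_rate = ambient_rate,
              n_clusters = as.integer(n_clusters),
              seed = seed)
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1")
  bl <- cfg$bead_loading
  if (is.null(names(bl)) || anyNA(suppressWarnings(as.integer(names(bl)))) ||
      any(as.integer(names(bl)) < 1L))
    stop("bead_loading must be named by bead counts >= 1")
  if (abs(sum(bl) - 1) > 1e-8) stop("bead_loading must sum to 1")
  for (p in c("complex_bead_prob", "complex_minor_fraction",
              "shared_fragment_rate", "ambient_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$shared_run_length > cfg$barcode_length)
    stop("shared_run_length cannot exceed barcode_length")
  structure(cfg, class = "synthetic_config")
}

# Derive a secondary (synthesis-error) barcode from a primary: a
# contiguous run of `run_length` positions starting at `offset` is kept,
# every other position is mutated to a different base, guaranteeing
# rLCS(primary, secondary) >= run_length and primary != secondary.
make_complex_secondary <- function(primary, run_length = 9L,
                                   offset = NULL) {
  chars <- strsplit(primary, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (is.null(offset)) offset <- sample.int(L - run_length + 1L, 1L)
  keep_pos <- seq(offset, offset + run_length - 1L)
  mut <- setdiff(seq_len(L), keep_pos)
  bases <- c("A", "C", "G", "T")
  chars[mut] <- vapply(chars[mut], function(b)
    sample(setdiff(bases, b), 1L), character(1L))
  paste(chars, collapse = "")
}

#' Simulate a synthetic droplet scATAC library
#'
#' Runs the forward process described in [synthetic_config()]: each
#' cell-containing droplet draws a number of beads, each bead may be
#' complex (carrying a secondary barcode that preserves a contiguous run
#' of its primary), the cell's fragments (distinct Tn5 insertion
#' coordinate pairs along the synthetic genome) are split among the
#' droplet's barcodes multinomially, a configurable fraction of fragments
#' is duplicated onto a second member barcode (re-amplified identical
#' insertions), and an ambient fraction is re-emitted under random
#' barcodes. Deterministic under `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_library`: list with `fragments`
#'   (5-column `data.table` sorted by coordinate), `barcodes`
#'   (annotations: `barcode`, `n_fragments`, `cluster`), `truth` (list
#'   with per-barcode `barcodes` table carrying `droplet_id`, `cell`,
#'   `class`; and `multiplet_pairs`), and `config`.
#' @export
simulate_library <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    L <- config$barcode_length

    beads_per_droplet <- resample(as.integer(names(config$bead_loading)),
                                  n, prob = config$bead_loading)
    B <- sum(beads_per_droplet)
    bead_droplet <- rep(seq_len(n), beads_per_droplet)
    complex_flag <- stats::runif(B) < config$complex_bead_prob
    primary <- random_barcodes(B, L)

    # per-droplet barcode/weight tables
    bc_list <- vector("list", B)
    for (bi in seq_len(B)) {
      if (complex_flag[bi]) {
        sec <- make_complex_secondary(primary[bi], config$shared_run_length)
        while (sec %in% primary) {
          sec <- make_complex_secondary(primary[bi], config$shared_run_length)
        }
        bc_list[[bi]] <- data.table(
          droplet = bead_droplet[bi],
          barcode = c(primary[bi], sec),
          weight = c(1 - config$complex_minor_fraction,
                     config$complex_minor_fraction),
          on_complex_bead = TRUE)
      } else {
        bc_list[[bi]] <- data.table(droplet = bead_droplet[bi],
                                    barcode = primary[bi], weight = 1,
                                    on_complex_bead = FALSE)
      }
    }
    bc <- rbindlist(bc_list)
    bc[, weight := weight / sum(weight), by = droplet]

    clusters <- if (config$n_clusters > 0L)
      sample(paste0("C", seq_len(config$n_clusters)), n, replace = TRUE)
    else rep(NA_character_, n)

    # per-cell fragments
    n_frag <- pmax(stats::rnbinom(n, mu = config$fragments_per_cell,
                                  size = config$fragment_dispersion), 10L)
    total <- sum(n_frag)
    frag_cell <- rep(seq_len(n), n_frag)
    chrom <- paste0("chr", sample.int(config$n_chromosomes, total,
                                      replace = TRUE))
    flen <- sample(seq(config$fragment_length_range[1L],
                       config$fragment_length_range[2L]), total,
                   replace = TRUE)
    start <- floor(stats::runif(total,
                                min = 0,
                                max = config$chromosome_length - flen))
    frags <- data.table(cell = frag_cell, chrom = chrom,
                        start = as.integer(start),
                        end = as.integer(start) + flen)

    # assign each fragment a member barcode; duplicate a fraction onto a
    # second member barcode for multi-barcode droplets
    droplet_bcs <- split(bc, by = "droplet", keep.by = FALSE)
    assigned <- vector("list", n)
    extra <- vector("list", n)
    row_of_cell <- split(seq_len(total), frag_cell)
    for (d in seq_len(n)) {
      tab <- droplet_bcs[[as.character(d)]]
      rows <- row_of_cell[[as.character(d)]]
      nf <- length(rows)
      if (nrow(tab) == 1L) {
        assigned[[d]] <- rep(tab$barcode, nf)
        next
      }
      pick <- sample.int(nrow(tab), nf, replace = TRUE, prob = tab$weight)
      assigned[[d]] <- tab$barcode[pick]
      dup <- which(stats::runif(nf) < config$shared_fragment_rate)
      if (length(dup) > 0L) {
        other <- vapply(pick[dup], function(i)
          if (nrow(tab) == 2L) 3L - i
          else sample(setdiff(seq_len(nrow(tab)), i), 1L), integer(1L))
        extra[[d]] <- data.table(row = rows[dup],
                                 barcode = tab$barcode[other])
      }
    }
    # rows are grouped by cell in droplet order, matching unlist(assigned)
    frags[, barcode := unlist(assigned)]
    shared_rows <- rbindlist(extra[!vapply(extra, is.null, logical(1L))])
    frag_out <- frags[, .(chrom, start, end, barcode)]
    if (nrow(shared_rows) > 0L) {
      dup_dt <- frags[shared_rows$row, .(chrom, start, end)]
      dup_dt[, barcode := shared_rows$barcode]
      frag_out <- rbind(frag_out, dup_dt)
    }

    # ambient: a fraction of fragments re-emitted under a random barcode
    n_amb <- stats::rbinom(1L, nrow(frag_out), config$ambient_rate)
    if (n_amb > 0L) {
      amb <- frag_out[sample.int(nrow(frag_out), n_amb)]
      amb[, barcode := sample(bc$barcode, n_amb, replace = TRUE)]
      frag_out <- rbind(frag_out, amb)
    }
    frag_out[, count := 1L]
    setorder(frag_out, chrom, start, end, barcode)

    # ground truth
    bc[, n_droplet_barcodes := .N, by = droplet]
    bc[, class := fifelse(on_complex_bead, "complex_bead",
                   fifelse(n_droplet_barcodes > 1L, "bead_multiplet",
                           "singlet"))]
    bc[, droplet_id := min(barcode), by = droplet]
    truth_bc <- bc[, .(barcode, droplet_id, cell = droplet, class,
                       cluster = clusters[droplet])]
    multi <- split(bc$barcode, bc$droplet)
    multi <- multi[lengths(multi) >= 2L]
    multiplet_pairs <- if (length(multi) > 0L) {
      rbindlist(lapply(multi, function(b) {
        b <- sort(b)
        pr <- utils::combn(b, 2L)
        data.table(barcode_a = pr[1L, ], barcode_b = pr[2L, ])
      }))
    } else data.table(barcode_a = character(), barcode_b = character())

    ann <- frag_out[, .(n_fragments = .N), by = barcode]
    ann <- merge(ann, truth_bc[, .(barcode, cluster)], by = "barcode")
    setorder(ann, barcode)

    structure(list(fragments = frag_out[], barcodes = ann[],
                   truth = list(barcodes = truth_bc[],
                                multiplet_pairs = multiplet_pairs[]),
                   config = config),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  tb <- x$truth$barcodes
  cat("Synthetic droplet library:", nrow(tb), "barcodes from",
      x$config$n_cells, "cells;", nrow(x$fragments), "fragment records;",
      sum(tb$class != "singlet"), "barcodes in planted multiplets\n")
  invisible(x)
}

#' Simulate two independent channels
#'
#' Convenience wrapper producing two independent libraries for the in
#' silico mixing experiment: no shared cells and no shared insertion
#' pools beyond chance, so any cross-channel pair merged after
#' [mix_channels()] + [detect()] is a false positive.
#'
#' @param config_1,config_2 [synthetic_config()] objects; their seeds
#'   should differ (identical non-NULL seeds trigger a warning since the
#'   channels would be copies).
#' @return A list with `channel_1` and `channel_2` synthetic libraries.
#' @export
simulate_two_channels <- function(config_1, config_2) {
  if (!is.null(config_1$seed) && identical(config_1$seed, config_2$seed))
    warning("identical seeds: the two channels will be identical copies")
  list(channel_1 = simulate_library(config_1),
       channel_2 = simulate_library(config_2))
}

#' Simulate a V(D)J repertoire observed through barcode multiplets
#'
#' Forward model for the clonotype adjustment: true cells receive
#' clonotypes from a clone-size distribution; each cell independently
#' draws a barcode multiplicity `m` from `dist` and emits `m` barcodes
#' (secondary barcodes preserve a contiguous `shared_run_length`-base run
#' of the cell's primary barcode, as complex beads do), so the observed
#' clonotype table inflates clone sizes by the multiplet process.
#'
#' @param n_cells Number of true cells.
#' @param clone_size_probs Named probability vector over true clone
#'   sizes.
#' @param dist A [multiplicity_distribution()] for barcodes per cell.
#' @param barcode_length Barcode length (default 16).
#' @param shared_run_length Run preserved on secondary barcodes
#'   (default 9).
#' @param seed Optional integer seed.
#' @return A list with `clonotypes` (observed barcode-level table),
#'   `truth` (list: `cells` table with `cell`, `clonotype_id`, `m`;
#'   `true_sizes`; `true_pct_cells_in_clones` -- percentage of cells in
#'   clones of >= 2 cells).
#' @export
simulate_repertoire <- function(n_cells = 1000L,
                                clone_size_probs = c(`1` = 0.90, `2` = 0.06,
                                                     `3` = 0.02, `4` = 0.01,
                                                     `5` = 0.01),
                                dist = multiplicity_distribution(),
                                barcode_length = 16L,
                                shared_run_length = 9L,
                                seed = NULL) {
  if (!inherits(dist, "multiplicity_distribution"))
    dist <- multiplicity_distribution(dist)
  sz <- suppressWarnings(as.integer(names(clone_size_probs)))
  if (anyNA(sz) || any(sz < 1L)) stop("clone sizes must be integers >= 1")
  if (abs(sum(clone_size_probs) - 1) > 1e-8)
    stop("clone_size_probs must sum to 1")
  with_seed(seed, {
    # draw clone sizes until all cells are covered; trim the last clone
    sizes <- integer(0)
    while (sum(sizes) < n_cells) {
      sizes <- c(sizes, resample(sz, max(64L, n_cells %/% 2L),
                                 prob = clone_size_probs))
    }
    cut_at <- which(cumsum(sizes) >= n_cells)[1L]
    sizes <- sizes[seq_len(cut_at)]
    sizes[cut_at] <- sizes[cut_at] - (sum(sizes) - n_cells)
    if (sizes[cut_at] == 0L) sizes <- sizes[-cut_at]
    clone_ids <- sprintf("clonotype%04d", seq_along(sizes))
    cell_clone <- rep(clone_ids, sizes)
    n_true <- length(cell_clone)

    m <- resample(dist$m, n_true, prob = dist$p)
    primary <- random_barcodes(n_true, barcode_length)
    rows <- vector("list", n_true)
    for (i in seq_len(n_true)) {
      bcs <- primary[i]
      if (m[i] > 1L) {
        offset <- sample.int(barcode_length - shared_run_length + 1L, 1L)
        for (j in seq_len(m[i] - 1L)) {
          repeat {
            sec <- make_complex_secondary(primary[i], shared_run_length,
                                          offset = offset)
            if (!sec %in% bcs && !sec %in% primary) break
          }
          bcs <- c(bcs, sec)
        }
      }
      rows[[i]] <- data.table(barcode = bcs, clonotype_id = cell_clone[i],
                              cell = i)
    }
    obs <- rbindlist(rows)
    true_sizes <- data.table(clonotype_id = clone_ids, n_cells = sizes)
    pct_true <- 100 * sum(sizes[sizes >= 2L]) / sum(sizes)
    list(
      clonotypes = obs[, .(barcode, clonotype_id)],
      truth = list(
        cells = data.table(cell = seq_len(n_true),
                           clonotype_id = cell_clone, m = m),
        true_sizes = true_sizes,
        true_pct_cells_in_clones = pct_true,
        barcode_cell = obs[]
      )
    )
  })
}
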
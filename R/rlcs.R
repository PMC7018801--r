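# Restricted longest common subsequence (rLCS) machinery: the statistic
# itself, its null distribution, multiplet classification into complex
# beads vs bead multiplets, and the clonotype rLCS screen.

#' Restricted longest common subsequence of two barcodes
#'
#' The rLCS is the largest number of *consecutive* positions at which two
#' equal-length strings match, without shifting either string: no
#' insertions or deletions are considered (unlike the LCS) and the matches
#' must form one contiguous run (unlike the Hamming distance, which counts
#' scattered matches). `N` bases match nothing, including another `N`.
#'
#' @param s1,s2 Equal-length barcode strings over `{A,C,G,T,N}`.
#' @return Integer run length in `0..nchar(s1)`.
#' @examples
#' rlcs("ACGT", "ACGT")  # 4
#' rlcs("ACGT", "TGCA")  # 0
#' @export
rlcs <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("rlcs requires equal-length strings (got ",
         nchar(s1), " and ", nchar(s2), ")")
  a <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b <- strsplit(s2, "", fixed = TRUE)[[1L]]
  m <- a == b & a != "N"
  if (!any(m)) return(0L)
  r <- rle(m)
  max(r$lengths[r$values])
}

# Vectorized rLCS for index pairs into a pre-encoded barcode matrix.
pairwise_rlcs <- function(enc, ia, ib) {
  E <- enc[ia, , drop = FALSE] == enc[ib, , drop = FALSE] &
       enc[ia, , drop = FALSE] != 0L
  longest_run_by_row(E)
}

#' Null distribution of the rLCS between random barcode pairs
#'
#' Samples `n_draws` barcode pairs -- from a supplied pool (with
#' replacement, excluding self-pairs), or from uniformly random
#' `barcode_length`-mers over `{A,C,G,T}` when no pool is given (the
#' packaged stand-in for a platform whitelist file) -- and computes the
#' rLCS of each pair. The exceedance probability at the classification
#' threshold (default 6) quantifies how often unrelated barcodes reach
#' that similarity by chance.
#'
#' @param n_draws Number of sampled pairs (>= 1).
#' @param barcode_pool Optional character vector of >= 2 barcodes.
#' @param barcode_length Length of the random barcodes when no pool is
#'   supplied (default 16).
#' @param threshold rLCS threshold at which the exceedance is reported
#'   (default 6).
#' @param seed Optional integer seed.
#' @return An object of class `rlcs_null`: list with `n_draws`, `values`
#'   (integer rLCS per draw), `threshold`, and `exceedance` (fraction of
#'   draws with rLCS >= threshold).
#' @export
sample_rlcs_null <- function(n_draws, barcode_pool = NULL,
                             barcode_length = 16L, threshold = 6L,
                             seed = NULL) {
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("n_draws must be >= 1")
  values <- with_seed(seed, {
    if (is.null(barcode_pool)) {
      L <- as.integer(barcode_length)
      m1 <- matrix(sample.int(4L, n_draws * L, replace = TRUE), n_draws, L)
      m2 <- matrix(sample.int(4L, n_draws * L, replace = TRUE), n_draws, L)
      longest_run_by_row(m1 == m2)
    } else {
      np <- length(barcode_pool)
      if (np < 2L) stop("barcode_pool must contain at least 2 barcodes")
      enc <- barcode_int_matrix(barcode_pool)
      ia <- sample.int(np, n_draws, replace = TRUE)
      ib <- sample.int(np, n_draws, replace = TRUE)
      while (any(self <- ia == ib)) {
        ib[self] <- sample.int(np, sum(self), replace = TRUE)
      }
      pairwise_rlcs(enc, ia, ib)
    }
  })
  structure(list(n_draws = n_draws, values = values,
                 threshold = as.integer(threshold),
                 exceedance = mean(values >= threshold)),
            class = "rlcs_null")
}

#' Exceedance probability of an rLCS null at a query threshold
#'
#' @param null An `rlcs_null` from [sample_rlcs_null()].
#' @param threshold Query rLCS value.
#' @return Fraction of sampled pairs with rLCS >= `threshold`.
#' @export
rlcs_exceedance <- function(null, threshold) {
  stopifnot(inherits(null, "rlcs_null"))
  mean(null$values >= threshold)
}

#' @export
print.rlcs_null <- function(x, ...) {
  cat(sprintf("rLCS null: %d draws; P(rLCS >= %d) = %.4g\n",
              x$n_draws, x$threshold, x$exceedance))
  invisible(x)
}

# Symmetric percent difference of log2 fragment counts for one pair.
log2_pct_diff <- function(fa, fb) {
  la <- log2(fa); lb <- log2(fb)
  m <- (la + lb) / 2
  ifelse(m == 0, 0, abs(la - lb) / m * 100)
}

#' Classify multiplets as complex beads vs bead multiplets
#'
#' For each multiplet, the rLCS of every pairwise combination of member
#' barcodes is averaged; a multiplet of four barcodes thus contributes six
#' pairs. Multiplets with mean rLCS at or above `rlcs_threshold` (default
#' 6, below the chance exceedance of the null) are called `complex_bead`
#' -- heterogeneous barcodes synthesized on one bead -- and the rest
#' `bead_multiplet`. The per-multiplet mean of the pairwise percent
#' difference of log2 unique fragment counts,
#' `|log2 f_a - log2 f_b| / ((log2 f_a + log2 f_b)/2) * 100`,
#' is attached for the fragment balance comparison between classes.
#'
#' @param assignment A `multiplet_assignment` (or `multiplet_detection`).
#' @param annotations Barcode annotations with `barcode` and `n_fragments`
#'   (see [read_barcode_list()]); required for every multiplet member.
#' @param rlcs_threshold Classification cutoff (default 6).
#' @return A `data.table` with one row per multiplet: `droplet_id`,
#'   `n_barcodes`, `n_pairs`, `mean_rlcs`, `class`, `mean_log2_pct_diff`.
#' @export
classify_multiplets <- function(assignment, annotations,
                                rlcs_threshold = 6L) {
  if (inherits(assignment, "multiplet_detection"))
    assignment <- assignment$assignment
  stopifnot(inherits(assignment, "multiplet_assignment"))
  ann <- as.data.table(annotations)
  groups <- assignment$groups[group_size > 1L]
  if (nrow(groups) == 0L) {
    return(data.table(droplet_id = character(), n_barcodes = integer(),
                      n_pairs = integer(), mean_rlcs = numeric(),
                      class = character(), mean_log2_pct_diff = numeric()))
  }
  frag_of <- ann$n_fragments
  names(frag_of) <- ann$barcode
  missing_bc <- setdiff(groups$barcode, ann$barcode)
  if (length(missing_bc) > 0L || anyNA(frag_of[groups$barcode]))
    stop("missing n_fragments annotation for multiplet barcode(s), e.g. ",
         c(missing_bc, groups$barcode[is.na(frag_of[groups$barcode])])[1L])

  out <- groups[, {
    bcs <- sort(barcode)
    pr <- utils::combn(bcs, 2L)
    rl <- vapply(seq_len(ncol(pr)),
                 function(i) rlcs(pr[1L, i], pr[2L, i]), integer(1L))
    pd <- log2_pct_diff(unname(frag_of[pr[1L, ]]), unname(frag_of[pr[2L, ]]))
    .(n_barcodes = length(bcs), n_pairs = ncol(pr),
      mean_rlcs = mean(rl), mean_log2_pct_diff = mean(pd))
  }, by = droplet_id]
  out[, class := ifelse(mean_rlcs >= rlcs_threshold,
                        "complex_bead", "bead_multiplet")]
  setcolorder(out, c("droplet_id", "n_barcodes", "n_pairs", "mean_rlcs",
                     "class", "mean_log2_pct_diff"))
  setorder(out, droplet_id)
  out[]
}

#' Complex bead rate
#'
#' The percentage of *beads* that carry heterogeneous barcodes:
#' \deqn{100 \times n_{complex} / (n_{singlet} + n_{bead\_multiplet\_beads}
#'   + n_{complex})}
#' The numerator counts complex beads (one per heterogeneous-bead
#' multiplet), while the barcodes of each complex bead collapse to a
#' single bead in the denominator; barcodes in bead multiplets each count
#' as one bead.
#'
#' @param n_singlets Number of singlet beads.
#' @param n_barcodes_in_bead_multiplets Number of beads residing in
#'   multi-bead droplets.
#' @param n_complex_beads Number of complex (heterogeneous) beads.
#' @return Percentage (0-100).
#' @examples
#' complex_bead_rate(4732, 121, 253)  # 4.95...
#' @export
complex_bead_rate <- function(n_singlets, n_barcodes_in_bead_multiplets,
                              n_complex_beads) {
  counts <- c(n_singlets, n_barcodes_in_bead_multiplets, n_complex_beads)
  if (any(counts < 0)) stop("counts must be non-negative")
  denom <- sum(counts)
  if (denom == 0) stop("all-zero denominator")
  100 * n_complex_beads / denom
}

#' Compare fragment balance between multiplet classes
#'
#' Tests whether droplets containing multiple beads split reads more
#' evenly than complex beads do, using the per-multiplet mean percent
#' difference of log2 unique fragments from [classify_multiplets()] and a
#' two-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param classes Classification table from [classify_multiplets()].
#' @return A list with `statistic` (KS D), `p_value`, and the two
#'   per-class distributions `complex_bead` and `bead_multiplet`.
#' @export
fragment_balance_test <- function(classes) {
  cl <- as.data.table(classes)
  x <- cl[class == "complex_bead", mean_log2_pct_diff]
  y <- cl[class == "bead_multiplet", mean_log2_pct_diff]
  if (length(x) < 2L || length(y) < 2L)
    stop("both multiplet classes need at least 2 observations")
  ks <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       complex_bead = x, bead_multiplet = y)
}

#' Screen clonotypes for multiplet-driven barcode similarity
#'
#' Within every clonotype of two or more barcodes, computes the rLCS of
#' all barcode pairs; clonotypes whose pairs *all* reach
#' `flag_threshold` (default 9) are flagged as presumptive single-cell
#' multiplets -- apparent clones more parsimoniously explained by one cell
#' observed through a complex bead. A permutation null is built by
#' shuffling the clonotype labels across barcodes so random barcode pairs
#' are considered under the same group-size structure.
#'
#' @param clonotypes Clonotype table (see [read_clonotype_table()]).
#' @param n_permutations Number of label permutations (default 100).
#' @param flag_threshold Minimum rLCS that every pair of a flagged
#'   clonotype must reach (default 9).
#' @param seed Optional integer seed.
#' @return A list with `summary` (per multi-barcode clonotype:
#'   `clonotype_id`, `n_barcodes`, `n_pairs`, `mean_rlcs`, `min_rlcs`,
#'   `flagged`), `observed_values`, `observed_mean`, and `permuted_means`.
#' @export
clonotype_rlcs_screen <- function(clonotypes, n_permutations = 100L,
                                  flag_threshold = 9L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  tbl <- as.data.table(clonotypes)
  sizes <- tbl[, .N, by = clonotype_id]
  if (!any(sizes$N >= 2L))
    stop("no clonotype with >= 2 barcodes to screen")
  enc <- barcode_int_matrix(tbl$barcode)

  pair_index <- function(group_ids) {
    # all within-group index pairs for groups of size >= 2
    idx <- split(seq_along(group_ids), group_ids)
    idx <- idx[lengths(idx) >= 2L]
    prs <- lapply(idx, function(ii) utils::combn(ii, 2L))
    do.call(cbind, prs)
  }

  idx <- split(seq_len(nrow(tbl)), tbl$clonotype_id)
  idx <- idx[lengths(idx) >= 2L]
  prs <- lapply(idx, function(ii) utils::combn(ii, 2L))
  pr <- do.call(cbind, prs)
  grp <- rep(names(prs), vapply(prs, ncol, integer(1L)))
  vals <- pairwise_rlcs(enc, pr[1L, ], pr[2L, ])
  summ <- data.table(clonotype_id = grp, rl = vals)[, .(
    n_pairs = .N, mean_rlcs = mean(rl), min_rlcs = min(rl)
  ), by = clonotype_id]
  summ <- merge(summ, sizes[, .(clonotype_id, n_barcodes = N)],
                by = "clonotype_id")
  summ[, flagged := min_rlcs >= flag_threshold]
  setcolorder(summ, c("clonotype_id", "n_barcodes", "n_pairs",
                      "mean_rlcs", "min_rlcs", "flagged"))

  permuted_means <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      shuffled <- sample(tbl$clonotype_id)
      prp <- pair_index(shuffled)
      mean(pairwise_rlcs(enc, prp[1L, ], prp[2L, ]))
    }, numeric(1L))
  })
  list(summary = summ[order(clonotype_id)], observed_values = vals,
       observed_mean = mean(vals), permuted_means = permuted_means)
}
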
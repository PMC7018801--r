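# Bead-loading arithmetic and cluster-association statistics.

#' Barcode multiplet rate implied by imaged bead loading
#'
#' Given manual counts of beads per droplet from imaging, computes the
#' percentage of bead barcodes that reside in multi-bead droplets:
#' \deqn{\% multiplets = \sum_{b=2}^{4} b\,n_b / \sum_{b=1}^{4} b\,n_b
#'   \times 100}
#' Droplets with zero beads are excluded from both sums; droplet classes
#' above four beads cannot be reliably counted by imaging and are folded
#' into the `b = 4` class.
#'
#' @param counts Named non-negative numeric vector of droplet counts, the
#'   names giving the number of beads per droplet (e.g.
#'   `c("0" = 15, "1" = 80, "2" = 5)`).
#' @return Percentage (0-100).
#' @examples
#' imaging_multiplet_rate(c("0" = 15, "1" = 80, "2" = 5))  # 11.11
#' @export
imaging_multiplet_rate <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named by beads/droplet")
  b <- suppressWarnings(as.integer(names(counts)))
  if (anyNA(b) || any(b < 0L)) stop("names must be integers >= 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  b <- pmin(b, 4L)
  n_b <- tapply(as.numeric(counts), b, sum)
  bb <- as.integer(names(n_b))
  denom <- sum(bb[bb >= 1L] * n_b[bb >= 1L])
  if (denom == 0) stop("no bead-containing droplets")
  100 * sum(bb[bb >= 2L] * n_b[bb >= 2L]) / denom
}

#' Build the multiplet-by-cluster contingency table
#'
#' Assembles the 2 x n table crossing multiplet membership (in a group of
#' size >= 2, or not) with cluster labels, for
#' [cluster_association_test()].
#'
#' @param assignment A `multiplet_assignment` (or `multiplet_detection`).
#' @param clusters Barcode cluster labels: a `data.table` with `barcode`
#'   and `cluster` columns, or a named character vector.
#' @return An integer matrix with rows `in_multiplet`, `singlet` and one
#'   column per cluster.
#' @export
make_contingency_table <- function(assignment, clusters) {
  if (inherits(assignment, "multiplet_detection"))
    assignment <- assignment$assignment
  lab <- cluster_lookup(clusters)
  g <- assignment$groups
  cl <- unname(lab[g$barcode])
  if (anyNA(cl)) stop("barcode without a cluster label: ",
                      g$barcode[which(is.na(cl))[1L]])
  status <- ifelse(g$group_size > 1L, "in_multiplet", "singlet")
  tab <- table(factor(status, levels = c("in_multiplet", "singlet")), cl)
  m <- matrix(as.integer(tab), nrow = 2L,
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

cluster_lookup <- function(clusters) {
  if (is.data.frame(clusters)) {
    dt <- as.data.table(clusters)
    lab <- as.character(dt$cluster)
    names(lab) <- dt$barcode
  } else {
    lab <- as.character(clusters)
    names(lab) <- names(clusters)
  }
  lab
}

#' Chi-squared test of multiplet status against cluster assignment
#'
#' Pearson chi-squared statistic on a 2 x n contingency table of multiplet
#' status by cluster, with the p-value taken from the chi-squared
#' distribution with `n - 1` degrees of freedom (for a 2 x n table this
#' coincides with the usual `(2-1)(n-1)`).
#'
#' @param table A 2 x n integer matrix (see [make_contingency_table()]).
#' @return A list with `statistic`, `df`, `p_value`, `table`.
#' @export
cluster_association_test <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L) stop("expected a 2 x n contingency table")
  if (ncol(tab) < 2L) stop("need at least 2 clusters")
  if (any(tab < 0)) stop("negative cell count")
  if (any(colSums(tab) == 0)) stop("cluster column with zero total")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Same-cluster enrichment of multiplet barcode pairs
#'
#' Over all pairwise combinations of barcodes within each multiplet (a
#' 4-barcode multiplet contributes six pairs), computes the proportion of
#' pairs whose two barcodes share a cluster label, and a background rate
#' from permutations in which cluster labels are shuffled across the
#' *full* barcode set. As permutations grow, the background converges to
#' the label collision probability `sum(f_c^2)` for cluster frequencies
#' `f_c`.
#'
#' @param assignment A `multiplet_assignment` (or `multiplet_detection`).
#' @param clusters Barcode cluster labels (see
#'   [make_contingency_table()]); every barcode in the assignment must be
#'   labeled.
#' @param n_permutations Number of label permutations (default 100).
#' @param seed Optional integer seed.
#' @return A list with `observed`, `permuted` (vector of per-permutation
#'   proportions), `expected_collision` (`sum(f_c^2)`), and `n_pairs`.
#' @export
same_cluster_enrichment <- function(assignment, clusters,
                                    n_permutations = 100L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (inherits(assignment, "multiplet_detection"))
    assignment <- assignment$assignment
  lab <- cluster_lookup(clusters)
  g <- assignment$groups[group_size > 1L]
  if (nrow(g) == 0L) stop("no multiplets in assignment")
  idx <- split(g$barcode, g$droplet_id)
  pr <- do.call(cbind, lapply(idx, function(b) utils::combn(b, 2L)))
  la <- unname(lab[pr[1L, ]]); lb <- unname(lab[pr[2L, ]])
  if (anyNA(la) || anyNA(lb)) stop("multiplet barcode without cluster label")
  observed <- mean(la == lb)

  all_bc <- names(lab)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      pl <- lab
      names(pl) <- sample(all_bc)
      mean(unname(pl[pr[1L, ]]) == unname(pl[pr[2L, ]]))
    }, numeric(1L))
  })
  f <- table(lab) / length(lab)
  list(observed = observed, permuted = permuted,
       expected_collision = sum(f^2), n_pairs = ncol(pr))
}
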
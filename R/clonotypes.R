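# Multiplet-adjusted clonotype abundance simulation: every observed
# barcode is imagined to carry a latent multiplicity m (how many barcodes
# its droplet emitted), and clonotype sizes are deflated by resampling
# droplets until the observed barcode count is explained.

#' Barcode multiplicity distribution
#'
#' Probability that a droplet emits `m` detectable barcodes. The default
#' is the conservative parameterization estimated from scATAC-seq
#' multiplet calls: `P(1)=0.93, P(2)=0.05, P(3)=0.01, P(4)=0.005,
#' P(5)=0.005`.
#'
#' @param probs Named (or positionally `1..length`) non-negative numeric
#'   vector summing to 1.
#' @return An object of class `multiplicity_distribution`.
#' @export
multiplicity_distribution <- function(probs = c(`1` = 0.93, `2` = 0.05,
                                                `3` = 0.01, `4` = 0.005,
                                                `5` = 0.005)) {
  p <- as.numeric(probs)
  nm <- if (is.null(names(probs))) as.character(seq_along(p)) else names(probs)
  m <- suppressWarnings(as.integer(nm))
  if (anyNA(m) || any(m < 1L)) stop("multiplicities must be integers >= 1")
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  structure(list(m = m, p = unname(p)), class = "multiplicity_distribution")
}

#' @export
print.multiplicity_distribution <- function(x, ...) {
  cat("Multiplicity distribution: P(m) =",
      paste(sprintf("%d:%g", x$m, x$p), collapse = ", "),
      sprintf("; expected multiplet rate %.1f%%\n",
              expected_multiplet_rate(x)))
  invisible(x)
}

#' Expected barcode multiplet rate of a multiplicity distribution
#'
#' The expected fraction of barcodes residing in droplets that emitted two
#' or more barcodes:
#' \deqn{100 \times \sum_{m \ge 2} m P(m) / \sum_m m P(m)}
#'
#' @param dist A [multiplicity_distribution()].
#' @return Percentage (0-100). The default distribution gives 15.8%
#'   (0.175 / 1.105).
#' @export
expected_multiplet_rate <- function(dist = multiplicity_distribution()) {
  if (!inherits(dist, "multiplicity_distribution"))
    dist <- multiplicity_distribution(dist)
  with(dist, 100 * sum(m[m >= 2L] * p[m >= 2L]) / sum(m * p))
}

#' Draw barcode multiplicities with a singleton-clonotype reservation
#'
#' Draws `n` i.i.d. multiplicities `M` and reserves `k` of the drawn 1s as
#' the set `K` for the `k` singleton clonotypes (which can only arise from
#' barcode singlets); the remainder `M' = M \ K` is the multiplicity pool
#' used to deflate multi-barcode clonotypes. If a draw of `M` contains
#' fewer than `k` ones, the whole vector is redrawn (and the redraw
#' counted).
#'
#' @param n Total number of barcodes.
#' @param k Number of singleton clonotypes (`k <= n`).
#' @param dist A [multiplicity_distribution()].
#' @param seed Optional integer seed.
#' @param max_redraws Safety cap on redraws.
#' @return A list with `M`, `K`, `M_prime`, `n_redraws`.
#' @export
draw_multiplicities <- function(n, k, dist = multiplicity_distribution(),
                                seed = NULL, max_redraws = 10000L) {
  if (!inherits(dist, "multiplicity_distribution"))
    dist <- multiplicity_distribution(dist)
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L) stop("n must be >= 1")
  if (k > n) stop("k (singleton clonotypes) cannot exceed n (barcodes)")
  with_seed(seed, {
    n_redraws <- 0L
    repeat {
      M <- resample(dist$m, n, prob = dist$p)
      if (sum(M == 1L) >= k) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop("could not draw ", k, " singleton multiplicities in ",
             max_redraws, " redraws")
    }
    ones <- which(M == 1L)
    K <- rep(1L, k)
    M_prime <- if (k > 0L) M[-ones[seq_len(k)]] else M
    list(M = M, K = K, M_prime = M_prime, n_redraws = n_redraws)
  })
}

#' Multiplet-adjusted clonotype abundances
#'
#' For each clonotype `j` of observed size `c_j >= 2`, repeatedly samples
#' multiplicities from the pool `M'` (with replacement) until their
#' running sum meets or exceeds `c_j`; the number of draws is the adjusted
#' cell count `c'_j` -- the number of multiplet-aware droplets needed to
#' explain the observed barcode abundance. Singleton clonotypes are the
#' reserved set `K` and keep size 1. The procedure is repeated over
#' `n_iterations` independent iterations (iteration `i` is seeded with
#' `seed + i` when a seed is given) and summarized by per-clonotype means,
#' the clone false discovery rate (fraction of `c_j >= 2` clonotypes
#' collapsing to `c'_j = 1`), and the percentage of cells residing in
#' clonotypes of two or more cells before vs after adjustment.
#'
#' @param clonotypes Barcode-level clonotype table (see
#'   [read_clonotype_table()]), or any table with `clonotype_id` one row
#'   per barcode.
#' @param dist A [multiplicity_distribution()].
#' @param n_iterations Number of simulation iterations (default 100).
#' @param seed Optional integer master seed.
#' @return An object of class `clonotype_adjustment`: list with
#'   `per_clonotype` (`clonotype_id`, `c_original`, `c_adjusted_mean`,
#'   `p_collapsed`), `clone_fdr`, `clone_fdr_se`,
#'   `pct_cells_in_clones_before`, `pct_cells_in_clones_after`,
#'   `pct_cells_in_clones_after_se`, `n_iterations`.
#' @export
adjust_clonotypes <- function(clonotypes, dist = multiplicity_distribution(),
                              n_iterations = 100L, seed = NULL) {
  if (!inherits(dist, "multiplicity_distribution"))
    dist <- multiplicity_distribution(dist)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  sizes <- clonotype_sizes(clonotypes)
  if (any(sizes$n_barcodes < 1L)) stop("clonotype of size 0")
  n <- sum(sizes$n_barcodes)
  k <- sizes[n_barcodes == 1L, .N]
  multi <- sizes[n_barcodes >= 2L]
  cj <- multi$n_barcodes

  pct_before <- if (n > 0) 100 * sum(cj) / n else 0

  cp_mat <- matrix(NA_integer_, nrow = nrow(multi), ncol = n_iterations)
  fdr_it <- numeric(n_iterations)
  pct_after_it <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    it_seed <- if (is.null(seed)) NULL else as.integer(seed) + i
    cp <- with_seed(it_seed, {
      dr <- draw_multiplicities(n, k, dist)
      Mp <- dr$M_prime
      if (length(Mp) == 0L && nrow(multi) > 0L)
        stop("empty M' with multi-barcode clonotypes present")
      vapply(cj, function(c_j) {
        d <- resample(Mp, c_j)  # at most c_j draws suffice
        which.max(cumsum(d) >= c_j)
      }, integer(1L))
    })
    cp_mat[, i] <- cp
    fdr_it[i] <- if (length(cp) > 0L) mean(cp == 1L) else NA_real_
    # adjusted library: K singletons plus the c'_j
    total_after <- k + sum(cp)
    pct_after_it[i] <- if (total_after > 0)
      100 * sum(cp[cp >= 2L]) / total_after else 0
  }

  per_clone <- rbind(
    data.table(clonotype_id = multi$clonotype_id, c_original = cj,
               c_adjusted_mean = rowMeans(cp_mat),
               p_collapsed = rowMeans(cp_mat == 1L)),
    data.table(clonotype_id = sizes[n_barcodes == 1L, clonotype_id],
               c_original = 1L, c_adjusted_mean = 1, p_collapsed = 0)
  )
  setorder(per_clone, clonotype_id)

  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(
    per_clonotype = per_clone[],
    clone_fdr = mean(fdr_it),
    clone_fdr_se = se(fdr_it),
    pct_cells_in_clones_before = pct_before,
    pct_cells_in_clones_after = mean(pct_after_it),
    pct_cells_in_clones_after_se = se(pct_after_it),
    n_iterations = n_iterations
  ), class = "clonotype_adjustment")
}

#' @export
print.clonotype_adjustment <- function(x, ...) {
  cat(sprintf(paste0(
    "Clonotype multiplet adjustment (%d iterations):\n",
    "  cells in clones (>= 2): %.1f%% -> %.1f%% (SE %.2f)\n",
    "  clone FDR: %.1f%% (SE %.2f)\n"),
    x$n_iterations, x$pct_cells_in_clones_before,
    x$pct_cells_in_clones_after, x$pct_cells_in_clones_after_se,
    100 * x$clone_fdr, 100 * x$clone_fdr_se))
  invisible(x)
}
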
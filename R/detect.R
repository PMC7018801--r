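# Core multiplet detection: Tn5 insertion indexing, the pairwise overlap
# statistic, the knee call on the ranked pair curve, and grouping of
# above-threshold pairs into multiplets.

#' Build a per-barcode Tn5 insertion index
#'
#' Each ATAC fragment is bounded by two Tn5 insertion events. Under the
#' half-open BED convention of the fragments format, the two one-base-pair
#' insertion coordinates of a fragment `[start, end)` are `start` and
#' `end - 1`. Duplicate coordinates within a barcode collapse (set
#' semantics); when the count-weighted statistic is requested later, the
#' summed duplicate count per coordinate is retained as a weight.
#'
#' @param fragments A fragments `data.table` (see [read_fragments()]),
#'   already whitelist-filtered.
#' @return An object of class `insertion_index`: a list with `insertions`
#'   (`data.table` of `barcode`, `chrom`, `pos`, `weight`) and `counts`
#'   (`data.table` of `barcode`, `n_insertions`).
#' @export
extract_insertions <- function(fragments) {
  f <- as.data.table(fragments)
  need <- c("chrom", "start", "end", "barcode")
  if (!all(need %in% names(f)))
    stop("fragments must have columns chrom, start, end, barcode")
  if (!"count" %in% names(f)) f <- copy(f)[, count := 1L]
  ins <- rbind(
    f[, .(barcode, chrom, pos = start, count)],
    f[, .(barcode, chrom, pos = end - 1L, count)]
  )
  ins <- ins[, .(weight = sum(count)), by = .(barcode, chrom, pos)]
  counts <- ins[, .(n_insertions = .N), by = barcode]
  setkey(ins, chrom, pos)
  structure(list(insertions = ins, counts = counts),
            class = "insertion_index")
}

#' @export
print.insertion_index <- function(x, ...) {
  cat("Tn5 insertion index:", nrow(x$counts), "barcodes,",
      nrow(x$insertions), "distinct (barcode, coordinate) insertions\n")
  invisible(x)
}

#' Pairwise barcode overlap statistic
#'
#' Scores every barcode pair sharing at least one Tn5 insertion coordinate
#' with a modified Jaccard index
#' \deqn{score = shared / (n_a + n_b - shared)}
#' over the barcodes' distinct insertion sets. The returned list is sorted
#' by descending score with lexicographic `(barcode_a, barcode_b)`
#' tie-breaks, so runs are fully deterministic.
#'
#' @param index An `insertion_index` from [extract_insertions()].
#' @param min_insertions Barcodes with fewer distinct insertions are
#'   excluded before pairing (noise floor; default 100).
#' @param top_k_per_barcode If set, a pair is retained only when it ranks
#'   within the strongest `k` partners of at least one of its barcodes,
#'   before global ranking.
#' @param min_shared Minimum shared-insertion count for a pair to be
#'   reported (default 1; [detect()] uses 2 before ranking).
#' @param statistic `"jaccard"` (distinct coordinates; default) or
#'   `"weighted"` (duplicate-count-weighted: the numerator sums
#'   `min(weight_a, weight_b)` over shared coordinates and the denominator
#'   is the weighted union).
#' @return A `data.table` with columns `barcode_a`, `barcode_b`
#'   (`barcode_a < barcode_b`), `shared`, `n_a`, `n_b`, `score`.
#' @export
pair_overlap_statistic <- function(index, min_insertions = 100L,
                                   top_k_per_barcode = NULL,
                                   min_shared = 1L,
                                   statistic = c("jaccard", "weighted")) {
  stopifnot(inherits(index, "insertion_index"))
  statistic <- match.arg(statistic)
  if (nrow(index$insertions) == 0L) stop("empty insertion index")
  stopifnot(min_insertions >= 1L, min_shared >= 1L)

  keep_bc <- index$counts[n_insertions >= min_insertions, barcode]
  ins <- index$insertions[barcode %chin% keep_bc]
  empty <- data.table(barcode_a = character(), barcode_b = character(),
                      shared = integer(), n_a = integer(), n_b = integer(),
                      score = numeric())
  if (nrow(ins) == 0L) return(empty)

  j <- ins[ins, on = .(chrom, pos), allow.cartesian = TRUE]
  j <- j[barcode < i.barcode]
  if (nrow(j) == 0L) return(empty)
  pairs <- j[, .(shared = .N, shared_w = sum(pmin(weight, i.weight))),
             by = .(barcode_a = barcode, barcode_b = i.barcode)]

  if (statistic == "jaccard") {
    n_of <- index$counts$n_insertions
    names(n_of) <- index$counts$barcode
    pairs[, n_a := unname(n_of[barcode_a])]
    pairs[, n_b := unname(n_of[barcode_b])]
    pairs[, score := shared / (n_a + n_b - shared)]
  } else {
    tot_w <- ins[, .(w = sum(weight)), by = barcode]
    w_of <- tot_w$w
    names(w_of) <- tot_w$barcode
    pairs[, n_a := unname(w_of[barcode_a])]
    pairs[, n_b := unname(w_of[barcode_b])]
    pairs[, score := shared_w / (n_a + n_b - shared_w)]
  }
  pairs[, shared_w := NULL]
  pairs <- pairs[shared >= min_shared]
  setorder(pairs, -score, barcode_a, barcode_b)

  if (!is.null(top_k_per_barcode)) {
    k <- as.integer(top_k_per_barcode)
    stopifnot(k >= 1L)
    long <- rbind(pairs[, .(bc = barcode_a, id = .I, score)],
                  pairs[, .(bc = barcode_b, id = .I, score)])
    setorder(long, bc, -score)
    long[, rank_a := seq_len(.N), by = bc]
    keep_ids <- unique(long[rank_a <= k, id])
    pairs <- pairs[sort(keep_ids)]
    setorder(pairs, -score, barcode_a, barcode_b)
  }
  pairs[]
}

#' Knee call on the ranked barcode-pair curve
#'
#' Infers the merge threshold `T` as an inflection ("knee") point on the
#' ranked pair-score curve, in log10(rank) vs log10(score) space over the
#' inspected prefix. The log-score curve is smoothed with a centered
#' running mean (window `smooth_window` ranks, applied only when the curve
#' has more than twice that many points), and the knee is the point of
#' maximum perpendicular distance *below* the chord joining the first and
#' last inspected points -- the top of the lower (noise) regime of a
#' plateau-cliff-tail curve. When no point falls below the chord (a curve
#' with no elbow, e.g. pure geometric decay, which is concave in log-log
#' space) the interior point of maximum unsigned distance is used and the
#' `kneeness` quality score is non-positive, flagging an unreliable call.
#' The returned threshold is the *unsmoothed* score at the knee rank.
#'
#' @param pairs Pair table from [pair_overlap_statistic()] (sorted
#'   non-increasing by score) or a numeric score vector.
#' @param inspect_top Number of top-ranked pairs inspected (default
#'   500,000).
#' @param smooth_window Running-mean window in ranks (default 25).
#' @param threshold Optional explicit threshold; when supplied the knee
#'   call is bypassed and the value is echoed in the result.
#' @return An object of class `knee_result`: list with `threshold_T`,
#'   `rank_at_knee`, `curve` (the inspected scores), `kneeness`, `method`.
#' @export
rank_and_knee <- function(pairs, inspect_top = 500000L, smooth_window = 25L,
                          threshold = NULL) {
  scores <- if (is.numeric(pairs)) as.numeric(pairs) else pairs$score
  scores <- sort(scores, decreasing = TRUE)
  if (!is.null(threshold)) {
    return(structure(list(threshold_T = as.numeric(threshold),
                          rank_at_knee = NA_integer_, curve = scores,
                          kneeness = NA_real_, method = "user"),
                     class = "knee_result"))
  }
  n <- min(length(scores), as.integer(inspect_top))
  if (n < 3L)
    stop("fewer than 3 pairs: no knee definable, supply an explicit threshold")
  s <- scores[seq_len(n)]
  if (any(s <= 0)) stop("scores must be positive for the log-log knee call")

  x <- log10(seq_len(n))
  y <- log10(s)
  ys <- y
  if (n > 2L * smooth_window) {
    kern <- rep(1 / smooth_window, smooth_window)
    sm <- as.numeric(stats::filter(y, kern, sides = 2L))
    ys[!is.na(sm)] <- sm[!is.na(sm)]
  }
  below_chord <- function(yy) {
    slope <- (yy[n] - yy[1L]) / (x[n] - x[1L])
    d <- ((yy[1L] + slope * (x - x[1L])) - yy) / sqrt(1 + slope^2)
    d[c(1L, n)] <- 0
    d
  }
  chord_len <- sqrt((x[n] - x[1L])^2 + (ys[n] - ys[1L])^2)
  d <- below_chord(ys)
  if (max(d) > 0) {
    knee <- which.max(d)
    kneeness <- max(d) / chord_len
    if (!identical(ys, y)) {
      # smoothing smears the cliff across the window, and on a long flat
      # tail the distance maximum drifts to where the tail slope matches
      # the chord; anchor the threshold at the cliff edge instead -- the
      # largest single-rank log-score drop near the smoothed knee
      win <- seq(max(2L, knee - smooth_window),
                 min(n, knee + smooth_window))
      drops <- y[win - 1L] - y[win]
      knee <- win[which.max(drops)]
    }
  } else {
    inner <- seq(2L, n - 1L)
    knee <- inner[which.max(abs(d[inner]))]
    kneeness <- -max(abs(d[inner])) / chord_len
  }
  structure(list(threshold_T = s[knee], rank_at_knee = as.integer(knee),
                 curve = s, kneeness = kneeness, method = "knee"),
            class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  cat("Knee call (", x$method, "): threshold T = ",
      format(x$threshold_T, digits = 4),
      if (!is.na(x$rank_at_knee)) paste0(" at rank ", x$rank_at_knee) else "",
      ", kneeness = ", format(x$kneeness, digits = 3),
      ", ", length(x$curve), " pairs inspected\n", sep = "")
  invisible(x)
}

#' Group barcodes into multiplets
#'
#' Barcodes connected (transitively) by pairs with score strictly
#' exceeding `threshold` form one multiplet: starting from the
#' highest-scoring remaining pair, any barcode whose overlap with a member
#' exceeds the threshold is appended, which is equivalent to the connected
#' components of the above-threshold pair graph. Remaining barcodes are
#' singlets. Each group's `droplet_id` is its lexicographically smallest
#' member barcode.
#'
#' @param pairs Pair table from [pair_overlap_statistic()].
#' @param threshold The merge threshold `T`; pairs must *exceed* it.
#' @param barcodes Optional universe of barcodes (e.g. the cell whitelist);
#'   defaults to the barcodes present in `pairs`.
#' @return An object of class `multiplet_assignment`: list with `groups`
#'   (`data.table` of `barcode`, `droplet_id`, `group_size`),
#'   `above_threshold_pairs`, and `threshold`.
#' @export
group_multiplets <- function(pairs, threshold, barcodes = NULL) {
  pairs <- as.data.table(pairs)
  ap <- pairs[score > threshold]
  setorder(ap, -score, barcode_a, barcode_b)
  universe <- sort(unique(c(barcodes, ap$barcode_a, ap$barcode_b)))
  if (length(universe) == 0L) universe <- character(0)

  parent <- seq_along(universe)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(ap$barcode_a, universe)
  ib <- match(ap$barcode_b, universe)
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(universe), find, integer(1L))
  groups <- data.table(barcode = universe, root = root)
  if (nrow(groups) > 0L) {
    groups[, droplet_id := min(barcode), by = root]
    groups[, group_size := .N, by = root]
  } else {
    groups[, `:=`(droplet_id = character(), group_size = integer())]
  }
  groups[, root := NULL]
  setorder(groups, droplet_id, barcode)
  structure(list(groups = groups[], above_threshold_pairs = ap[],
                 threshold = threshold),
            class = "multiplet_assignment")
}

#' @export
print.multiplet_assignment <- function(x, ...) {
  g <- x$groups
  n_multi <- g[group_size > 1L, uniqueN(droplet_id)]
  cat("Multiplet assignment:", nrow(g), "barcodes;",
      n_multi, "multiplets containing", g[group_size > 1L, .N],
      "barcodes; threshold T =", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Percentage of barcodes residing in multiplets
#'
#' @param n_multiplet_barcodes Number of barcodes in groups of size >= 2.
#' @param n_total Total number of cell barcodes.
#' @return Percentage (0-100).
#' @export
multiplet_barcode_pct <- function(n_multiplet_barcodes, n_total) {
  stopifnot(n_total > 0, n_multiplet_barcodes >= 0,
            n_multiplet_barcodes <= n_total)
  100 * n_multiplet_barcodes / n_total
}

#' End-to-end barcode multiplet detection
#'
#' Runs the full pipeline: insertion extraction, pairwise overlap
#' statistic, knee threshold (unless an explicit `threshold` is given), and
#' grouping into multiplets, plus the multiplet barcode percentage. With
#' fewer than three scored pairs and no explicit threshold, no knee is
#' definable and every barcode is reported as a singlet.
#'
#' @param fragments Fragments `data.table` or a path readable by
#'   [read_fragments()].
#' @param barcodes Optional cell-barcode whitelist: a character vector, a
#'   `data.table` with a `barcode` column, or a path readable by
#'   [read_barcode_list()]. Restricts fragments and defines the
#'   singlet universe.
#' @param threshold Optional explicit merge threshold `T`.
#' @param min_insertions,min_shared,top_pairs,smooth_window,statistic
#'   Tuning knobs passed through to [pair_overlap_statistic()] and
#'   [rank_and_knee()]; `min_shared = 2` drops single-coincidence pairs
#'   before ranking.
#' @return An object of class `multiplet_detection`: list with
#'   `assignment` ([group_multiplets()] result), `knee`
#'   ([rank_and_knee()] result or `NULL`), `pairs` (the ranked pair
#'   table), `multiplet_pct`, and `n_barcodes`.
#' @export
detect <- function(fragments, barcodes = NULL, threshold = NULL,
                   min_insertions = 100L, min_shared = 2L,
                   top_pairs = 500000L, smooth_window = 25L,
                   statistic = "jaccard") {
  wl <- NULL
  if (!is.null(barcodes)) {
    if (is.character(barcodes) && length(barcodes) == 1L &&
        file.exists(barcodes)) {
      barcodes <- read_barcode_list(barcodes)
    }
    wl <- if (is.data.frame(barcodes)) as.character(barcodes[["barcode"]])
          else as.character(barcodes)
  }
  if (is.character(fragments) && length(fragments) == 1L) {
    fragments <- read_fragments(fragments, barcode_whitelist = wl)
  } else {
    fragments <- as.data.table(fragments)
    if (!is.null(wl)) fragments <- fragments[barcode %chin% wl]
  }
  index <- extract_insertions(fragments)
  universe <- if (!is.null(wl)) wl else index$counts$barcode

  pairs <- if (nrow(index$insertions) > 0L) {
    pair_overlap_statistic(index, min_insertions = min_insertions,
                           min_shared = min_shared, statistic = statistic)
  } else {
    data.table(barcode_a = character(), barcode_b = character(),
               shared = integer(), n_a = integer(), n_b = integer(),
               score = numeric())
  }

  knee <- NULL
  if (!is.null(threshold)) {
    knee <- rank_and_knee(pairs, inspect_top = top_pairs,
                          smooth_window = smooth_window,
                          threshold = threshold)
  } else if (nrow(pairs) >= 3L) {
    knee <- rank_and_knee(pairs, inspect_top = top_pairs,
                          smooth_window = smooth_window)
  } else if (nrow(pairs) > 0L) {
    warning("fewer than 3 scored pairs; no knee definable, ",
            "all barcodes reported as singlets")
  }
  thr <- if (!is.null(knee)) knee$threshold_T else Inf
  assignment <- group_multiplets(pairs, thr, barcodes = universe)

  n_total <- length(unique(universe))
  n_multi <- assignment$groups[group_size > 1L, .N]
  structure(list(assignment = assignment, knee = knee, pairs = pairs,
                 multiplet_pct = multiplet_barcode_pct(n_multi, n_total),
                 n_barcodes = n_total),
            class = "multiplet_detection")
}

#' @export
print.multiplet_detection <- function(x, ...) {
  print(x$assignment)
  if (!is.null(x$knee)) print(x$knee)
  cat(sprintf("Multiplet barcode percentage: %.1f%% of %d barcodes\n",
              x$multiplet_pct, x$n_barcodes))
  invisible(x)
}

#' Merge two channels for an in silico mixing experiment
#'
#' Suffixes every barcode with its channel tag so barcodes from the two
#' experiments stay uniquely identifiable, concatenates the fragment
#' streams, and emits the combined whitelist plus a channel map. Any
#' barcode pair merged *across* channels by a subsequent [detect()] run is
#' by construction a false positive.
#'
#' @param fragments_1,fragments_2 Fragment `data.table`s (or paths).
#' @param barcodes_1,barcodes_2 Optional per-channel barcode whitelists.
#' @param tag_1,tag_2 Distinct channel tags appended as `"-<tag>"`.
#' @return A list with `fragments`, `barcodes` (combined whitelist) and
#'   `channel_map` (`data.table` of `barcode`, `channel`).
#' @export
mix_channels <- function(fragments_1, fragments_2,
                         barcodes_1 = NULL, barcodes_2 = NULL,
                         tag_1 = "1", tag_2 = "2") {
  if (identical(tag_1, tag_2)) stop("channel tags collide: ", tag_1)
  load1 <- function(f) if (is.character(f) && length(f) == 1L)
    read_fragments(f) else as.data.table(f)
  f1 <- copy(load1(fragments_1)); f2 <- copy(load1(fragments_2))
  f1[, barcode := paste0(barcode, "-", tag_1)]
  f2[, barcode := paste0(barcode, "-", tag_2)]
  bc1 <- if (is.null(barcodes_1)) unique(f1$barcode)
         else paste0(as.character(barcodes_1), "-", tag_1)
  bc2 <- if (is.null(barcodes_2)) unique(f2$barcode)
         else paste0(as.character(barcodes_2), "-", tag_2)
  list(
    fragments = rbind(f1, f2),
    barcodes = c(bc1, bc2),
    channel_map = data.table(barcode = c(bc1, bc2),
                             channel = rep(c(tag_1, tag_2),
                                           c(length(bc1), length(bc2))))
  )
}

#' Summarize merged pairs by channel of origin
#'
#' Counts the above-threshold pairs of a mixed-channel [detect()] run that
#' fall within channel 1, within channel 2, or across channels (false
#' positives under the mixing design).
#'
#' @param detection A `multiplet_detection` run on [mix_channels()] output.
#' @param channel_map The `channel_map` from [mix_channels()].
#' @return A list with `within_1`, `within_2`, `cross`, `total`.
#' @export
cross_channel_summary <- function(detection, channel_map) {
  ap <- detection$assignment$above_threshold_pairs
  ch <- channel_map$channel
  names(ch) <- channel_map$barcode
  ca <- unname(ch[ap$barcode_a])
  cb <- unname(ch[ap$barcode_b])
  if (anyNA(ca) || anyNA(cb))
    stop("pair barcode missing from channel map")
  tags <- unique(channel_map$channel)
  list(within_1 = sum(ca == tags[1L] & cb == tags[1L]),
       within_2 = sum(ca == tags[2L] & cb == tags[2L]),
       cross = sum(ca != cb),
       total = length(ca))
}

#' Downsample fragment records
#'
#' Retains each fragment record independently with probability `rate`;
#' deterministic for a fixed seed. Used to probe the stability of the
#' overlap statistic as a function of sequencing depth.
#'
#' @param fragments Fragments `data.table`.
#' @param rate Retention probability in (0, 1].
#' @param seed Optional integer seed (caller's RNG state is restored).
#' @return The downsampled fragments `data.table`.
#' @export
downsample_fragments <- function(fragments, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1)
    stop("rate must be in (0, 1]")
  f <- as.data.table(fragments)
  if (rate == 1) return(f)
  keep_row <- with_seed(seed, stats::runif(nrow(f)) < rate)
  f[keep_row]
}
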
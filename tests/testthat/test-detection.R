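test_that("insertion extraction maps fragment ends to one-bp coordinates", {
  one <- data.table(chrom = "chr1", start = 100L, end = 250L,
                    barcode = "AAAA", count = 1L)
  idx <- extract_insertions(one)
  expect_equal(idx$insertions[, .(chrom, pos)],
               data.table(chrom = "chr1", pos = c(100L, 249L)),
               ignore_attr = TRUE)
  expect_equal(idx$counts$n_insertions, 2L)

  # duplicate fragments collapse (set semantics)
  two <- rbind(one, one)
  idx2 <- extract_insertions(two)
  expect_equal(idx2$counts$n_insertions, 2L)
  expect_equal(idx2$insertions[, .(barcode, chrom, pos)],
               idx$insertions[, .(barcode, chrom, pos)])

  # two fragments sharing a start coordinate share one insertion
  ab <- data.table(chrom = "chr1", start = c(100L, 100L),
                   end = c(250L, 300L), barcode = c("AAAA", "CCCC"),
                   count = 1L)
  idxab <- extract_insertions(ab)
  shared <- merge(idxab$insertions[barcode == "AAAA", .(chrom, pos)],
                  idxab$insertions[barcode == "CCCC", .(chrom, pos)])
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$pos, 100L)
})

test_that("pair statistic is the modified Jaccard index over insertion sets", {
  # A = {10,20,30}, B = {20,30,40}: shared 2, score 2/(3+3-2) = 0.5
  frags <- data.table(
    chrom = "chr1",
    start = c(10L, 20L, 20L, 30L),
    end = c(21L, 31L, 31L, 41L),
    barcode = c("AAAA", "AAAA", "CCCC", "CCCC"),
    count = 1L)
  pairs <- pair_overlap_statistic(extract_insertions(frags),
                                  min_insertions = 1L)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$shared, 2L)
  expect_equal(pairs$score, 0.5)

  # identical insertion sets -> score exactly 1
  same <- data.table(chrom = "chr1", start = c(10L, 10L), end = c(21L, 21L),
                     barcode = c("GGGG", "TTTT"), count = 1L)
  expect_equal(pair_overlap_statistic(extract_insertions(same),
                                      min_insertions = 1L)$score, 1)

  # disjoint sets -> pair absent
  disj <- data.table(chrom = "chr1", start = c(10L, 500L),
                     end = c(21L, 511L), barcode = c("GGGG", "TTTT"),
                     count = 1L)
  expect_equal(nrow(pair_overlap_statistic(extract_insertions(disj),
                                           min_insertions = 1L)), 0L)

  expect_error(pair_overlap_statistic(
    extract_insertions(disj[0]), min_insertions = 1L), "empty")
})

test_that("pair statistic matches the brute-force set-intersection oracle", {
  for (seed in c(3L, 17L)) {
    frags <- random_fragment_table(15L, seed = seed)
    got <- pair_overlap_statistic(extract_insertions(frags),
                                  min_insertions = 1L)
    want <- brute_force_pairs(frags)
    expect_equal(nrow(got), nrow(want))
    expect_equal(pair_key(got), pair_key(want))
    expect_equal(got$shared, want$shared)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("scores are bounded in [0,1] and reach 1 only for identical sets", {
  frags <- random_fragment_table(12L, seed = 5L)
  idx <- extract_insertions(frags)
  pairs <- pair_overlap_statistic(idx, min_insertions = 1L)
  expect_true(all(pairs$score > 0 & pairs$score <= 1))
  ones <- pairs[score == 1]
  if (nrow(ones) > 0L) {
    for (r in seq_len(nrow(ones))) {
      sa <- idx$insertions[barcode == ones$barcode_a[r], paste(chrom, pos)]
      sb <- idx$insertions[barcode == ones$barcode_b[r], paste(chrom, pos)]
      expect_setequal(sa, sb)
    }
  }
})

test_that("min_insertions and top_k_per_barcode prune the pair list", {
  frags <- random_fragment_table(10L, frags_per_bc = 10L, seed = 9L)
  idx <- extract_insertions(frags)
  # all barcodes have ~20 insertions; a high floor removes everything
  expect_equal(nrow(pair_overlap_statistic(idx, min_insertions = 1000L)), 0L)
  all_pairs <- pair_overlap_statistic(idx, min_insertions = 1L)
  top1 <- pair_overlap_statistic(idx, min_insertions = 1L,
                                 top_k_per_barcode = 1L)
  expect_true(nrow(top1) <= nrow(all_pairs))
  # every retained pair is some barcode's single strongest partner
  best <- c(tapply(all_pairs$score, all_pairs$barcode_a, max),
            tapply(all_pairs$score, all_pairs$barcode_b, max))
  best <- tapply(best, names(best), max)
  expect_true(all(top1$score == best[top1$barcode_a] |
                  top1$score == best[top1$barcode_b]))
})

test_that("knee call lands between score plateaus and flags kneeless decay", {
  plateau <- c(1, 1, 1, 1, 0.001, 0.0009, 0.0008, 0.0007, 0.0006, 0.0005)
  k <- rank_and_knee(plateau)
  # independent re-derivation: signed distance below the chord in log-log
  x <- log10(seq_along(plateau)); y <- log10(plateau)
  slope <- (y[10] - y[1]) / (x[10] - x[1])
  d <- ((y[1] + slope * (x - x[1])) - y) / sqrt(1 + slope^2)
  d[c(1, 10)] <- 0
  expect_equal(k$rank_at_knee, which.max(d))
  expect_equal(k$rank_at_knee, 5L)
  expect_equal(k$threshold_T, 0.001)
  # all four plateau pairs sit strictly above T
  expect_true(all(plateau[1:4] > k$threshold_T))
  expect_gt(k$kneeness, 0)

  # geometric decay: interior knee, low kneeness quality
  geom <- 0.9^(1:50)
  kg <- rank_and_knee(geom)
  expect_true(kg$rank_at_knee > 1L && kg$rank_at_knee < 50L)
  expect_lt(kg$kneeness, k$kneeness)
  expect_lte(kg$kneeness, 0)

  # explicit threshold bypasses the call
  ko <- rank_and_knee(plateau, threshold = 0.123)
  expect_equal(ko$threshold_T, 0.123)
  expect_equal(ko$method, "user")

  expect_error(rank_and_knee(c(1, 0.5)), "fewer than 3")
})

test_that("grouping merges transitively above T and equals components", {
  p1 <- make_pairs(c("b1", "b1"), c("b2", "b3"), c(0.9, 0.8))
  g1 <- group_multiplets(p1, 0.5)
  expect_equal(unique(g1$groups$group_size), 3L)
  expect_equal(unique(g1$groups$droplet_id), "b1")

  p2 <- make_pairs(c("b1", "b3"), c("b2", "b4"), c(0.9, 0.8))
  g2 <- group_multiplets(p2, 0.5)
  expect_equal(sort(unique(g2$groups$droplet_id)), c("b1", "b3"))
  expect_true(all(g2$groups$group_size == 2L))

  # all scores at or below T -> every barcode a singlet (strict exceedance)
  g3 <- group_multiplets(p2, 0.9, barcodes = c("b1", "b2", "b3", "b4"))
  expect_true(all(g3$groups$group_size == 1L))
  expect_equal(nrow(g3$groups), 4L)
})

test_that("grouping equals igraph connected components on random graphs", {
  for (seed in c(2L, 4L, 8L)) {
    set.seed(seed)
    n <- 30L
    bcs <- random_barcodes(n, 6L)
    m <- 40L
    ij <- cbind(sample(n, m, replace = TRUE), sample(n, m, replace = TRUE))
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    pr <- make_pairs(bcs[ij[, 1]], bcs[ij[, 2]], runif(nrow(ij)))
    pr <- unique(pr, by = c("barcode_a", "barcode_b"))
    thr <- 0.4
    got <- group_multiplets(pr, thr, barcodes = bcs)
    gr <- igraph::graph_from_data_frame(
      pr[score > thr, .(barcode_a, barcode_b)], directed = FALSE,
      vertices = bcs)
    comp <- igraph::components(gr)$membership
    want <- split(names(comp), comp)
    part_got <- split(got$groups$barcode, got$groups$droplet_id)
    expect_setequal(lapply(unname(want), sort),
                    lapply(unname(part_got), sort))
  }
})

test_that("downsampling is a per-record Bernoulli thinning", {
  frags <- random_fragment_table(5L, frags_per_bc = 2000L, seed = 21L)
  expect_equal(downsample_fragments(frags, 1), frags)
  kept <- downsample_fragments(frags, 0.5, seed = 33L)
  # binomial 99% interval for n = 10,000, p = 0.5
  expect_true(abs(nrow(kept) - 5000) < 2.576 * sqrt(10000 * 0.25))
  expect_equal(downsample_fragments(frags, 0.5, seed = 33L), kept)
  expect_error(downsample_fragments(frags, 0), "rate")
  expect_error(downsample_fragments(frags, 1.5), "rate")
})

test_that("detection recovers planted multiplets and none after label shuffle", {
  # doublet-rich loading so the recovery comparison has power
  lib <- simulate_library(synthetic_config(n_cells = 60L,
                                           bead_loading = c(`1` = 0.7,
                                                            `2` = 0.3),
                                           fragments_per_cell = 2000,
                                           seed = 31L))
  det <- detect(lib$fragments, barcodes = lib$barcodes$barcode)
  tp <- lib$truth$multiplet_pairs
  ap <- det$assignment$above_threshold_pairs
  expect_gt(nrow(tp), 0L)
  expect_true(all(pair_key(tp) %in% pair_key(ap)))
  expect_true(all(pair_key(ap) %in% pair_key(tp)))
  expect_equal(det$multiplet_pct,
               100 * nrow(lib$truth$barcodes[class != "singlet"]) /
                 nrow(lib$barcodes))

  # permutation safety: shuffling barcode labels on fragments destroys
  # droplet structure, so planted-pair recovery collapses to chance
  shuffled <- copy(lib$fragments)
  set.seed(77)
  shuffled[, barcode := sample(barcode)]
  det2 <- suppressWarnings(detect(shuffled,
                                  barcodes = lib$barcodes$barcode))
  ap2 <- det2$assignment$above_threshold_pairs
  # recovery collapses from 100% to chance: the fraction of all pairs
  # that happen to sit above the (noise-driven) threshold
  n_bc <- nrow(lib$barcodes)
  chance <- nrow(ap2) / choose(n_bc, 2L)
  recovered <- mean(pair_key(tp) %in% pair_key(ap2))
  expect_lt(recovered, 0.5)
  expect_lt(abs(recovered - chance),
            4 * sqrt(chance * (1 - chance) / nrow(tp)) + 0.02)
})

test_that("zero-overlap libraries yield zero multiplets", {
  # distinct cells with disjoint coordinate ranges
  frags <- data.table(chrom = "chr1",
                      start = c(1:50 * 1000L, 1:50 * 1000L + 500L),
                      barcode = rep(c("AAAA", "CCCC"), each = 50L),
                      count = 1L)
  frags[, end := start + 100L]
  det <- suppressWarnings(detect(frags, barcodes = c("AAAA", "CCCC"),
                                 min_insertions = 1L))
  expect_equal(det$multiplet_pct, 0)
  expect_true(all(det$assignment$groups$group_size == 1L))
})

test_that("mixing tags keep barcodes from both channels distinct", {
  f <- data.table(chrom = "chr1", start = 1L, end = 101L,
                  barcode = "AAAA", count = 1L)
  mx <- mix_channels(f, f)
  expect_setequal(mx$fragments$barcode, c("AAAA-1", "AAAA-2"))
  expect_equal(sort(mx$channel_map$channel), c("1", "2"))
  # channel map partitions the merged whitelist exactly in two
  expect_equal(nrow(mx$channel_map), length(mx$barcodes))
  expect_error(mix_channels(f, f, tag_1 = "x", tag_2 = "x"), "collide")
})
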
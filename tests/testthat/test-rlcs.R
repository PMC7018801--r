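test_that("rLCS counts the longest positional match run without shifting", {
  expect_equal(rlcs("ACGT", "ACGT"), 4L)
  expect_equal(rlcs("ACGT", "TGCA"), 0L)
  # runs of 6 (pos 1-6) and 9 (pos 8-16): the longer wins
  expect_equal(rlcs("ACGTACGTACGTACGT", "ACGTACTTACGTACGT"), 9L)
  # N matches nothing, including another N
  expect_equal(rlcs("NNNN", "NNNN"), 0L)
  expect_equal(rlcs("ANGT", "ANGT"), 2L)
  expect_error(rlcs("ACGT", "ACGTA"), "equal-length")
  # symmetry and identity
  expect_equal(rlcs("ACGTAC", "ATGTAC"), rlcs("ATGTAC", "ACGTAC"))
  s <- random_barcodes(1L, 16L, seed = 2L)
  expect_equal(rlcs(s, s), 16L)
})

test_that("rLCS agrees with the O(L^2) window-scan oracle", {
  set.seed(101)
  a <- random_barcodes(1000L, 16L)
  b <- random_barcodes(1000L, 16L)
  scalar <- mapply(rlcs, a, b, USE.NAMES = FALSE)
  oracle <- mapply(rlcs_window_oracle, a, b, USE.NAMES = FALSE)
  expect_equal(scalar, oracle)
  # hamming-zero iff full-length rLCS
  expect_true(all((scalar == 16L) ==
                  (mapply(function(x, y) identical(x, y), a, b))))
})

test_that("rLCS null sampling reports exceedance probabilities", {
  # two identical barcodes: every draw is the full length
  pool <- rep(random_barcodes(1L, 16L, seed = 4L), 2L)
  null_id <- sample_rlcs_null(100L, barcode_pool = pool, seed = 1L)
  expect_true(all(null_id$values == 16L))
  expect_equal(null_id$exceedance, 1)
  expect_equal(rlcs_exceedance(null_id, 0L), 1)

  # uniform random 16-mers: rLCS >= 6 is rare (< 0.5%)
  null_u <- sample_rlcs_null(200000L, seed = 7L)
  expect_lt(null_u$exceedance, 0.005)
  expect_equal(rlcs_exceedance(null_u, 0L), 1)
  # deterministic under seed
  expect_equal(sample_rlcs_null(1000L, seed = 3L)$values,
               sample_rlcs_null(1000L, seed = 3L)$values)
  expect_error(sample_rlcs_null(0L), "n_draws")
  expect_error(sample_rlcs_null(10L, barcode_pool = "ACGT"), "at least 2")
})

test_that("multiplets classify by mean pairwise rLCS at the threshold", {
  # complex pair: shares a 9-base aligned run
  b1 <- "ACGTACGTACGTACGT"
  b2 <- "TGCAACGTACGTATGC"  # positions 5..13 match ("ACGTACGTA")
  expect_gte(rlcs(b1, b2), 9L)
  # unrelated pair
  b3 <- "GGGGCCCCAAAATTTT"
  b4 <- "CCCCGGGGTTTTAAAA"
  pairs <- make_pairs(c(b1, b3), c(b2, b4), c(0.9, 0.8))
  asg <- group_multiplets(pairs, 0.5)
  ann <- data.table(barcode = c(b1, b2, b3, b4),
                    n_fragments = c(1000L, 500L, 800L, 800L))
  cls <- classify_multiplets(asg, ann)
  expect_equal(cls[droplet_id == min(b1, b2), class], "complex_bead")
  expect_equal(cls[droplet_id == min(b3, b4), class], "bead_multiplet")
  # equal fragment counts -> zero percent difference
  expect_equal(cls[droplet_id == min(b3, b4), mean_log2_pct_diff], 0)

  # 4-barcode multiplet contributes exactly choose(4,2) = 6 pairs
  quad <- random_barcodes(4L, 16L, seed = 11L)
  p4 <- make_pairs(rep(quad[1L], 3L), quad[2:4], c(0.9, 0.8, 0.7))
  asg4 <- group_multiplets(p4, 0.5)
  ann4 <- data.table(barcode = quad, n_fragments = 100L)
  cls4 <- classify_multiplets(asg4, ann4)
  expect_equal(cls4$n_pairs, 6L)

  # invariant to barcode order within the multiplet
  p4b <- make_pairs(rep(quad[4L], 3L), quad[c(2L, 1L, 3L)], c(0.9, 0.8, 0.7))
  cls4b <- classify_multiplets(group_multiplets(p4b, 0.5), ann4)
  expect_equal(cls4$mean_rlcs, cls4b$mean_rlcs)

  expect_error(classify_multiplets(asg4, ann4[1:2]), "missing n_fragments")
})

test_that("complex bead rate follows the collapsed-bead formula", {
  expect_equal(round(complex_bead_rate(4732, 121, 253), 2), 4.95)
  expect_equal(complex_bead_rate(100, 0, 0), 0)
  expect_equal(complex_bead_rate(0, 0, 10), 100)
  # scale invariance
  expect_equal(complex_bead_rate(40, 10, 5), complex_bead_rate(400, 100, 50))
  expect_error(complex_bead_rate(0, 0, 0), "denominator")
  expect_error(complex_bead_rate(-1, 0, 1), "non-negative")
})

test_that("fragment balance KS test separates shifted distributions", {
  # identical per-class distributions: D = 0, p = 1
  cls <- data.table(droplet_id = sprintf("d%02d", 1:8),
                    n_barcodes = 2L, n_pairs = 1L,
                    mean_rlcs = rep(c(9, 2), each = 4L),
                    class = rep(c("complex_bead", "bead_multiplet"),
                                each = 4L),
                    mean_log2_pct_diff = rep(c(5, 10, 15, 20), 2L))
  same <- fragment_balance_test(cls)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # U(0,1) vs U(0.5,1.5): true D = 0.5
  set.seed(12)
  cls2 <- data.table(droplet_id = sprintf("e%03d", 1:400),
                     n_barcodes = 2L, n_pairs = 1L,
                     mean_rlcs = rep(c(9, 2), each = 200L),
                     class = rep(c("complex_bead", "bead_multiplet"),
                                 each = 200L),
                     mean_log2_pct_diff = c(runif(200), runif(200) + 0.5))
  shift <- fragment_balance_test(cls2)
  expect_true(shift$statistic > 0.35 && shift$statistic < 0.65)
  expect_lt(shift$p_value, 1e-6)

  expect_error(fragment_balance_test(cls[class == "complex_bead"]),
               "at least 2")
})

test_that("clonotype screen flags all-high-rLCS clones against a permuted null", {
  set.seed(42)
  # planted: one clone of 5 barcodes sharing a 9-base run
  primary <- random_barcodes(1L, 16L)
  planted <- c(primary, replicate(4L, {
    ch <- strsplit(primary, "")[[1L]]
    mut <- setdiff(1:16, 4:12)
    ch[mut] <- vapply(ch[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    paste(ch, collapse = "")
  }))
  background <- random_barcodes(40L, 16L)
  tbl <- data.table(
    barcode = c(planted, background),
    clonotype_id = c(rep("cPLANT", 5L),
                     rep(sprintf("c%02d", 1:20), each = 2L)))
  scr <- clonotype_rlcs_screen(tbl, n_permutations = 50L, seed = 6L)
  expect_true(scr$summary[clonotype_id == "cPLANT", flagged])
  expect_equal(scr$summary[clonotype_id == "cPLANT", n_pairs], 10L)
  # random 2-barcode clones are not flagged
  expect_true(all(!scr$summary[clonotype_id != "cPLANT", flagged]))

  # exchangeability: with no planting, permuted mean tracks observed mean
  tbl0 <- data.table(barcode = background,
                     clonotype_id = rep(sprintf("c%02d", 1:20), each = 2L))
  scr0 <- clonotype_rlcs_screen(tbl0, n_permutations = 100L, seed = 8L)
  expect_lt(abs(scr0$observed_mean - mean(scr0$permuted_means)), 0.5)
  expect_error(clonotype_rlcs_screen(tbl, n_permutations = 0L),
               "n_permutations")
})
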
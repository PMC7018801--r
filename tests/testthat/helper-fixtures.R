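library(data.table)

# Independent brute-force oracle for the pairwise overlap statistic:
# plain set intersection over per-barcode insertion-coordinate sets.
brute_force_pairs <- function(frags, min_insertions = 1L) {
  frags <- as.data.frame(frags)
  sets <- tapply(seq_len(nrow(frags)), frags$barcode, function(ii) {
    unique(c(paste0(frags$chrom[ii], ":", frags$start[ii]),
             paste0(frags$chrom[ii], ":", frags$end[ii] - 1L)))
  })
  sets <- sets[lengths(sets) >= min_insertions]
  bcs <- sort(names(sets))
  out <- list()
  for (i in seq_along(bcs)) {
    for (j in seq_len(max(0L, i - 1L))) {
      a <- bcs[j]; b <- bcs[i]
      sh <- length(intersect(sets[[a]], sets[[b]]))
      if (sh >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          barcode_a = a, barcode_b = b, shared = sh,
          score = sh / (length(sets[[a]]) + length(sets[[b]]) - sh),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res[order(-res$score, res$barcode_a, res$barcode_b), ]
}

# Independent O(L^2) window-scan oracle for the rLCS.
rlcs_window_oracle <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  L <- length(ca)
  best <- 0L
  for (i in seq_len(L)) {
    for (j in i:L) {
      if (all(ca[i:j] == cb[i:j] & ca[i:j] != "N"))
        best <- max(best, j - i + 1L)
    }
  }
  best
}

# Random fragment table with frequent coordinate collisions, for
# property tests of the pair statistic.
random_fragment_table <- function(n_barcodes, frags_per_bc = 30L,
                                  positions = 400L, seed = 1L) {
  set.seed(seed)
  bcs <- random_barcodes(n_barcodes, 8L)
  n <- n_barcodes * frags_per_bc
  s <- sample.int(positions, n, replace = TRUE)
  data.table(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = s, end = s + sample(50:100, n, replace = TRUE),
             barcode = rep(bcs, each = frags_per_bc), count = 1L)
}

pair_key <- function(d) paste(d$barcode_a, d$barcode_b)

# Small deterministic pair table builder.
make_pairs <- function(a, b, score) {
  data.table(barcode_a = pmin(a, b), barcode_b = pmax(a, b),
             shared = 1L, n_a = 1L, n_b = 1L, score = score)
}

write_temp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
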
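# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed evaluates in the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# sample() treats a scalar first argument as 1:x; this always samples
# from the values of x.
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

is_valid_barcode <- function(x) {
  grepl("^[ACGTN]+$", x)
}

#' Generate random nucleotide barcodes
#'
#' Draws `n` distinct barcodes uniformly over `{A,C,G,T}^length`. Used by the
#' synthetic-data generator and as the whitelist stand-in for the rLCS null.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases (default 16, the 10x Chromium size).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Character vector of `n` distinct barcodes.
#' @export
random_barcodes <- function(n, length = 16L, seed = NULL) {
  stopifnot(n >= 1L, length >= 1L)
  with_seed(seed, {
    draw <- function(k) {
      m <- matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                  nrow = k)
      apply(m, 1L, paste, collapse = "")
    }
    out <- draw(n)
    # regenerate collisions until all distinct (vanishingly rare at L = 16)
    while (anyDuplicated(out)) {
      dup <- which(duplicated(out))
      out[dup] <- draw(length(dup))
    }
    out
  })
}

# Encode barcodes as an integer matrix (A=1, C=2, G=3, T=4, N=0).
# N never matches anything, including another N.
barcode_int_matrix <- function(barcodes) {
  L <- unique(nchar(barcodes))
  if (length(L) != 1L)
    stop("barcodes must share a common length")
  chars <- strsplit(barcodes, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c("A", "C", "G", "T"), nomatch = 0L),
              nrow = length(barcodes), ncol = L, byrow = TRUE)
  m
}

# Longest run of TRUE per row of a logical matrix.
longest_run_by_row <- function(E) {
  n <- nrow(E)
  run <- integer(n)
  best <- integer(n)
  for (j in seq_len(ncol(E))) {
    run <- ifelse(E[, j], run + 1L, 0L)
    best <- pmax(best, run)
  }
  best
}
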
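# Readers and writers for the external formats the pipeline touches:
# fragment files, barcode lists, clonotype tables, multiplet reports.

open_maybe_gz <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, open = mode) else file(path, open = mode)
}

#' Read a droplet fragments file
#'
#' Parses the standard 5-column BED-like fragments format
#' (chrom, start, end, barcode, count), plain or gzip-compressed.
#' Coordinates follow the half-open 0-based BED convention of
#' `fragments.tsv`; no additional Tn5 +4/-5 shift is applied -- fragment
#' files are assumed to have been shifted upstream. Lines starting with
#' `#` are comments. Malformed lines (fewer than five columns, non-integer
#' coordinates, `end <= start`) raise an error rather than being skipped.
#'
#' @param path Path to a fragments file (`.tsv` or `.tsv.gz`).
#' @param barcode_whitelist Optional character vector; records whose barcode
#'   is not in the whitelist are dropped.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`, in file order.
#' @export
read_fragments <- function(path, barcode_whitelist = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(
      con, sep = "\t", comment.char = "#", quote = "",
      col.names = c("chrom", "start", "end", "barcode", "count"),
      colClasses = c("character", "integer", "integer", "character", "integer"),
      stringsAsFactors = FALSE),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("no lines available", msg)) return(NULL)
      stop("malformed fragments file '", path, "': ", msg, call. = FALSE)
    })
  if (is.null(df)) {
    df <- data.table(chrom = character(), start = integer(), end = integer(),
                     barcode = character(), count = integer())
  }
  dt <- as.data.table(df)
  validate_fragments(dt, path)
  if (!is.null(barcode_whitelist)) {
    dt <- dt[barcode %chin% as.character(barcode_whitelist)]
  }
  dt[]
}

validate_fragments <- function(dt, what = "fragments") {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (anyNA(dt$start) || anyNA(dt$end) || anyNA(dt$count))
    stop("non-integer coordinates or counts in ", what)
  if (any(dt$start < 0L)) stop("negative start coordinate in ", what)
  if (any(dt$end <= dt$start)) stop("end <= start in ", what)
  if (any(dt$count < 1L)) stop("non-positive duplicate count in ", what)
  bad <- !is_valid_barcode(dt$barcode)
  if (any(bad))
    stop("invalid barcode (alphabet ACGTN) in ", what, ": ",
         dt$barcode[which(bad)[1L]])
  invisible(dt)
}

#' Write a fragments file
#'
#' Writes the 5-column tab-separated fragments format; a `.gz` suffix
#' triggers gzip compression.
#'
#' @param fragments A `data.table`/data.frame with columns
#'   `chrom,start,end,barcode,count`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  dt <- as.data.table(fragments)[, .(chrom, start, end, barcode, count)]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(dt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a barcode list with optional annotations
#'
#' One barcode per line, optionally followed by tab-separated columns
#' `n_fragments` (the "passed_filter" unique fragment count) and `cluster`.
#' A header line is auto-detected when the first token is not a plain
#' ACGTN string. Duplicate barcodes are an error.
#'
#' @param path Path to a 1-3 column TSV.
#' @return A `data.table` with columns `barcode`, `n_fragments`, `cluster`
#'   (absent annotations are `NA`), in file order.
#' @export
read_barcode_list <- function(path) {
  if (!file.exists(path)) stop("barcode file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty barcode file: ", path)
  first_tok <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1L]
  has_header <- !is_valid_barcode(first_tok)
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) stop("barcode file contains only a header: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  get_col <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[[i]] else NA_character_, character(1L))
  dt <- data.table(
    barcode = get_col(1L),
    n_fragments = suppressWarnings(as.integer(get_col(2L))),
    cluster = get_col(3L)
  )
  if (any(!is_valid_barcode(dt$barcode)))
    stop("invalid barcode in ", path)
  if (anyDuplicated(dt$barcode))
    stop("duplicate barcode in ", path, ": ",
         dt$barcode[which(duplicated(dt$barcode))[1L]])
  dt[]
}

#' Read a clonotype annotation table
#'
#' Reads a CSV mapping cell barcodes to clonotype identifiers (such as the
#' per-barcode contig annotation files emitted by V(D)J pipelines). Column
#' names are configurable. Duplicated (barcode, clonotype) rows are an
#' error; per-clonotype sizes are obtained with [clonotype_sizes()].
#'
#' @param path Path to a CSV file.
#' @param barcode_col,clonotype_col,constant_col Column names holding the
#'   barcode, the clonotype identifier, and (optionally) a constant-region
#'   sequence.
#' @return A `data.table` with columns `barcode`, `clonotype_id`, and
#'   `constant_region` (`NA` when not supplied).
#' @export
read_clonotype_table <- function(path, barcode_col = "barcode",
                                 clonotype_col = "clonotype_id",
                                 constant_col = NULL) {
  if (!file.exists(path)) stop("clonotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(barcode_col, clonotype_col, constant_col)) {
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path)
  }
  dt <- data.table(
    barcode = as.character(df[[barcode_col]]),
    clonotype_id = as.character(df[[clonotype_col]]),
    constant_region = if (is.null(constant_col)) NA_character_
                      else as.character(df[[constant_col]])
  )
  if (anyDuplicated(dt[, .(barcode, clonotype_id)]))
    stop("duplicated (barcode, clonotype) row in ", path)
  dt[]
}

#' Per-clonotype sizes
#'
#' @param clonotypes A clonotype table as returned by
#'   [read_clonotype_table()] (or any table with `clonotype_id`).
#' @return A `data.table` with columns `clonotype_id`, `n_barcodes`.
#' @export
clonotype_sizes <- function(clonotypes) {
  dt <- as.data.table(clonotypes)
  dt[, .(n_barcodes = .N), by = clonotype_id][order(clonotype_id)]
}

#' Write a per-barcode multiplet report
#'
#' One row per barcode: `barcode`, `droplet_id` (the lexicographically
#' smallest member barcode of its group), `group_size`, `group_class`
#' (`singlet`, `bead_multiplet`, or `complex_bead`; `NA` when multiplets
#' have not been classified), and `mean_rlcs` (`NA` for singlets).
#'
#' @param assignment A `multiplet_assignment` from [group_multiplets()] or
#'   `detect()$assignment`.
#' @param path Output TSV path.
#' @param classes Optional classification table from
#'   [classify_multiplets()], used to fill `group_class` and `mean_rlcs`.
#' @return The path, invisibly.
#' @seealso [read_multiplet_report()]
#' @export
write_multiplet_report <- function(assignment, path, classes = NULL) {
  stopifnot(inherits(assignment, "multiplet_assignment"))
  rep_dt <- copy(assignment$groups)
  rep_dt[, group_class := ifelse(group_size == 1L, "singlet", NA_character_)]
  rep_dt[, mean_rlcs := NA_real_]
  if (!is.null(classes)) {
    cl <- as.data.table(classes)
    idx <- match(rep_dt$droplet_id, cl$droplet_id)
    hit <- !is.na(idx) & rep_dt$group_size > 1L
    rep_dt[hit, group_class := cl$class[idx[hit]]]
    rep_dt[hit, mean_rlcs := cl$mean_rlcs[idx[hit]]]
  }
  setorder(rep_dt, droplet_id, barcode)
  utils::write.table(rep_dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a multiplet report written by [write_multiplet_report()]
#'
#' @param path Path to the report TSV.
#' @return A `data.table` with one row per barcode.
#' @export
read_multiplet_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  dt <- as.data.table(utils::read.table(
    path, sep = "\t", header = TRUE, quote = "",
    colClasses = c(barcode = "character", droplet_id = "character",
                   group_size = "integer", group_class = "character",
                   mean_rlcs = "numeric"),
    stringsAsFactors = FALSE))
  dt[]
}
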
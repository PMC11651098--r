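#' Construct a genus x microcosm abundance table
#'
#' The canonical container used throughout the package is a tibble whose first
#' column is `genus` (unique character ids) and whose remaining columns are
#' non-negative counts, one column per microcosm. The growth-cycle id travels
#' in the `cycle` attribute.
#'
#' @param counts A numeric matrix (genera in rows, microcosms in columns) or a
#'   data frame already holding a `genus` column.
#' @param genus Character vector of genus ids (ignored when `counts` already
#'   carries them as rownames or a `genus` column).
#' @param microcosms Optional character vector of microcosm ids.
#' @param cycle Optional cycle id (integer) stored as an attribute.
#'
#' @return A tibble with columns `genus` and one count column per microcosm.
#' @export
#' @examples
#' abundance_table(matrix(c(5, 3, 0, 2), 2, 2,
#'   dimnames = list(c("gA", "gB"), c("m1", "m2"))), cycle = 0)
abundance_table <- function(counts, genus = NULL, microcosms = NULL, cycle = NULL) {
  if (is.data.frame(counts)) {
    tbl <- tibble::as_tibble(counts)
    if (!"genus" %in% names(tbl)) {
      if (is.null(genus)) stop("`counts` has no `genus` column and `genus` is NULL", call. = FALSE)
      tbl <- dplyr::bind_cols(tibble::tibble(genus = as.character(genus)), tbl)
    }
    tbl <- dplyr::relocate(tbl, "genus")
  } else {
    counts <- as.matrix(counts)
    if (is.null(genus)) genus <- rownames(counts)
    if (is.null(genus)) genus <- sprintf("g%03d", seq_len(nrow(counts)))
    if (is.null(microcosms)) microcosms <- colnames(counts)
    if (is.null(microcosms)) microcosms <- sprintf("m%02d", seq_len(ncol(counts)))
    dimnames(counts) <- list(NULL, microcosms)
    tbl <- dplyr::bind_cols(tibble::tibble(genus = as.character(genus)),
                            tibble::as_tibble(counts))
  }
  if (!is.null(cycle)) attr(tbl, "cycle") <- as.integer(cycle)
  validate_abundance_table(tbl)
  tbl
}

#' Validate an abundance table
#'
#' Checks the invariants every abundance table must satisfy: a unique `genus`
#' id column, unique microcosm column names, and non-negative, finite counts.
#' (Whole-number counts are additionally enforced when parsing TSV input in
#' [read_abundance_table()].)
#'
#' @param table A tibble as produced by [abundance_table()].
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending cell or id.
#' @export
validate_abundance_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"genus" %in% names(table)) stop("abundance table needs a `genus` column", call. = FALSE)
  if (ncol(table) < 2L) stop("abundance table has no microcosm columns", call. = FALSE)
  if (nrow(table) == 0L) stop("no genera: abundance table is empty", call. = FALSE)
  if (anyDuplicated(table$genus)) {
    stop("duplicate genus ids: ", paste(unique(table$genus[duplicated(table$genus)]), collapse = ", "),
         call. = FALSE)
  }
  mids <- setdiff(names(table), "genus")
  if (anyDuplicated(mids)) stop("duplicate microcosm ids", call. = FALSE)
  m <- as.matrix(table[mids])
  if (!is.numeric(m)) stop("counts must be numeric", call. = FALSE)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at genus '%s', microcosm '%s': %s",
                 table$genus[bad[1, 1]], mids[bad[1, 2]], format(m[bad[1, , drop = FALSE]])),
         call. = FALSE)
  }
  invisible(table)
}

#' Extract the count matrix from an abundance table
#'
#' @param table An abundance table.
#' @return Numeric matrix with genus rownames and microcosm colnames.
#' @export
count_matrix <- function(table) {
  validate_abundance_table(table)
  mids <- setdiff(names(table), "genus")
  m <- as.matrix(table[mids])
  rownames(m) <- table$genus
  m
}

#' Relative abundances per microcosm
#'
#' Divides each microcosm column by its total. All-zero microcosms yield zero
#' columns (with a warning) rather than NaN.
#'
#' @param table An abundance table.
#' @return A tibble of the same shape with columns summing to 1 (or 0).
#' @export
relative_abundance <- function(table) {
  m <- count_matrix(table)
  tot <- colSums(m)
  if (any(tot == 0)) warning("all-zero microcosm(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  tot[tot == 0] <- 1
  out <- sweep(m, 2, tot, "/")
  res <- dplyr::bind_cols(tibble::tibble(genus = table$genus), tibble::as_tibble(out))
  attr(res, "cycle") <- attr(table, "cycle")
  res
}

#' Pivot an abundance table to long format
#'
#' @param table An abundance table.
#' @return A tibble with columns `genus`, `microcosm`, `count`.
#' @export
abundance_long <- function(table) {
  validate_abundance_table(table)
  tidyr::pivot_longer(table, -"genus", names_to = "microcosm", values_to = "count")
}

#' Read an abundance table from TSV
#'
#' The canonical dialect is UTF-8 tab-separated text with a header row whose
#' first field is `genus`, followed by microcosm ids; counts are integers.
#' [write_abundance_table()] round-trips this dialect byte-identically.
#'
#' @param path Path to a TSV file.
#' @return An abundance table tibble.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"genus" %in% names(raw)) stop("header must start with `genus`", call. = FALSE)
  mids <- setdiff(names(raw), "genus")
  if (length(mids) == 0L) stop("no microcosm columns in ", path, call. = FALSE)
  if (nrow(raw) == 0L) stop("no genera: ", path, " holds a header only", call. = FALSE)
  counts <- suppressWarnings(vapply(raw[mids], as.numeric, numeric(nrow(raw))))
  counts <- matrix(counts, nrow = nrow(raw), dimnames = list(NULL, mids))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("parse error in %s: row %d (genus '%s'), column '%s' is not a non-negative integer",
                 path, bad[1, 1], raw$genus[bad[1, 1]], mids[bad[1, 2]]), call. = FALSE)
  }
  abundance_table(counts, genus = raw$genus, microcosms = mids)
}

#' Write an abundance table as TSV
#'
#' @param table An abundance table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  validate_abundance_table(table)
  out <- table
  mids <- setdiff(names(out), "genus")
  out[mids] <- lapply(out[mids], function(x) format(round(x), scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
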
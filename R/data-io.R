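#' Read a genus-level relative-abundance table from TSV
#'
#' The table is samples x genera: a header row of `g__`-prefixed genus
#' names and a first column of sample IDs. The transposed orientation
#' (genera in rows) is auto-detected via the `g__` prefix and flipped.
#' Rows are renormalised to sum to one, with a notice when any row
#' deviates by more than `1e-6` (integer count tables are accepted this
#' way and converted to relative abundance).
#'
#' @param path Path to a UTF-8, tab-delimited file with `.` decimals.
#' @return A tibble with a `sample_id` column followed by genus columns.
#' @export
read_abundance <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  first <- names(tbl)[1]
  if (!any(is_genus_name(names(tbl)[-1])) && any(is_genus_name(as.character(tbl[[first]])))) {
    # genera in rows: transpose to samples x genera
    m <- as.matrix(tbl[-1])
    rownames(m) <- tbl[[first]]
    m <- t(m)
    tbl <- matrix_to_tbl(m)
  } else {
    names(tbl)[1] <- "sample_id"
    tbl$sample_id <- as.character(tbl$sample_id)
  }
  validate_abundance(tbl)
}

#' Write an abundance table to TSV
#'
#' @param table Abundance tibble (`sample_id` + genus columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-sample host metadata
#'
#' Expected columns: `sample_id`, `subject_id`, `stage` (before/after),
#' `gender` (Male/Female), `age` (years), `bmi` (kg/m^2), `probiotics`
#' (yes/no), `health_status`, `batch`, `region`, `selenium_before`,
#' `selenium_after` (hair selenium content, e.g. ug/g).
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tbl)) names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) abort("duplicated sample IDs in metadata")
  tbl
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read / write a square sample-by-sample distance matrix
#'
#' The matrix must be symmetric (within 1e-12) with a zero diagonal; it
#' is treated as a dissimilarity, so the triangle inequality is not
#' required. This is the entry point for precomputed distances (for
#' example a phylogeny-aware distance produced elsewhere) to be used in
#' place of the built-in Bray-Curtis.
#'
#' @param path Path to a square TSV with sample IDs as both header and
#'   first column.
#' @return A `dist` object with sample labels.
#' @export
read_distance <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[-1])
  rownames(m) <- as.character(tbl[[1]])
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix must be symmetric within 1e-12")
  if (any(diag(m) != 0)) abort("distance matrix diagonal must be zero")
  if (any(m < 0)) abort("distances must be non-negative")
  stats::as.dist(m)
}

#' @rdname read_distance
#' @param dist A `dist` object or square matrix.
#' @export
write_distance <- function(dist, path) {
  m <- as.matrix(dist)
  readr::write_tsv(matrix_to_tbl(m), path, progress = FALSE)
  invisible(path)
}

#' Align an abundance table with its metadata
#'
#' Keeps the samples present in both tables, in a common order
#' (abundance-table order), dropping the rest with a logged count.
#'
#' @param table Abundance tibble.
#' @param meta Metadata tibble.
#' @return A list with elements `abundance` and `metadata`, row-aligned.
#' @export
align_samples <- function(table, meta) {
  shared <- intersect(table$sample_id, meta$sample_id)
  if (length(shared) == 0) abort("no shared sample IDs between abundance and metadata")
  dropped <- (nrow(table) - length(shared)) + (nrow(meta) - length(shared))
  if (dropped > 0) {
    inform(sprintf("align_samples: dropped %d sample(s) missing from one side; %d kept",
                   dropped, length(shared)))
  }
  keep <- table$sample_id[table$sample_id %in% shared]
  list(
    abundance = table[match(keep, table$sample_id), ],
    metadata  = meta[match(keep, meta$sample_id), ]
  )
}

#' Put several abundance tables on a common genus set
#'
#' `union` mode zero-fills genera absent from a table; `intersection`
#' mode keeps only genera observed (nonzero in at least one sample) in
#' every table. The common genus order is lexicographic. Values are not
#' renormalised, so intersection output is a feature view of the
#' original compositions rather than a new composition.
#'
#' @param tables A list of two or more abundance tibbles.
#' @param mode `"union"` or `"intersection"`.
#' @return A list of abundance tibbles on the common genus set.
#' @export
harmonize_features <- function(tables, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(tables) < 2) abort("harmonize_features needs at least two tables")
  observed <- lapply(tables, function(t) {
    g <- genus_columns(t)
    g[colSums(t[g]) > 0]
  })
  common <- if (mode == "union") {
    sort(unique(unlist(lapply(tables, genus_columns))))
  } else {
    sort(Reduce(intersect, observed))
  }
  if (length(common) == 0) abort("no genus shared by every table: intersection is empty")
  lapply(tables, function(t) {
    m <- feature_matrix(t[c("sample_id", genus_columns(t))])
    out <- matrix(0, nrow(m), length(common), dimnames = list(rownames(m), common))
    have <- intersect(colnames(m), common)
    out[, have] <- m[, have, drop = FALSE]
    matrix_to_tbl(out)
  })
}
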
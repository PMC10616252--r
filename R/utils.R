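#' @importFrom rlang abort warn inform .data
#' @importFrom stats rnorm runif rbinom rlnorm predict quantile median sd cor
#' @importFrom utils head modifyList
NULL

# Column prefix marking a genus-level feature.
GENUS_PREFIX <- "g__"

is_genus_name <- function(x) startsWith(x, GENUS_PREFIX)

#' Extract the genus columns of an abundance (or feature) tibble
#'
#' @param tbl A tibble with a `sample_id` column and `g__`-prefixed
#'   genus columns.
#' @return Character vector of genus column names, in table order.
#' @export
genus_columns <- function(tbl) {
  names(tbl)[is_genus_name(names(tbl))]
}

# Convert a sample_id + feature-column tibble to a numeric matrix with
# sample_id as rownames. Used at the boundary to vegan / xgboost.
feature_matrix <- function(tbl) {
  stopifnot("sample_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  rownames(m) <- tbl$sample_id
  m
}

matrix_to_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id", .name_repair = "check_unique")
}

# Validate and renormalise an abundance tibble: non-negative values,
# unique sample ids, rows summing to one (renormalised with a notice
# when any row deviates by more than `tol`).
validate_abundance <- function(tbl, tol = 1e-6, renormalize = TRUE) {
  if (!"sample_id" %in% names(tbl)) abort("abundance table needs a 'sample_id' column")
  if (anyDuplicated(tbl$sample_id)) {
    dup <- unique(tbl$sample_id[duplicated(tbl$sample_id)])
    abort(paste0("duplicated sample IDs: ", paste(head(dup, 5), collapse = ", ")))
  }
  m <- feature_matrix(tbl)
  if (any(m < 0)) abort("negative abundance values are not allowed")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("all-zero abundance rows cannot be renormalized")
  if (renormalize && any(abs(rs - 1) > tol)) {
    n_bad <- sum(abs(rs - 1) > tol)
    inform(sprintf("renormalized %d row(s) whose sum deviated from 1 by > %g", n_bad, tol))
    m <- m / rs
    tbl <- matrix_to_tbl(m)
  }
  tbl
}

# L2-normalise matrix rows to unit norm; all-zero rows are left as-is
# and their ids returned in the "zero_rows" attribute.
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- m / nrm
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

# Coerce LE/HE labels (factor/character) to the canonical factor with
# LE as the reference level and HE as the positive class.
as_efficiency <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("LE", "HE"))
  if (length(bad)) abort(paste0("labels must be 'LE' or 'HE', found: ", paste(bad, collapse = ", ")))
  factor(y, levels = c("LE", "HE"))
}
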
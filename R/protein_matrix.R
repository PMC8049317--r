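#' Protein quantitation matrix with an explicit missingness mask
#'
#' `protein_matrix()` builds the container every other function in the
#' package consumes: a samples x proteins grid of log-scale intensities
#' together with a logical mask marking missing cells. Masked cells carry
#' `NA` in the value grid; every unmasked cell must be finite.
#'
#' @param values Numeric matrix, samples in rows and proteins in columns.
#'   `NA`/`NaN` cells are taken as missing.
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to `rownames(values)`.
#' @param protein_ids Character vector of unique protein identifiers.
#'   Defaults to `colnames(values)`.
#' @return An object of class `ProteinMatrix`: a list with elements
#'   `values` (numeric matrix with `NA` at masked cells), `mask` (logical
#'   matrix, `TRUE` where missing), `sample_ids` and `protein_ids`.
#' @examples
#' m <- protein_matrix(matrix(c(14, NA, 15, 16), 2, 2,
#'                            dimnames = list(c("s1", "s2"), c("pA", "pB"))))
#' n_missing(m)
#' @export
protein_matrix <- function(values, sample_ids = rownames(values),
                           protein_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x proteins)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(protein_ids)) protein_ids <- paste0("protein_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  protein_ids <- as.character(protein_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(protein_ids) != ncol(values)) {
    stop("length(protein_ids) must equal ncol(values)", call. = FALSE)
  }
  check_unique_ids(sample_ids, "sample")
  check_unique_ids(protein_ids, "protein")
  mask <- !is.finite(values)
  values[mask] <- NA_real_
  dimnames(values) <- list(sample_ids, protein_ids)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask,
         sample_ids = sample_ids, protein_ids = protein_ids),
    class = "ProteinMatrix"
  )
}

check_unique_ids <- function(ids, axis) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifiers: %s", axis,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.ProteinMatrix <- function(x, ...) {
  cat(sprintf("ProteinMatrix: %d samples x %d proteins\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing cells: %d of %d (%.1f%%)\n",
              n_missing(x), length(x$values),
              100 * n_missing(x) / length(x$values)))
  invisible(x)
}

#' Number of masked cells in a ProteinMatrix
#' @param m A `ProteinMatrix`.
#' @return Integer count of masked cells.
#' @export
n_missing <- function(m) {
  stopifnot(is_protein_matrix(m))
  sum(m$mask)
}

#' Test for the ProteinMatrix class
#' @param x Any object.
#' @return `TRUE` if `x` is a `ProteinMatrix`.
#' @export
is_protein_matrix <- function(x) inherits(x, "ProteinMatrix")

#' Validate the internal invariants of a ProteinMatrix
#'
#' Checks the dimension/id agreement and the mask-value correspondence
#' (masked cells are `NA`, unmasked cells finite). Called internally before
#' any non-trivial computation.
#'
#' @param m A `ProteinMatrix`.
#' @return `m`, invisibly; errors if any invariant is violated.
#' @export
validate_protein_matrix <- function(m) {
  if (!is_protein_matrix(m)) stop("not a ProteinMatrix", call. = FALSE)
  stopifnot(
    is.matrix(m$values), is.logical(m$mask),
    identical(dim(m$values), dim(m$mask)),
    nrow(m$values) == length(m$sample_ids),
    ncol(m$values) == length(m$protein_ids)
  )
  check_unique_ids(m$sample_ids, "sample")
  check_unique_ids(m$protein_ids, "protein")
  if (any(m$mask & !is.na(m$values))) {
    stop("masked cells must hold NA values", call. = FALSE)
  }
  if (any(!m$mask & !is.finite(m$values))) {
    stop("unmasked cells must be finite", call. = FALSE)
  }
  invisible(m)
}

#' Per-protein and per-sample missing fractions
#'
#' Convenience accessors used throughout thresholding and profiling.
#'
#' @param m A `ProteinMatrix`.
#' @return Named numeric vector of missing fractions in `[0, 1]`.
#' @export
protein_missing_fraction <- function(m) {
  validate_protein_matrix(m)
  colMeans(m$mask)
}

#' @rdname protein_missing_fraction
#' @export
sample_missing_fraction <- function(m) {
  validate_protein_matrix(m)
  rowMeans(m$mask)
}

#' Subset a ProteinMatrix by sample or protein identifiers
#'
#' @param m A `ProteinMatrix`.
#' @param samples,proteins Character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps the axis unchanged.
#' @return A `ProteinMatrix` restricted to the requested ids.
#' @export
subset_matrix <- function(m, samples = NULL, proteins = NULL) {
  validate_protein_matrix(m)
  if (is.null(samples)) samples <- m$sample_ids
  if (is.null(proteins)) proteins <- m$protein_ids
  missing_s <- setdiff(samples, m$sample_ids)
  missing_p <- setdiff(proteins, m$protein_ids)
  if (length(missing_s) || length(missing_p)) {
    stop(sprintf("unknown identifiers: %s",
                 paste(c(missing_s, missing_p), collapse = ", ")), call. = FALSE)
  }
  protein_matrix(m$values[samples, proteins, drop = FALSE],
                 sample_ids = samples, protein_ids = proteins)
}

#' Equality of two ProteinMatrix objects
#'
#' Exact comparison of ids, mask and values (bitwise on the doubles); used
#' by round-trip and determinism checks.
#'
#' @param a,b `ProteinMatrix` objects.
#' @return `TRUE` or `FALSE`.
#' @export
matrices_identical <- function(a, b) {
  identical(a$sample_ids, b$sample_ids) &&
    identical(a$protein_ids, b$protein_ids) &&
    identical(a$mask, b$mask) &&
    isTRUE(all.equal(a$values, b$values, tolerance = 0, check.attributes = FALSE)) &&
    identical(is.na(a$values), is.na(b$values))
}
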
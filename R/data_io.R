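#' Read a protein quantitation matrix from delimited text
#'
#' Accepts the two layouts seen in practice for protein-level DIA/SWATH
#' output: a wide grid (one axis of identifiers per margin) in either
#' orientation, and a tidy long table with columns `sample_id`,
#' `protein_id`, `value`. Values are taken as already log-transformed;
#' no transformation is applied on load (set `log2 = TRUE` for raw-scale
#' input).
#'
#' @param path Path to a delimited text file.
#' @param orientation For wide files: `"samples_in_rows"`,
#'   `"proteins_in_rows"`, or `"auto"`. Auto-detection treats the longer
#'   axis as proteins (there are usually far more proteins than samples)
#'   and reports the choice with a message.
#' @param delimiter Field delimiter, default tab.
#' @param na_tokens Character vector of cell contents treated as missing.
#'   The accepted encodings are a package choice (the field has no
#'   standard); override to match your upstream tool.
#' @param layout `"wide"`, `"long"`, or `"auto"` (long is recognised by its
#'   three-column header).
#' @param log2 If `TRUE`, apply `log2` to observed values on load.
#' @return A [protein_matrix()].
#' @export
load_matrix <- function(path,
                        orientation = c("auto", "samples_in_rows", "proteins_in_rows"),
                        delimiter = "\t",
                        na_tokens = c("", "NA", "NaN", "null"),
                        layout = c("auto", "wide", "long"),
                        log2 = FALSE) {
  orientation <- match.arg(orientation)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (!length(lines)) stop("empty file", call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  n_fields <- lengths(fields)
  # trailing empty cells are dropped by strsplit; pad to the header width
  width <- n_fields[1]
  short <- which(n_fields < width)
  for (i in short) fields[[i]] <- c(fields[[i]], rep("", width - n_fields[[i]]))
  if (any(lengths(fields) != width)) {
    stop(sprintf("ragged rows: line(s) %s have a different field count than the header",
                 paste(which(lengths(fields) != width), collapse = ", ")), call. = FALSE)
  }

  header <- fields[[1]]
  if (layout == "auto") {
    layout <- if (width == 3 &&
                  identical(tolower(header), c("sample_id", "protein_id", "value")))
      "long" else "wide"
  }

  m <- if (layout == "long") {
    parse_long(fields, na_tokens)
  } else {
    parse_wide(fields, orientation, na_tokens)
  }
  if (log2) {
    v <- m$values
    if (any(v[!m$mask] <= 0)) {
      stop("log2 requested but non-positive values present", call. = FALSE)
    }
    v <- base::log2(v)
    m <- protein_matrix(v, m$sample_ids, m$protein_ids)
  }
  validate_protein_matrix(m)
}

parse_cells <- function(cells, na_tokens, where) {
  miss <- cells %in% na_tokens
  out <- rep(NA_real_, length(cells))
  vals <- suppressWarnings(as.numeric(cells[!miss]))
  bad <- which(!miss)[is.na(vals)]
  if (length(bad)) {
    stop(sprintf("non-numeric cell(s) at %s: %s",
                 paste(where[bad], collapse = ", "),
                 paste(sprintf("'%s'", cells[bad[seq_len(min(5, length(bad)))]]),
                       collapse = ", ")), call. = FALSE)
  }
  out[!miss] <- vals
  out
}

parse_wide <- function(fields, orientation, na_tokens) {
  header <- fields[[1]]
  col_ids <- header[-1]
  if (length(fields) < 2 || length(col_ids) < 1) {
    stop("wide file needs at least one data row and one data column", call. = FALSE)
  }
  body <- fields[-1]
  row_ids <- vapply(body, `[[`, character(1), 1)
  grid <- matrix(NA_real_, length(row_ids), length(col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    where <- sprintf("row '%s' column '%s'", row_ids[i], col_ids)
    grid[i, ] <- parse_cells(cells, na_tokens, where)
  }
  check_unique_ids(row_ids, "row")
  check_unique_ids(col_ids, "column")
  if (orientation == "auto") {
    orientation <- if (length(col_ids) >= length(row_ids))
      "samples_in_rows" else "proteins_in_rows"
    message(sprintf("orientation auto-detected as %s (%d rows x %d columns)",
                    orientation, length(row_ids), length(col_ids)))
  }
  if (orientation == "proteins_in_rows") {
    grid <- t(grid)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  protein_matrix(grid, sample_ids = row_ids, protein_ids = col_ids)
}

parse_long <- function(fields, na_tokens) {
  body <- fields[-1]
  if (!length(body)) stop("long file has no data rows", call. = FALSE)
  s_id <- vapply(body, `[[`, character(1), 1)
  p_id <- vapply(body, `[[`, character(1), 2)
  cells <- vapply(body, `[[`, character(1), 3)
  key <- paste(s_id, p_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop(sprintf("duplicate (sample, protein) pairs in long file: %s",
                 paste(gsub("\r", "/", dup[seq_len(min(5, length(dup)))]),
                       collapse = ", ")), call. = FALSE)
  }
  vals <- parse_cells(cells, na_tokens,
                      sprintf("sample '%s' protein '%s'", s_id, p_id))
  samples <- unique(s_id)
  proteins <- unique(p_id)
  grid <- matrix(NA_real_, length(samples), length(proteins),
                 dimnames = list(samples, proteins))
  grid[cbind(match(s_id, samples), match(p_id, proteins))] <- vals
  protein_matrix(grid, sample_ids = samples, protein_ids = proteins)
}

#' Write a ProteinMatrix to delimited text
#'
#' Masked cells are written as the first element of `na_tokens`. Numbers
#' are printed with 17 significant digits so that
#' `load_matrix(write_matrix(m))` reproduces `m` to full double precision.
#'
#' @param m A [protein_matrix()].
#' @param path Output file path.
#' @param orientation `"samples_in_rows"` (default) or `"proteins_in_rows"`.
#' @param delimiter Field delimiter, default tab.
#' @param na_tokens Missing-cell encodings; the first is used on write.
#' @param layout `"wide"` or `"long"` (tidy sample_id/protein_id/value).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path,
                         orientation = c("samples_in_rows", "proteins_in_rows"),
                         delimiter = "\t",
                         na_tokens = c("", "NA", "NaN", "null"),
                         layout = c("wide", "long")) {
  orientation <- match.arg(orientation)
  layout <- match.arg(layout)
  validate_protein_matrix(m)
  na_token <- na_tokens[1]
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- na_token
    out
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  if (layout == "long") {
    writeLines(paste(c("sample_id", "protein_id", "value"), collapse = delimiter), con)
    for (i in seq_along(m$sample_ids)) {
      writeLines(paste(m$sample_ids[i], m$protein_ids, fmt(m$values[i, ]),
                       sep = delimiter), con)
    }
  } else {
    v <- m$values
    row_ids <- m$sample_ids; col_ids <- m$protein_ids
    if (orientation == "proteins_in_rows") {
      v <- t(v); row_ids <- m$protein_ids; col_ids <- m$sample_ids
    }
    writeLines(paste(c("id", col_ids), collapse = delimiter), con)
    for (i in seq_along(row_ids)) {
      writeLines(paste(c(row_ids[i], fmt(v[i, ])), collapse = delimiter), con)
    }
  }
  invisible(path)
}
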
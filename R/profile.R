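#' Profile the missingness structure of a protein matrix
#'
#' Computes the explorative statistics shown on a missingness dashboard:
#' per-sample and per-protein missing counts and fractions, the overall
#' missing fraction, the number of complete proteins, the per-sample
#' fraction range, and histogram bins of the missing counts along both
#' axes (samples: how many proteins are absent per sample; proteins: in
#' how many samples each protein is absent).
#'
#' @param m A [protein_matrix()].
#' @param n_bins Number of equal-width histogram bins over `[0, max count]`
#'   for each axis. Default 30.
#' @return A `MissingnessProfile`: list with `per_sample_count`,
#'   `per_sample_fraction`, `per_protein_count`, `per_protein_fraction`
#'   (all named), `overall_fraction`, `n_complete_proteins`,
#'   `sample_fraction_range`, and `sample_hist`/`protein_hist`
#'   (each a list with `breaks` and `counts`).
#' @examples
#' m <- protein_matrix(matrix(c(14, NA, 15, 16), 2, 2))
#' profile_missingness(m)$overall_fraction  # 0.25
#' @export
profile_missingness <- function(m, n_bins = 30) {
  validate_protein_matrix(m)
  if (length(m$values) == 0) stop("empty matrix", call. = FALSE)
  stopifnot(n_bins >= 1)
  s_count <- rowSums(m$mask)
  p_count <- colSums(m$mask)
  prof <- list(
    per_sample_count = s_count,
    per_sample_fraction = s_count / ncol(m$values),
    per_protein_count = p_count,
    per_protein_fraction = p_count / nrow(m$values),
    overall_fraction = sum(m$mask) / length(m$mask),
    n_complete_proteins = sum(p_count == 0),
    sample_fraction_range = range(s_count / ncol(m$values)),
    sample_hist = count_hist(s_count, n_bins),
    protein_hist = count_hist(p_count, n_bins)
  )
  structure(prof, class = "MissingnessProfile")
}

# equal-width binning of non-negative integer counts over [0, max]
count_hist <- function(counts, n_bins) {
  mx <- max(counts)
  if (mx == 0) {
    return(list(breaks = c(0, 1), counts = length(counts)))
  }
  width <- mx / n_bins
  idx <- pmin(floor(counts / width), n_bins - 1) + 1
  list(breaks = seq(0, mx, length.out = n_bins + 1),
       counts = tabulate(idx, nbins = n_bins))
}

#' @export
print.MissingnessProfile <- function(x, ...) {
  cat("MissingnessProfile\n")
  cat(sprintf("  overall missing:     %.4f (%.1f%%)\n",
              x$overall_fraction, 100 * x$overall_fraction))
  cat(sprintf("  per-sample range:    %.4f - %.4f\n",
              x$sample_fraction_range[1], x$sample_fraction_range[2]))
  cat(sprintf("  complete proteins:   %d of %d\n",
              x$n_complete_proteins, length(x$per_protein_fraction)))
  invisible(x)
}

#' Write a MissingnessProfile to JSON and CSV
#'
#' The JSON file holds every scalar and vector at full precision; the two
#' CSV tables give the per-sample and per-protein counts and fractions.
#'
#' @param profile A `MissingnessProfile`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"profile"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_profile <- function(profile, dir, prefix = "profile") {
  stopifnot(inherits(profile, "MissingnessProfile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(unclass(profile), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  s_path <- file.path(dir, paste0(prefix, "_per_sample.csv"))
  utils::write.csv(data.frame(sample_id = names(profile$per_sample_count),
                              n_missing = profile$per_sample_count,
                              fraction = profile$per_sample_fraction,
                              row.names = NULL),
                   s_path, row.names = FALSE)
  p_path <- file.path(dir, paste0(prefix, "_per_protein.csv"))
  utils::write.csv(data.frame(protein_id = names(profile$per_protein_count),
                              n_missing = profile$per_protein_count,
                              fraction = profile$per_protein_fraction,
                              row.names = NULL),
                   p_path, row.names = FALSE)
  invisible(c(json_path, s_path, p_path))
}

#' Plot the two explorative missingness histograms
#'
#' Protein-level histogram (number of samples in which each protein is
#' missing) on top, sample-level histogram below, mirroring the usual
#' dashboard layout.
#'
#' @param profile A `MissingnessProfile`.
#' @param path Optional PNG path; if `NULL`, draws on the active device.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_profile <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "MissingnessProfile"))
  draw <- function() {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    bar_hist(profile$protein_hist, "Missing values per protein",
             "samples missing", "steelblue")
    bar_hist(profile$sample_hist, "Missing values per sample",
             "proteins missing", "firebrick")
  }
  render_png(draw, path, width = 700, height = 700)
}

bar_hist <- function(h, main, xlab, col) {
  mids <- (utils::head(h$breaks, -1) + utils::tail(h$breaks, -1)) / 2
  graphics::barplot(h$counts, names.arg = signif(mids, 3), main = main,
                    xlab = xlab, ylab = "frequency", col = col, border = NA,
                    las = 2, cex.names = 0.6)
}

# draw onto a PNG if a path is given and a bitmap device exists; fall back
# to no-op with a message on devices-free systems
render_png <- function(draw, path, width = 700, height = 500) {
  if (is.null(path)) {
    draw()
    return(invisible(NULL))
  }
  opened <- tryCatch({
    grDevices::png(path, width = width, height = height, type = "cairo")
    TRUE
  }, error = function(e) {
    tryCatch({
      grDevices::png(path, width = width, height = height)
      TRUE
    }, error = function(e2) FALSE)
  })
  if (!opened) {
    message("no PNG device available; skipping plot ", path)
    return(invisible(NULL))
  }
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}
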
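#' Filter proteins by a missingness threshold
#'
#' Keeps exactly the proteins whose missing-value fraction is strictly
#' below `tau` (a threshold of 0.8 keeps proteins with less than 80%
#' missing values). Consequently `tau = 0` keeps no protein, and a fully
#' missing protein is dropped even at `tau = 1`. The sample axis is
#' unchanged. An empty result is legal here; downstream consumers reject
#' it explicitly.
#'
#' @param m A [protein_matrix()].
#' @param tau Missingness threshold in `[0, 1]`.
#' @return A `ProteinMatrix` restricted to the kept proteins.
#' @export
filter_by_threshold <- function(m, tau) {
  validate_protein_matrix(m)
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0, tau <= 1)
  keep <- protein_missing_fraction(m) < tau
  protein_matrix(m$values[, keep, drop = FALSE],
                 m$sample_ids, m$protein_ids[keep])
}

#' Mean observed intensity per sample
#'
#' For each sample, the mean over the observed values of the (already
#' filtered) proteins. Samples with no observed value are excluded from
#' the result and reported with a message; their ids are attached as
#' attribute `"excluded"`.
#'
#' @param m A [protein_matrix()].
#' @return Named numeric vector, one entry per retained sample.
#' @export
mean_intensity_per_sample <- function(m) {
  validate_protein_matrix(m)
  if (ncol(m$values) == 0) stop("no proteins in matrix", call. = FALSE)
  n_obs <- rowSums(!m$mask)
  means <- rowMeans(m$values, na.rm = TRUE)
  excluded <- m$sample_ids[n_obs == 0]
  if (length(excluded) == length(m$sample_ids)) {
    stop("every sample has zero observed values", call. = FALSE)
  }
  if (length(excluded)) {
    message(sprintf("excluding %d sample(s) with no observed values: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  out <- means[n_obs > 0]
  names(out) <- m$sample_ids[n_obs > 0]
  attr(out, "excluded") <- excluded
  out
}

#' Gaussian kernel density estimate on a fixed grid
#'
#' KDE with a Gaussian kernel on a 512-point grid spanning
#' `[min(x) - 3h, max(x) + 3h]`, bandwidth `h` by Silverman's
#' rule of thumb unless overridden. The returned density is renormalised
#' so its trapezoid integral over the grid is exactly 1. A constant input
#' yields a narrow spike at the constant, with a warning.
#'
#' @param x Numeric vector, at least 2 finite values.
#' @param bandwidth `"silverman"` or a positive number.
#' @return A `DensityCurve`: list with `grid`, `density`, `bandwidth`.
#' @export
estimate_density <- function(x, bandwidth = "silverman") {
  x <- as.numeric(x)
  if (length(x) < 2) stop("density estimation needs at least 2 values", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in density input", call. = FALSE)
  if (diff(range(x)) == 0) {
    warning("degenerate (constant) input; returning a spike density")
    h <- max(abs(x[1]), 1) * 1e-6
  } else {
    h <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(x) else {
      stopifnot(is.numeric(bandwidth), bandwidth > 0)
      bandwidth
    }
    if (!is.finite(h) || h <= 0) h <- max(abs(x[1]), 1) * 1e-6
  }
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 512,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  dens <- d$y / trapezoid(d$x, d$y)
  structure(list(grid = d$x, density = dens, bandwidth = h),
            class = "DensityCurve")
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Location of the density maximum
#'
#' Grid point of the global maximum; ties are broken towards the smallest
#' grid value.
#'
#' @param d A `DensityCurve` from [estimate_density()].
#' @return The peak location (a scalar on the intensity scale).
#' @export
density_peak <- function(d) {
  stopifnot(inherits(d, "DensityCurve"))
  d$grid[which.max(d$density)]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the supremum distance `D` between the two empirical
#' distribution functions directly (ties handled by evaluating at the
#' right edge of each tie group) and, by default, the asymptotic p-value
#' from the Kolmogorov distribution at `sqrt(n_eff) * D` with effective
#' sample size `n_eff = |x||y| / (|x| + |y|)`. `exact = TRUE` delegates
#' the p-value to the exact conditional distribution (small samples).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Use the exact small-sample p-value instead of the
#'   asymptotic one.
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty input vector", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("non-finite values", call. = FALSE)
  n <- length(x); m <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)  # right edge of each tie group
  D <- max(abs(z[keep]))
  p <- if (exact) {
    stats::ks.test(x, y, exact = TRUE)$p.value
  } else {
    n_eff <- n * m / (n + m)
    kolmogorov_sf(sqrt(n_eff) * D)
  }
  list(D = D, p = min(max(p, 0), 1))
}

# survival function of the Kolmogorov distribution, Q(lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- seq_len(100)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Compare imputed against non-imputed data at one missingness threshold
#'
#' Replays the whole-cohort comparison view: both matrices are filtered
#' to the proteins whose missing fraction in the NON-imputed data is
#' below `tau`, per-sample mean intensities are computed for each, and
#' the record collects protein counts, missing percentages, quartiles,
#' density peaks and their distance, and the two-sample KS statistic
#' between the two mean-intensity distributions.
#'
#' @param non_imputed A [protein_matrix()] with its original mask.
#' @param imputed A complete `ProteinMatrix` over the same samples and
#'   proteins (e.g. `impute(non_imputed, ...)$completed`).
#' @param tau Missingness threshold in `[0, 1]`.
#' @param bandwidth Passed to [estimate_density()].
#' @param exact_ks Passed to [ks_two_sample()].
#' @return A `ThresholdComparison`: list with `tau`, `n_proteins_kept`,
#'   `pct_missing_non_imputed` (after filtering),
#'   `pct_missing_non_imputed_unfiltered`, `pct_missing_imputed`,
#'   `quartiles_non_imputed`, `quartiles_imputed`, `peak_non_imputed`,
#'   `peak_imputed`, `peak_distance`, `ks_D`, `ks_p`.
#' @export
compare_at_threshold <- function(non_imputed, imputed, tau,
                                 bandwidth = "silverman", exact_ks = FALSE) {
  validate_protein_matrix(non_imputed)
  validate_protein_matrix(imputed)
  if (!identical(non_imputed$sample_ids, imputed$sample_ids) ||
      !identical(non_imputed$protein_ids, imputed$protein_ids)) {
    stop("matrices must share sample and protein identifiers", call. = FALSE)
  }
  if (any(imputed$mask)) stop("`imputed` still contains missing values", call. = FALSE)
  keep <- non_imputed$protein_ids[protein_missing_fraction(non_imputed) < tau]
  if (!length(keep)) {
    stop(sprintf("no protein has missing fraction below tau = %g", tau), call. = FALSE)
  }
  ni <- subset_matrix(non_imputed, proteins = keep)
  im <- subset_matrix(imputed, proteins = keep)
  v_ni <- mean_intensity_per_sample(ni)
  v_im <- mean_intensity_per_sample(im)
  d_ni <- estimate_density(v_ni, bandwidth)
  d_im <- estimate_density(v_im, bandwidth)
  ks <- ks_two_sample(v_ni, v_im, exact = exact_ks)
  structure(list(
    tau = tau,
    n_proteins_kept = length(keep),
    kept_proteins = keep,
    pct_missing_non_imputed = 100 * mean(ni$mask),
    pct_missing_non_imputed_unfiltered = 100 * mean(non_imputed$mask),
    pct_missing_imputed = 100 * mean(im$mask),
    quartiles_non_imputed = stats::quantile(v_ni, c(0.25, 0.5, 0.75), names = FALSE),
    quartiles_imputed = stats::quantile(v_im, c(0.25, 0.5, 0.75), names = FALSE),
    peak_non_imputed = density_peak(d_ni),
    peak_imputed = density_peak(d_im),
    peak_distance = abs(density_peak(d_im) - density_peak(d_ni)),
    ks_D = ks$D,
    ks_p = ks$p,
    density_non_imputed = d_ni,
    density_imputed = d_im
  ), class = "ThresholdComparison")
}

#' @export
print.ThresholdComparison <- function(x, ...) {
  cat(sprintf("ThresholdComparison (tau = %.2f)\n", x$tau))
  cat(sprintf("  proteins kept:       %d\n", x$n_proteins_kept))
  cat(sprintf("  %% missing (non-imp): %.4f\n", x$pct_missing_non_imputed))
  cat(sprintf("  peaks: non-imp %.4f, imputed %.4f (distance %.4f)\n",
              x$peak_non_imputed, x$peak_imputed, x$peak_distance))
  cat(sprintf("  KS: D = %.4f, p = %.4g\n", x$ks_D, x$ks_p))
  invisible(x)
}

#' Sweep a grid of missingness thresholds
#'
#' Runs [compare_at_threshold()] over a threshold grid (default the
#' 0.05-step grid from 0.05 to 0.95, matching interactive slider
#' exploration) and tabulates the scalar fields. Thresholds whose
#' kept-set is empty are dropped with a message.
#'
#' @param non_imputed,imputed As in [compare_at_threshold()].
#' @param taus Numeric vector of thresholds.
#' @param ... Passed to [compare_at_threshold()].
#' @return A data.frame with one row per feasible threshold.
#' @export
threshold_sweep <- function(non_imputed, imputed,
                            taus = seq(0.05, 0.95, by = 0.05), ...) {
  rows <- lapply(taus, function(tau) {
    tc <- tryCatch(compare_at_threshold(non_imputed, imputed, tau, ...),
                   error = function(e) {
                     message(sprintf("tau = %.2f skipped: %s", tau,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(tc)) return(NULL)
    data.frame(tau = tc$tau,
               n_proteins_kept = tc$n_proteins_kept,
               pct_missing_non_imputed = tc$pct_missing_non_imputed,
               pct_missing_imputed = tc$pct_missing_imputed,
               q1_non_imputed = tc$quartiles_non_imputed[1],
               median_non_imputed = tc$quartiles_non_imputed[2],
               q3_non_imputed = tc$quartiles_non_imputed[3],
               q1_imputed = tc$quartiles_imputed[1],
               median_imputed = tc$quartiles_imputed[2],
               q3_imputed = tc$quartiles_imputed[3],
               peak_non_imputed = tc$peak_non_imputed,
               peak_imputed = tc$peak_imputed,
               peak_distance = tc$peak_distance,
               ks_D = tc$ks_D,
               ks_p = tc$ks_p)
  })
  do.call(rbind, rows)
}

#' Compare one protein's distributions in imputed and non-imputed data
#'
#' Restricts the comparison to a single protein: the non-imputed vector
#' holds its observed values only, the imputed vector all samples.
#'
#' @param non_imputed,imputed As in [compare_at_threshold()].
#' @param protein_id Protein identifier; unknown ids raise an error
#'   listing near-matches.
#' @param bandwidth,exact_ks As in [compare_at_threshold()].
#' @return List with `protein_id`, `missing_fraction`,
#'   `values_non_imputed`, `values_imputed`, both densities, both peaks,
#'   `peak_distance`, `ks_D`, `ks_p`.
#' @export
compare_protein <- function(non_imputed, imputed, protein_id,
                            bandwidth = "silverman", exact_ks = FALSE) {
  validate_protein_matrix(non_imputed)
  validate_protein_matrix(imputed)
  if (!protein_id %in% non_imputed$protein_ids ||
      !protein_id %in% imputed$protein_ids) {
    near <- unique(c(
      utils::head(agrep(protein_id, non_imputed$protein_ids, value = TRUE,
                        max.distance = 0.3), 5)))
    stop(sprintf("unknown protein '%s'%s", protein_id,
                 if (length(near)) paste0("; near matches: ",
                                          paste(near, collapse = ", ")) else ""),
         call. = FALSE)
  }
  col_ni <- non_imputed$values[, protein_id]
  col_im <- imputed$values[, protein_id]
  obs <- col_ni[!non_imputed$mask[, protein_id]]
  if (length(obs) < 2) {
    stop(sprintf("protein '%s' has fewer than 2 observed values", protein_id),
         call. = FALSE)
  }
  d_ni <- estimate_density(obs, bandwidth)
  d_im <- estimate_density(col_im, bandwidth)
  ks <- ks_two_sample(obs, col_im, exact = exact_ks)
  list(protein_id = protein_id,
       missing_fraction = mean(non_imputed$mask[, protein_id]),
       values_non_imputed = unname(obs),
       values_imputed = unname(col_im),
       density_non_imputed = d_ni,
       density_imputed = d_im,
       peak_non_imputed = density_peak(d_ni),
       peak_imputed = density_peak(d_im),
       peak_distance = abs(density_peak(d_im) - density_peak(d_ni)),
       ks_D = ks$D, ks_p = ks$p)
}

#' Overlay plot of the imputed and non-imputed densities
#'
#' Non-imputed in blue, imputed in red, with dashed vertical lines at the
#' two density peaks and the KS statistic in the title.
#'
#' @param tc A `ThresholdComparison` (or the list from [compare_protein()]).
#' @param path Optional PNG path; `NULL` draws on the active device.
#' @return `path`, invisibly.
#' @export
plot_comparison <- function(tc, path = NULL) {
  d1 <- tc$density_non_imputed; d2 <- tc$density_imputed
  title <- if (!is.null(tc$tau)) {
    sprintf("tau = %.2f | KS D = %.3f, p = %.3g", tc$tau, tc$ks_D, tc$ks_p)
  } else {
    sprintf("%s | KS D = %.3f, p = %.3g", tc$protein_id, tc$ks_D, tc$ks_p)
  }
  draw <- function() {
    xlim <- range(d1$grid, d2$grid)
    ylim <- c(0, max(d1$density, d2$density))
    graphics::plot(d1$grid, d1$density, type = "l", col = "steelblue", lwd = 2,
                   xlim = xlim, ylim = ylim, xlab = "mean intensity (log scale)",
                   ylab = "density", main = title)
    graphics::lines(d2$grid, d2$density, col = "firebrick", lwd = 2)
    graphics::abline(v = tc$peak_non_imputed, col = "steelblue", lty = 2)
    graphics::abline(v = tc$peak_imputed, col = "firebrick", lty = 2)
    graphics::legend("topleft", legend = c("non-imputed", "imputed"),
                     col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  }
  render_png(draw, path)
}
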
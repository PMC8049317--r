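#' Impute missing values in a protein matrix
#'
#' Single dispatch point over the five imputation engines. Model-based
#' methods (everything except `lowest_value`) require at least one
#' observed value per protein. All methods preserve observed cells
#' exactly and return a matrix with no missing cells.
#'
#' @param m A [protein_matrix()].
#' @param method One of `"lowest_value"`, `"chained_equations"`,
#'   `"iterative_forest"`, `"ppca"`, `"em"`.
#' @param params Named list of method parameters, passed to the engine
#'   (see [impute_lowest_value()], [impute_chained()], [impute_forest()],
#'   [impute_ppca()], [impute_em()]).
#' @param seed Integer seed controlling any randomness in the engine;
#'   `NULL` leaves the RNG state untouched.
#' @return An `ImputationResult`: list with `completed` (a complete
#'   `ProteinMatrix`), `method`, `params`, `seed`, `n_iterations_run`,
#'   `converged`.
#' @export
impute <- function(m, method = c("lowest_value", "chained_equations",
                                 "iterative_forest", "ppca", "em"),
                   params = list(), seed = NULL) {
  method <- match.arg(method)
  validate_protein_matrix(m)
  if (method != "lowest_value") {
    empty <- m$protein_ids[colSums(!m$mask) == 0]
    if (length(empty)) {
      stop(sprintf("method '%s' requires at least one observed value per protein; offending proteins: %s",
                   method, paste(empty, collapse = ", ")), call. = FALSE)
    }
  }
  fn <- switch(method,
    lowest_value = impute_lowest_value,
    chained_equations = impute_chained,
    iterative_forest = impute_forest,
    ppca = impute_ppca,
    em = impute_em
  )
  args <- c(list(m = m), params)
  if (method %in% c("chained_equations", "iterative_forest", "ppca")) {
    args$seed <- seed
  }
  do.call(fn, args)
}

new_imputation_result <- function(m, completed_values, method, params, seed,
                                  n_iterations_run, converged) {
  # observed-value preservation is enforced here, for every engine
  completed_values[!m$mask] <- m$values[!m$mask]
  if (any(!is.finite(completed_values))) {
    stop("imputation produced non-finite values", call. = FALSE)
  }
  completed <- protein_matrix(completed_values, m$sample_ids, m$protein_ids)
  structure(
    list(completed = completed, method = method, params = params,
         seed = seed, n_iterations_run = n_iterations_run,
         converged = converged),
    class = "ImputationResult"
  )
}

#' @export
print.ImputationResult <- function(x, ...) {
  cat(sprintf("ImputationResult: method=%s, iterations=%d, converged=%s\n",
              x$method, x$n_iterations_run, x$converged))
  print(x$completed)
  invisible(x)
}

#' Lowest-value imputation (MNAR)
#'
#' Substitutes every missing cell with a fixed low value, reflecting the
#' assumption that intensities are absent because they fell below the
#' instrument's detection sensitivity. The default fill is the constant 1
#' (the lowest possible value on a log-transformed intensity scale);
#' `use_observed_min = TRUE` uses the global observed minimum instead,
#' the other common reading of "lowest value".
#'
#' @param m A [protein_matrix()].
#' @param fill Fill value, default 1.
#' @param use_observed_min If `TRUE`, ignore `fill` and use
#'   `min(observed values)`.
#' @return An `ImputationResult` (see [impute()]).
#' @export
impute_lowest_value <- function(m, fill = 1, use_observed_min = FALSE) {
  validate_protein_matrix(m)
  if (use_observed_min) {
    if (all(m$mask)) stop("no observed values to take the minimum of", call. = FALSE)
    fill <- min(m$values[!m$mask])
  }
  v <- m$values
  v[m$mask] <- fill
  new_imputation_result(m, v, "lowest_value",
                        list(fill = fill, use_observed_min = use_observed_min),
                        seed = NULL, n_iterations_run = 0L, converged = TRUE)
}

#' Chained-equations (MICE-style) imputation
#'
#' Missing cells are initialised with the column means of the observed
#' values, then refreshed by cycling over proteins: each protein with
#' missing entries is regressed (ridge-regularised linear model) on all
#' other proteins using the currently completed data, restricted to the
#' samples where that protein was genuinely observed, and its missing
#' entries are replaced by the fitted conditional means, optionally plus
#' a draw of Gaussian residual noise.
#'
#' @param m A [protein_matrix()].
#' @param n_iterations Number of full sweeps over the proteins, default 10.
#' @param seed Integer seed for the residual-noise draws.
#' @param deterministic If `TRUE` (default `FALSE`), skip the noise draw
#'   and use pure conditional-mean updates.
#' @param ridge Ridge penalty relative to the mean diagonal of the
#'   predictor cross-product, default `1e-3`.
#' @return An `ImputationResult`.
#' @export
impute_chained <- function(m, n_iterations = 10, seed = NULL,
                           deterministic = FALSE, ridge = 1e-3) {
  validate_protein_matrix(m)
  if (ncol(m$values) < 2) {
    stop("chained-equations imputation needs at least 2 proteins", call. = FALSE)
  }
  if (!any(m$mask)) {
    return(new_imputation_result(m, m$values, "chained_equations",
                                 list(n_iterations = n_iterations,
                                      deterministic = deterministic, ridge = ridge),
                                 seed, 0L, TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  X <- mean_fill(m)
  todo <- which(colSums(m$mask) > 0)
  for (iter in seq_len(n_iterations)) {
    for (j in todo) {
      obs <- !m$mask[, j]
      fit <- ridge_fit(X[obs, -j, drop = FALSE], m$values[obs, j], ridge)
      pred <- ridge_predict(fit, X[!obs, -j, drop = FALSE])
      if (!deterministic && fit$sigma > 0) {
        pred <- pred + stats::rnorm(length(pred), 0, fit$sigma)
      }
      X[!obs, j] <- pred
    }
  }
  new_imputation_result(m, X, "chained_equations",
                        list(n_iterations = n_iterations,
                             deterministic = deterministic, ridge = ridge),
                        seed, as.integer(n_iterations), TRUE)
}

mean_fill <- function(m) {
  X <- m$values
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0  # proteins with no observed value (lowest_value path only)
  idx <- which(m$mask, arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

# centered ridge regression; lambda scaled by the mean predictor variance
ridge_fit <- function(X, y, ridge) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  G <- crossprod(Xc)
  lambda <- ridge * mean(diag(G)) + 1e-12
  beta <- solve(G + diag(lambda, ncol(X)), crossprod(Xc, y - ym))
  resid <- (y - ym) - Xc %*% beta
  dof <- max(1, length(y) - 1)
  list(beta = beta, xm = xm, ym = ym,
       sigma = sqrt(sum(resid^2) / dof))
}

ridge_predict <- function(fit, X) {
  drop(sweep(X, 2, fit$xm) %*% fit$beta) + fit$ym
}

#' Iterative random-forest (missForest-style) imputation
#'
#' Missing cells are initialised with observed column means; proteins are
#' then visited in order of increasing missingness, each regressed with a
#' random forest on all other (currently completed) proteins over the
#' samples where it was observed, and its missing entries replaced by the
#' forest predictions. Rounds repeat until the normalised change in the
#' imputed values first increases (the standard stopping rule, returning
#' the previous round's values) or `max_iter` is reached.
#'
#' @param m A [protein_matrix()].
#' @param max_iter Maximum number of rounds, default 10.
#' @param n_trees Trees per forest, default 100.
#' @param seed Integer seed (forests are stochastic).
#' @return An `ImputationResult`.
#' @export
impute_forest <- function(m, max_iter = 10, n_trees = 100, seed = NULL) {
  validate_protein_matrix(m)
  if (ncol(m$values) < 2) {
    stop("forest imputation needs at least 2 proteins", call. = FALSE)
  }
  params <- list(max_iter = max_iter, n_trees = n_trees)
  if (!any(m$mask)) {
    return(new_imputation_result(m, m$values, "iterative_forest", params,
                                 seed, 0L, TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  X <- mean_fill(m)
  todo <- order(colSums(m$mask))
  todo <- todo[colSums(m$mask)[todo] > 0]
  prev_delta <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    X_new <- X
    for (j in todo) {
      obs <- !m$mask[, j]
      rf <- randomForest::randomForest(
        x = X_new[obs, -j, drop = FALSE], y = m$values[obs, j],
        ntree = n_trees)
      X_new[!obs, j] <- stats::predict(rf, X_new[!obs, -j, drop = FALSE])
    }
    delta <- sum((X_new[m$mask] - X[m$mask])^2) / max(sum(X_new[m$mask]^2), 1e-12)
    if (delta > prev_delta) {
      converged <- TRUE  # change increased: keep the previous round's values
      break
    }
    X <- X_new
    prev_delta <- delta
  }
  new_imputation_result(m, X, "iterative_forest", params, seed, iter, converged)
}
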
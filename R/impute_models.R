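#' Probabilistic-PCA imputation
#'
#' Fits a probabilistic PCA model (Gaussian latent factors plus isotropic
#' noise) by an EM scheme on the incomplete matrix: missing cells are
#' initialised with observed column means, the model is fitted to the
#' completed matrix by eigendecomposition (the maximum-likelihood
#' solution given complete data), missing cells are replaced by the
#' posterior-mean reconstruction, and the fit/replace cycle repeats until
#' the relative change in the imputed values drops below `tol` or
#' `max_iter` is reached. With noise-free low-rank data the fixed point
#' reproduces the generating grid on the masked cells.
#'
#' @param m A [protein_matrix()].
#' @param n_components Latent dimensionality; must be smaller than both
#'   axes. Default 2.
#' @param max_iter Maximum fit/replace cycles, default 500.
#' @param tol Relative-change convergence tolerance on the imputed
#'   values, default `1e-6`.
#' @param seed Recorded for provenance; the algorithm itself is
#'   deterministic.
#' @return An `ImputationResult`; `converged = FALSE` (with a warning)
#'   if `max_iter` was exhausted.
#' @export
impute_ppca <- function(m, n_components = 2, max_iter = 500, tol = 1e-6,
                        seed = NULL) {
  validate_protein_matrix(m)
  n <- nrow(m$values); p <- ncol(m$values)
  if (n_components >= min(n, p)) {
    stop(sprintf("n_components (%d) must be < min(n_samples, n_proteins) = %d",
                 n_components, min(n, p)), call. = FALSE)
  }
  params <- list(n_components = n_components, max_iter = max_iter, tol = tol)
  if (!any(m$mask)) {
    return(new_imputation_result(m, m$values, "ppca", params, seed, 0L, TRUE))
  }
  X <- mean_fill(m)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    fit <- ppca_fit(X, n_components)
    recon <- ppca_reconstruct(fit, X)
    old <- X[m$mask]
    X[m$mask] <- recon[m$mask]
    delta <- max(abs(X[m$mask] - old)) / max(max(abs(X[m$mask])), 1e-12)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("PPCA imputation did not converge in %d iterations", max_iter))
  }
  new_imputation_result(m, X, "ppca", params, seed, iter, converged)
}

# ML probabilistic-PCA fit on a complete matrix (samples x proteins):
# W = V_q (Lambda_q - sigma2 I)^(1/2), sigma2 = mean of discarded eigenvalues
ppca_fit <- function(X, q) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = q)
  n <- nrow(X)
  lambda <- sv$d^2 / max(1, n - 1)
  lam_q <- lambda[seq_len(q)]
  sigma2 <- if (length(lambda) > q) mean(lambda[-seq_len(q)]) else 0
  W <- sv$v %*% diag(sqrt(pmax(lam_q - sigma2, 0)), q, q)
  list(mu = mu, W = W, sigma2 = sigma2, q = q)
}

# posterior-mean latent scores and reconstruction for each row
ppca_scores <- function(fit, X) {
  Xc <- sweep(X, 2, fit$mu)
  M <- crossprod(fit$W) + diag(fit$sigma2 + 1e-12, fit$q)
  t(solve(M, t(Xc %*% fit$W)))
}

ppca_reconstruct <- function(fit, X) {
  Tm <- ppca_scores(fit, X)
  sweep(Tm %*% t(fit$W), 2, fit$mu, `+`)
}

#' Multivariate-normal EM imputation
#'
#' Fits a multivariate normal over proteins by expectation-maximisation
#' on the incomplete matrix: the E-step fills each sample's missing block
#' with its conditional expectation (and tracks the conditional
#' covariance), the M-step re-estimates the mean vector and covariance
#' matrix. The covariance receives a small ridge
#' (`ridge` x mean diagonal) each iteration so the method remains usable
#' when proteins outnumber samples. The returned matrix carries the
#' final conditional expectations in the missing cells.
#'
#' @param m A [protein_matrix()].
#' @param max_iter Maximum EM iterations, default 500.
#' @param tol Relative-change convergence tolerance on the imputed
#'   values, default `1e-6`.
#' @param ridge Relative ridge added to the covariance diagonal,
#'   default `1e-6`.
#' @return An `ImputationResult`.
#' @export
impute_em <- function(m, max_iter = 500, tol = 1e-6, ridge = 1e-6) {
  validate_protein_matrix(m)
  params <- list(max_iter = max_iter, tol = tol, ridge = ridge)
  if (!any(m$mask)) {
    return(new_imputation_result(m, m$values, "em", params, NULL, 0L, TRUE))
  }
  n <- nrow(m$values); p <- ncol(m$values)
  X <- mean_fill(m)
  mu <- colMeans(X)
  S <- stats::cov(X) * (n - 1) / n
  S <- regularise_cov(S, ridge)
  rows_missing <- which(rowSums(m$mask) > 0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    C_acc <- matrix(0, p, p)
    old <- X[m$mask]
    for (i in rows_missing) {
      mi <- m$mask[i, ]
      if (all(mi)) {  # no observed cells in this sample
        X[i, mi] <- mu[mi]
        C_acc[mi, mi] <- C_acc[mi, mi] + S[mi, mi]
        next
      }
      Soo <- S[!mi, !mi, drop = FALSE]
      Smo <- S[mi, !mi, drop = FALSE]
      sol <- tryCatch(solve(Soo, t(Smo)), error = function(e)
        stop("singular covariance in EM even after regularisation; raise the missingness threshold or use another method",
             call. = FALSE))
      X[i, mi] <- mu[mi] + drop(crossprod(sol, X[i, !mi] - mu[!mi]))
      C_acc[mi, mi] <- C_acc[mi, mi] + S[mi, mi, drop = FALSE] - Smo %*% sol
    }
    mu <- colMeans(X)
    S <- (crossprod(sweep(X, 2, mu)) + C_acc) / n
    S <- regularise_cov(S, ridge)
    delta <- max(abs(X[m$mask] - old)) / max(max(abs(X[m$mask])), 1e-12)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("EM imputation did not converge in %d iterations", max_iter))
  }
  new_imputation_result(m, X, "em", params, NULL, iter, converged)
}

regularise_cov <- function(S, ridge) {
  S + diag(ridge * mean(diag(S)) + 1e-12, nrow(S))
}
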
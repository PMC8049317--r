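# fixture builders shared across test files

pm <- function(values, sample_ids = NULL, protein_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(protein_ids)) protein_ids <- sprintf("p%d", seq_len(ncol(values)))
  protein_matrix(values, sample_ids, protein_ids)
}

# noise-free rank-1 grid (outer product of positive vectors) with MCAR mask
rank1_fixture <- function(n = 40, p = 15, mcar = 0.1, seed = 42) {
  set.seed(seed)
  truth <- outer(runif(n, 1, 3), runif(p, 2, 5))
  mask <- matrix(runif(n * p) < mcar, n, p)
  vals <- truth
  vals[mask] <- NA
  list(m = pm(vals), truth = truth, mask = mask)
}

# three proteins: p2 = 2 * p1 exactly, p3 independent; p2 partially masked
linear_fixture <- function(n = 100, n_missing = 15, seed = 3) {
  set.seed(seed)
  p1 <- runif(n, 10, 20)
  vals <- cbind(p1, 2 * p1, rnorm(n, 15, 1))
  mask <- matrix(FALSE, n, 3)
  mask[sample(n, n_missing), 2] <- TRUE
  truth <- vals
  vals[mask] <- NA
  list(m = pm(vals), truth = truth, mask = mask)
}

# two well-separated Gaussian sample blobs in protein space
blob_fixture <- function(n_per = 10, p = 5, gap = 50, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, 0, 1), n_per, p),
             matrix(rnorm(n_per * p, gap, 1), n_per, p))
  rownames(X) <- sprintf("s%d", seq_len(2 * n_per))
  colnames(X) <- sprintf("p%d", seq_len(p))
  X
}

# hand-built MapperGraph (for community/topology tests), using the package's
# internal constructor so the structure matches build_mapper output
graph_fixture <- function(member_sets, edges) {
  nodes <- lapply(seq_along(member_sets), function(i) {
    list(id = paste0("n", i), members = member_sets[[i]], bin = c(1L, 1L))
  })
  ids <- vapply(nodes, `[[`, "", "id")
  edge_mat <- if (length(edges)) {
    t(vapply(edges, function(e) paste0("n", e), c("", "")))
  } else matrix(character(0), 0, 2)
  universe <- sort(unique(unlist(member_sets)))
  lens_tab <- data.frame(sample_id = universe, lens1 = 0, lens2 = 0)
  protmiss:::new_mapper_graph(nodes, edge_mat, universe, lens_tab,
                              mapper_config(), seed = NULL)
}

expect_matrices_equal <- function(a, b) {
  testthat::expect_true(matrices_identical(a, b))
}

# trapezoid integral of a DensityCurve, written out directly
trapezoid_integral <- function(d) {
  y <- d$density
  sum(diff(d$grid) * (y[-length(y)] + y[-1]) / 2)
}
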
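test_that("distance matrix handles complete and pairwise-complete cases", {
  m <- pm(rbind(c(0, 0), c(3, 4)))
  D <- distance_matrix(m)
  expect_equal(D["s1", "s2"], 5)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
  # one co-masked protein out of p = 2: distance over the shared
  # coordinate, rescaled by sqrt(p / k) = sqrt(2)
  # rows 1,2 share only protein 1 (protein 2 masked in both)
  vals <- rbind(c(0, NA), c(3, 5), c(1, 1))
  vals[2, 2] <- NA
  D2 <- distance_matrix(pm(vals))
  expect_equal(D2["s1", "s2"], 3 * sqrt(2))
  # identical rows are at distance zero
  m3 <- pm(rbind(c(1, 2), c(1, 2)))
  expect_equal(distance_matrix(m3)["s1", "s2"], 0)
})

test_that("a pair with no co-observed protein is a named hard error", {
  vals <- rbind(c(1, NA), c(NA, 2), c(3, 4), c(5, 6))
  expect_error(distance_matrix(pm(vals)), "s1, s2|\\(s1, s2\\)")
  expect_message(D <- distance_matrix(pm(vals), policy = "complete_only"),
                 "dropping 2")
  expect_equal(rownames(D), c("s3", "s4"))
  expect_error(distance_matrix(pm(rbind(c(1, NA), c(NA, 2))),
                               policy = "complete_only"), "fewer than 2")
})

test_that("eccentricity lenses match hand computations", {
  X <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "p"))
  D <- distance_matrix(pm(X, sample_ids = c("a", "b", "c")))
  expect_equal(unname(lens_eccentricity(D)), c(2, 1, 2))
  expect_equal(unname(lens_eccentricity(D, "l1")), c(1.5, 1, 1.5))
  # vertices of a unit square: all eccentricities sqrt(2)
  sq <- pm(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(unname(lens_eccentricity(distance_matrix(sq))),
               rep(sqrt(2), 4))
  # identical points
  same <- pm(rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(lens_eccentricity(distance_matrix(same))), c(0, 0))
})

test_that("the PPCA lens tracks the generating factor and sign convention", {
  set.seed(31)
  u <- runif(30, 1, 3)
  X <- outer(u, runif(8, 2, 5))
  m <- pm(X)
  sc <- lens_ppca_first(m)
  expect_gt(abs(stats::cor(sc, u)), 0.99)
  expect_gt(stats::cor(sc, rowMeans(X)), 0)  # sign convention
  # duplicated sample rows receive equal scores
  m2 <- pm(rbind(X[1, ], X[1, ], X[2, ]))
  sc2 <- lens_ppca_first(m2)
  expect_equal(sc2[[1]], sc2[[2]])
  expect_error(lens_ppca_first(pm(matrix(5, 3, 2))), "zero-variance")
})

test_that("cover intervals follow the stated length formula", {
  cov <- build_cover(c(0, 1), c(0, 1), intervals = c(2, 1), overlap = 0.5)
  on1 <- cov[cov$bin2 == 1, ]
  expect_equal(on1$low1, c(0, 1 / 3))
  expect_equal(on1$high1, c(2 / 3, 1))
  # zero overlap gives an exact partition of length range/n
  cov0 <- build_cover(c(0, 10), c(0, 1), intervals = c(5, 1), overlap = 0)
  expect_equal(unique(round(cov0$high1 - cov0$low1, 12)), 2)
  # a single interval spans the full range
  cov1 <- build_cover(c(2, 9), c(0, 1), intervals = c(1, 1), overlap = 0.5)
  expect_equal(c(cov1$low1, cov1$high1), c(2, 9))
  expect_warning(build_cover(c(3, 3), c(0, 1), intervals = c(4, 2),
                             overlap = 0.3), "zero lens range")
})

test_that("every lens point lands in at least one cover bin", {
  set.seed(32)
  for (i in 1:50) {
    l1 <- runif(20, -5, 5); l2 <- rnorm(20)
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    g <- runif(1, 0, 0.9)
    cov <- build_cover(l1, l2, c(n1, n2), g)
    covered <- vapply(seq_along(l1), function(k) {
      any(l1[k] >= cov$low1 & l1[k] <= cov$high1 &
          l2[k] >= cov$low2 & l2[k] <= cov$high2)
    }, TRUE)
    expect_true(all(covered))
  }
})

test_that("pre-image clustering cuts at the first gap in merge heights", {
  # two tight groups separated by >= 10x the within-group spread
  set.seed(33)
  X <- rbind(matrix(rnorm(12, 0, 0.05), 4, 3),
             matrix(rnorm(12, 10, 0.05), 4, 3))
  m <- pm(X)
  D <- distance_matrix(m)
  cl <- cluster_preimage(m$sample_ids, D, clustering_bins = 10)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, length, 1L), c(4L, 4L))
  # singleton member set
  expect_equal(cluster_preimage("s1", D), list("s1"))
  # all pairwise distances equal: no gap, one cluster
  simplex <- pm(diag(3) * 5)
  Ds <- distance_matrix(simplex)
  expect_length(cluster_preimage(simplex$sample_ids, Ds, 10), 1)
})

test_that("mapper separates well-separated blobs into distinct components", {
  X <- blob_fixture(n_per = 10, gap = 50)
  m <- pm(X, sample_ids = rownames(X))
  cfg <- mapper_config(lens2 = "l1_eccentricity", intervals = c(4, 4),
                       overlap = 0.5)
  g <- build_mapper(m, cfg, seed = 1)
  expect_gte(g$summary$n_connected_components, 2)
  # no node mixes the two blobs
  blob1 <- rownames(X)[1:10]
  for (nd in g$nodes) {
    expect_true(all(nd$members %in% blob1) || !any(nd$members %in% blob1))
  }
  # coverage: every sample appears in at least one node
  expect_setequal(unique(unlist(lapply(g$nodes, `[[`, "members"))),
                  rownames(X))
})

test_that("a single sample yields a single node and no edges", {
  m <- pm(matrix(c(1, 2), 1, 2))
  g <- build_mapper(m, mapper_config())
  expect_equal(g$summary$n_nodes, 1)
  expect_equal(g$summary$n_edges, 0)
  expect_equal(g$nodes[[1]]$members, "s1")
})

test_that("mapper equals the brute-force oracle on small fixtures", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 3, 0, 2), n, 3)
    if (rep %% 2 == 0) X[seq_len(ceiling(n / 2)), ] <- X[seq_len(ceiling(n / 2)), ] + 6
    rownames(X) <- sprintf("s%02d", seq_len(n))
    colnames(X) <- c("pa", "pb", "pc")
    intervals <- if (rep %% 2 == 0) c(3, 2) else c(2, 2)
    cfg <- mapper_config(lens1 = "l_infinity_eccentricity",
                         lens2 = "l1_eccentricity",
                         intervals = intervals, overlap = 0.5,
                         clustering_bins = 5)
    g <- build_mapper(pm(X, sample_ids = rownames(X),
                         protein_ids = colnames(X)), cfg)
    got <- mapper_keys(g)
    want <- brute_mapper(X, intervals, 0.5, 5)
    expect_identical(got$node_keys, want$node_keys)
    expect_identical(got$edge_keys, want$edge_keys)
  }
})

test_that("edges exist exactly where nodes share samples", {
  sim <- simulate_dataset(simulation_config(30, 10, mcar_rate = 0.1, seed = 16))
  g <- build_mapper(sim$observed, mapper_config(intervals = c(4, 3)), seed = 1)
  ids <- vapply(g$nodes, `[[`, "", "id")
  members <- lapply(g$nodes, `[[`, "members")
  names(members) <- ids
  edge_set <- if (nrow(g$edges)) {
    apply(g$edges, 1, function(e) paste(sort(e), collapse = "|"))
  } else character(0)
  for (u in seq_along(ids)) {
    for (v in seq_along(ids)) {
      if (u >= v) next
      shares <- length(intersect(members[[u]], members[[v]])) > 0
      key <- paste(sort(c(ids[u], ids[v])), collapse = "|")
      expect_equal(key %in% edge_set, shares)
    }
  }
})

test_that("mapper output is deterministic", {
  sim <- simulate_dataset(simulation_config(25, 12, mcar_rate = 0.15, seed = 17))
  g1 <- build_mapper(sim$observed, mapper_config(intervals = c(5, 4)), seed = 2)
  g2 <- build_mapper(sim$observed, mapper_config(intervals = c(5, 4)), seed = 2)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("node enrichment is the mean member missing percentage", {
  g <- graph_fixture(list(c("a", "b"), c("b", "c"), "d"),
                     list(c(1, 2)))
  vals <- rbind(a = c(1, NA, 3, NA, 5),   # 0.4 missing
                b = c(NA, NA, NA, 4, 5),  # 0.6
                c = c(1, 2, 3, 4, 5),     # 0.0
                d = c(NA, 2, 3, 4, 5))    # 0.2
  prof <- profile_missingness(pm(vals, sample_ids = rownames(vals)))
  ge <- enrich_missingness(g, prof)
  expect_equal(unname(ge$node_enrichment["n1"]), 50)   # mean(0.4, 0.6) * 100
  expect_equal(unname(ge$node_enrichment["n2"]), 30)
  expect_equal(unname(ge$node_enrichment["n3"]), 20)   # singleton
  g_bad <- graph_fixture(list(c("zz")), list())
  expect_error(enrich_missingness(g_bad, prof), "zz")
})

test_that("two disconnected triangles form two communities", {
  g <- graph_fixture(as.list(letters[1:6]),
                     list(c(1, 2), c(2, 3), c(1, 3),
                          c(4, 5), c(5, 6), c(4, 6)))
  gc <- detect_communities(g)
  expect_equal(length(unique(gc$communities)), 2)
  expect_length(unique(gc$communities[c("n1", "n2", "n3")]), 1)
  expect_length(unique(gc$communities[c("n4", "n5", "n6")]), 1)
  expect_equal(gc$summary$modularity, 0.5)
})

test_that("an edgeless graph yields singleton communities, modularity 0", {
  g <- graph_fixture(as.list(letters[1:4]), list())
  gc <- detect_communities(g)
  expect_equal(unname(gc$communities), 1:4)
  expect_equal(gc$summary$modularity, 0)
})

test_that("exact detection attains the exhaustive-search modularity", {
  set.seed(35)
  graphs <- list(
    graph_fixture(as.list(letters[1:6]),
                  list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))),
    graph_fixture(as.list(letters[1:5]),
                  list(c(1, 2), c(2, 3), c(3, 4), c(4, 5))),
    graph_fixture(as.list(letters[1:7]),
                  list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5),
                       c(5, 6), c(5, 7), c(6, 7))))
  for (i in 1:3) {  # small random graphs
    n <- sample(4:8, 1)
    pairs <- utils::combn(n, 2)
    sel <- pairs[, runif(ncol(pairs)) < 0.45, drop = FALSE]
    if (!ncol(sel)) sel <- pairs[, 1, drop = FALSE]
    graphs[[length(graphs) + 1]] <-
      graph_fixture(as.list(paste0("x", seq_len(n))),
                    lapply(seq_len(ncol(sel)), function(k) sel[, k]))
  }
  for (g in graphs) {
    gc <- detect_communities(g)
    expect_equal(gc$summary$community_method, "exact")
    expect_equal(gc$summary$modularity, brute_max_modularity(as_igraph(g)),
                 tolerance = 1e-9)
  }
})

test_that("topology comparison scores partition agreement with ARI", {
  sim <- simulate_dataset(simulation_config(25, 10, mcar_rate = 0.1, seed = 18))
  g <- build_mapper(sim$observed, mapper_config(intervals = c(4, 3)), seed = 1)
  self <- compare_topologies(g, g)
  expect_equal(self$adjusted_rand_index, 1)
  expect_equal(self$n_shared_samples, 25)
  # multi-cluster partition vs everything-in-one-node
  g_multi <- graph_fixture(list(c("a", "b"), c("c", "d"), c("e", "f")), list())
  g_one <- graph_fixture(list(c("a", "b", "c", "d", "e", "f")), list())
  ari <- compare_topologies(g_multi, g_one)$adjusted_rand_index
  expect_lte(ari, 0.1)
  g_far <- graph_fixture(list(c("zz1", "zz2")), list())
  expect_error(compare_topologies(g_multi, g_far), "share no samples")
})

test_that("graph export writes GraphML plus a JSON node table", {
  sim <- simulate_dataset(simulation_config(20, 8, mcar_rate = 0.1, seed = 19))
  prof <- profile_missingness(sim$observed)
  g <- detect_communities(enrich_missingness(
    build_mapper(sim$observed, mapper_config(intervals = c(3, 3)), seed = 1),
    prof))
  gml <- withr::local_tempfile(fileext = ".graphml")
  js <- withr::local_tempfile(fileext = ".json")
  write_mapper_graph(g, gml, js)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), g$summary$n_nodes)
  expect_equal(igraph::ecount(reread), g$summary$n_edges)
  node_tab <- jsonlite::read_json(js)
  expect_length(node_tab$nodes, g$summary$n_nodes)
})
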
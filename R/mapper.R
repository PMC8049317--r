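#' Mapper configuration
#'
#' Bundles the parameters of the Mapper construction. The defaults mirror
#' a typical two-lens dashboard run on a protein matrix: L-infinity
#' eccentricity and the first probabilistic-PCA component as lenses,
#' 16 x 15 intervals, 50% overlap, single-linkage clustering with the
#' 10-bin histogram-gap cut, Euclidean metric.
#'
#' @param lens1,lens2 Lens names: `"l_infinity_eccentricity"`,
#'   `"l1_eccentricity"` or `"ppca_first_component"`.
#' @param intervals Integer pair: number of cover intervals per lens axis.
#' @param overlap Fractional overlap between adjacent intervals, in
#'   `[0, 1)`.
#' @param clustering_bins Histogram bin count for the single-linkage
#'   dendrogram cut heuristic.
#' @param metric Distance metric; only `"euclidean"` is provided.
#' @param missing_policy How missing values enter the distance:
#'   `"pairwise_complete_scaled"` (distance over co-observed proteins,
#'   rescaled by `sqrt(p / k)`) or `"complete_only"` (drop incomplete
#'   samples).
#' @return A `MapperConfig` list.
#' @export
mapper_config <- function(lens1 = "l_infinity_eccentricity",
                          lens2 = "ppca_first_component",
                          intervals = c(16, 15),
                          overlap = 0.5,
                          clustering_bins = 10,
                          metric = "euclidean",
                          missing_policy = c("pairwise_complete_scaled",
                                             "complete_only")) {
  lenses <- c("l_infinity_eccentricity", "l1_eccentricity",
              "ppca_first_component")
  stopifnot(lens1 %in% lenses, lens2 %in% lenses,
            length(intervals) == 2, all(intervals >= 1),
            is.numeric(overlap), overlap >= 0, overlap < 1,
            clustering_bins >= 1, metric == "euclidean")
  missing_policy <- match.arg(missing_policy)
  structure(list(lens1 = lens1, lens2 = lens2,
                 intervals = as.integer(intervals), overlap = overlap,
                 clustering_bins = as.integer(clustering_bins),
                 metric = metric, missing_policy = missing_policy),
            class = "MapperConfig")
}

#' Sample-to-sample distance matrix with missing-value policies
#'
#' Complete matrices give the plain Euclidean distance between sample
#' rows. With missing values, `"pairwise_complete_scaled"` computes the
#' distance over the `k` co-observed proteins of each pair and rescales
#' it by `sqrt(p / k)` (`p` = total proteins), the classical
#' available-case correction; a pair with no co-observed protein is a
#' hard error. `"complete_only"` instead drops every sample containing a
#' missing value (reported with a message).
#'
#' @param m A [protein_matrix()].
#' @param policy `"pairwise_complete_scaled"` or `"complete_only"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames set to
#'   the retained sample ids; attribute `"dropped"` lists samples removed
#'   under `"complete_only"`.
#' @export
distance_matrix <- function(m, policy = c("pairwise_complete_scaled",
                                          "complete_only")) {
  policy <- match.arg(policy)
  validate_protein_matrix(m)
  if (nrow(m$values) < 2) stop("need at least 2 samples", call. = FALSE)
  dropped <- character(0)
  v <- m$values
  if (policy == "complete_only" && any(m$mask)) {
    keep <- rowSums(m$mask) == 0
    dropped <- m$sample_ids[!keep]
    if (sum(keep) < 2) {
      stop("fewer than 2 complete samples under complete_only", call. = FALSE)
    }
    message(sprintf("complete_only: dropping %d incomplete sample(s)",
                    length(dropped)))
    v <- v[keep, , drop = FALSE]
  }
  # stats::dist scales the available-case sum by p/k, i.e. sqrt(p/k) on
  # the distance -- exactly the pairwise_complete_scaled rule
  D <- as.matrix(stats::dist(v, method = "euclidean"))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
    pair <- rownames(D)[bad[1, ]]
    stop(sprintf("sample pair (%s, %s) shares no observed protein",
                 pair[1], pair[2]), call. = FALSE)
  }
  diag(D) <- 0
  attr(D, "dropped") <- dropped
  D
}

#' Eccentricity lens
#'
#' Per sample, an aggregate of its distances to all other samples:
#' the maximum (`type = "linf"`, the default) or the mean
#' (`type = "l1"`).
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param type `"linf"` or `"l1"`.
#' @return Named numeric vector of lens values.
#' @export
lens_eccentricity <- function(D, type = c("linf", "l1")) {
  type <- match.arg(type)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) == 1) {
    out <- 0
    names(out) <- rownames(D)
    return(out)
  }
  out <- if (type == "linf") apply(D, 1, max) else rowSums(D) / (nrow(D) - 1)
  names(out) <- rownames(D)
  out
}

#' First probabilistic-PCA component lens
#'
#' Latent score of each sample on the first PPCA component, fitted on the
#' (possibly incomplete) matrix with the same engine as [impute_ppca()].
#' The sign is fixed so the scores correlate positively with the
#' per-sample mean observed intensity, making runs comparable.
#'
#' @param m A [protein_matrix()].
#' @param seed Recorded; the fit is deterministic.
#' @return Named numeric vector of lens values.
#' @export
lens_ppca_first <- function(m, seed = NULL) {
  validate_protein_matrix(m)
  if (nrow(m$values) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- if (any(m$mask)) {
    impute_ppca(m, n_components = 1, seed = seed)$completed$values
  } else m$values
  if (max(apply(X, 2, stats::var)) < 1e-24) {
    stop("degenerate (zero-variance) data; PPCA lens undefined", call. = FALSE)
  }
  fit <- ppca_fit(X, 1)
  scores <- drop(ppca_scores(fit, X))
  ref <- rowMeans(m$values, na.rm = TRUE)
  if (stats::var(scores) > 0 && stats::cor(scores, ref) < 0) scores <- -scores
  names(scores) <- m$sample_ids
  scores
}

#' Overlapping 2-D cover of the lens plane
#'
#' Per axis, `n` equal-length intervals spanning `[min, max]` with
#' fractional overlap `g`: length `L = range / (n - (n - 1) g)`, interval
#' `i` (0-based) starting at `min + i L (1 - g)`. The 2-D cover is the
#' cross product. Interval membership is closed on both ends, so the
#' maximum always belongs to the last interval. A zero-range axis
#' collapses to a single interval with a warning.
#'
#' @param lens1_values,lens2_values Finite numeric lens vectors.
#' @param intervals Integer pair `(n1, n2)`.
#' @param overlap Fractional overlap `g` in `[0, 1)`.
#' @return A data.frame with one row per 2-D bin: `bin1`, `bin2`,
#'   `low1`, `high1`, `low2`, `high2`.
#' @export
build_cover <- function(lens1_values, lens2_values, intervals = c(16, 15),
                        overlap = 0.5) {
  stopifnot(all(is.finite(lens1_values)), all(is.finite(lens2_values)),
            length(intervals) == 2, all(intervals >= 1),
            overlap >= 0, overlap < 1)
  iv1 <- axis_intervals(lens1_values, intervals[1], overlap)
  iv2 <- axis_intervals(lens2_values, intervals[2], overlap)
  grid <- expand.grid(i1 = seq_len(nrow(iv1)), i2 = seq_len(nrow(iv2)))
  data.frame(bin1 = grid$i1, bin2 = grid$i2,
             low1 = iv1$low[grid$i1], high1 = iv1$high[grid$i1],
             low2 = iv2$low[grid$i2], high2 = iv2$high[grid$i2])
}

axis_intervals <- function(values, n, g) {
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) {
    if (n > 1) warning("zero lens range on an axis; using a single interval")
    return(data.frame(low = lo, high = hi))
  }
  L <- (hi - lo) / (n - (n - 1) * g)
  start <- lo + (seq_len(n) - 1) * L * (1 - g)
  high <- start + L
  high[n] <- hi  # the max belongs to the last interval by closure
  data.frame(low = start, high = high)
}

#' Cluster the pre-image of one cover bin
#'
#' Single-linkage clustering of the bin's members with the Mapper
#' histogram-gap cut: the dendrogram merge heights are histogrammed into
#' `clustering_bins` equal-width bins over `[0, max height]`, and the
#' dendrogram is cut at the lower edge of the first empty bin that
#' follows an occupied one (a gap in the merge heights). With no such
#' gap -- including the all-heights-equal case -- the bin stays a single
#' cluster.
#'
#' @param member_ids Character ids of the bin members.
#' @param D Full distance matrix (subset internally).
#' @param clustering_bins Histogram bin count, default 10.
#' @return List of character vectors, a partition of `member_ids`.
#' @export
cluster_preimage <- function(member_ids, D, clustering_bins = 10) {
  n <- length(member_ids)
  if (n == 0) return(list())
  if (n == 1) return(list(member_ids))
  Dsub <- D[member_ids, member_ids]
  hc <- stats::hclust(stats::as.dist(Dsub), method = "single")
  h <- hc$height
  cut_h <- gap_cut_height(h, clustering_bins)
  labels <- if (is.null(cut_h)) rep(1L, n) else stats::cutree(hc, h = cut_h)
  split(member_ids, labels)
}

# lower edge of the first empty histogram bin following an occupied one;
# NULL when the merge heights show no gap
gap_cut_height <- function(heights, n_bins) {
  mx <- max(heights)
  if (mx <= 0 || n_bins < 2) return(NULL)
  width <- mx / n_bins
  idx <- pmin(floor(heights / width), n_bins - 1) + 1
  occupied <- tabulate(idx, nbins = n_bins) > 0
  first_occ <- which(occupied)[1]
  gaps <- which(!occupied & seq_len(n_bins) > first_occ)
  if (!length(gaps)) return(NULL)
  (gaps[1] - 1) * width
}

#' Build the Mapper graph of a protein matrix
#'
#' Composes the Mapper pipeline: distance matrix (respecting the missing
#' -value policy), the two lens vectors, the overlapping 2-D cover,
#' single-linkage clustering of each bin's pre-image, and the nerve
#' graph: one node per cluster, one edge per pair of nodes sharing at
#' least one sample. Deterministic given the seed (the seed only touches
#' engines that are themselves stochastic; the default lenses are
#' deterministic).
#'
#' @param m A [protein_matrix()].
#' @param cfg A [mapper_config()].
#' @param seed Integer seed, recorded and passed to the lens engines.
#' @return A `MapperGraph`: list with `nodes` (list of
#'   `list(id, members, bin)`), `edges` (2-column character matrix),
#'   `node_enrichment` (NA until [enrich_missingness()]), `communities`
#'   (NA until [detect_communities()]), `lens` (per-sample lens table),
#'   `summary` (`n_nodes`, `n_edges`, `n_connected_components`,
#'   `modularity`), `config`, `seed`.
#' @export
build_mapper <- function(m, cfg = mapper_config(), seed = NULL) {
  stopifnot(inherits(cfg, "MapperConfig"))
  validate_protein_matrix(m)
  if (nrow(m$values) == 1) {
    nodes <- list(list(id = "n1", members = m$sample_ids, bin = c(1L, 1L)))
    return(new_mapper_graph(nodes, matrix(character(0), 0, 2), m$sample_ids,
                            data.frame(sample_id = m$sample_ids,
                                       lens1 = 0, lens2 = 0),
                            cfg, seed))
  }
  D <- distance_matrix(m, cfg$missing_policy)
  ids <- rownames(D)
  msub <- if (length(attr(D, "dropped"))) subset_matrix(m, samples = ids) else m
  lens_of <- function(name) {
    switch(name,
      l_infinity_eccentricity = lens_eccentricity(D, "linf"),
      l1_eccentricity = lens_eccentricity(D, "l1"),
      ppca_first_component = lens_ppca_first(msub, seed = seed))
  }
  l1 <- lens_of(cfg$lens1)
  l2 <- lens_of(cfg$lens2)
  cover <- build_cover(l1, l2, cfg$intervals, cfg$overlap)
  nodes <- list()
  for (b in seq_len(nrow(cover))) {
    inbin <- ids[l1 >= cover$low1[b] & l1 <= cover$high1[b] &
                 l2 >= cover$low2[b] & l2 <= cover$high2[b]]
    if (!length(inbin)) next
    clusters <- cluster_preimage(inbin, D, cfg$clustering_bins)
    # deterministic ordering: by first member's position in the id list
    clusters <- clusters[order(vapply(clusters,
                                      function(cl) min(match(cl, ids)), 1))]
    seen <- character(0)
    for (cl in clusters) {
      key <- paste(sort(cl), collapse = "\r")
      if (key %in% seen) next  # identical member sets within a bin collapse
      seen <- c(seen, key)
      nodes[[length(nodes) + 1]] <- list(
        id = paste0("n", length(nodes) + 1),
        members = cl,
        bin = c(cover$bin1[b], cover$bin2[b]))
    }
  }
  edges <- nerve_edges(nodes)
  lens_tab <- data.frame(sample_id = ids, lens1 = unname(l1),
                         lens2 = unname(l2))
  new_mapper_graph(nodes, edges, ids, lens_tab, cfg, seed)
}

nerve_edges <- function(nodes) {
  k <- length(nodes)
  out <- list()
  if (k >= 2) {
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        if (length(intersect(nodes[[u]]$members, nodes[[v]]$members))) {
          out[[length(out) + 1]] <- c(nodes[[u]]$id, nodes[[v]]$id)
        }
      }
    }
  }
  if (!length(out)) return(matrix(character(0), 0, 2))
  do.call(rbind, out)
}

new_mapper_graph <- function(nodes, edges, sample_universe, lens_tab, cfg,
                             seed) {
  g <- structure(list(
    nodes = nodes, edges = edges,
    node_enrichment = stats::setNames(rep(NA_real_, length(nodes)),
                                      vapply(nodes, `[[`, "", "id")),
    communities = stats::setNames(rep(NA_integer_, length(nodes)),
                                  vapply(nodes, `[[`, "", "id")),
    sample_universe = sample_universe,
    lens = lens_tab,
    summary = list(n_nodes = length(nodes), n_edges = nrow(edges),
                   n_connected_components = NA_integer_,
                   modularity = NA_real_, community_method = NA_character_),
    config = cfg, seed = seed), class = "MapperGraph")
  g$summary$n_connected_components <-
    if (length(nodes)) igraph::count_components(as_igraph(g)) else 0L
  g
}

#' Convert a MapperGraph to an igraph object
#'
#' Node attributes carry the member lists (semicolon-joined), member
#' counts, enrichment and community labels, so the export is
#' self-contained.
#'
#' @param g A `MapperGraph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "MapperGraph"))
  ids <- vapply(g$nodes, `[[`, "", "id")
  ig <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(matrix(match(g$edges, ids), ncol = 2)))
  }
  ig <- igraph::set_vertex_attr(ig, "members", value =
    vapply(g$nodes, function(nd) paste(nd$members, collapse = ";"), ""))
  ig <- igraph::set_vertex_attr(ig, "size", value =
    vapply(g$nodes, function(nd) length(nd$members), 1L))
  ig <- igraph::set_vertex_attr(ig, "enrichment", value =
    unname(g$node_enrichment))
  ig <- igraph::set_vertex_attr(ig, "community", value =
    unname(g$communities))
  ig
}

#' @export
print.MapperGraph <- function(x, ...) {
  cat(sprintf("MapperGraph: %d nodes, %d edges, %d connected component(s)\n",
              x$summary$n_nodes, x$summary$n_edges,
              x$summary$n_connected_components))
  if (!is.na(x$summary$modularity)) {
    cat(sprintf("  communities: %d (modularity %.4f, %s)\n",
                length(unique(x$communities)), x$summary$modularity,
                x$summary$community_method))
  }
  invisible(x)
}

#' Colour the Mapper nodes by mean missingness
#'
#' Sets each node's enrichment to the mean per-sample missing percentage
#' of its members, taken from a [profile_missingness()] of the
#' NON-imputed matrix.
#'
#' @param g A `MapperGraph`.
#' @param profile A `MissingnessProfile` covering every node member.
#' @return `g` with `node_enrichment` filled (percent scale).
#' @export
enrich_missingness <- function(g, profile) {
  stopifnot(inherits(g, "MapperGraph"), inherits(profile, "MissingnessProfile"))
  fr <- profile$per_sample_fraction
  for (nd in g$nodes) {
    absent <- setdiff(nd$members, names(fr))
    if (length(absent)) {
      stop(sprintf("no missingness profile entry for sample(s): %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    g$node_enrichment[nd$id] <- 100 * mean(fr[nd$members])
  }
  g
}

#' Detect communities in a Mapper graph
#'
#' Modularity-maximising partition of the nodes: exact optimisation
#' (integer programming over all partitions) for graphs of at most
#' `exact_limit` nodes, greedy agglomerative modularity otherwise; the
#' method used is recorded in the summary. An edgeless graph puts every
#' node in its own community with modularity defined as 0.
#'
#' @param g A `MapperGraph` with at least one node.
#' @param exact_limit Largest node count for the exact search, default 12.
#' @return `g` with `communities` labels and `summary$modularity` set.
#' @export
detect_communities <- function(g, exact_limit = 12) {
  stopifnot(inherits(g, "MapperGraph"))
  if (!length(g$nodes)) stop("graph has no nodes", call. = FALSE)
  ig <- as_igraph(g)
  if (nrow(g$edges) == 0) {
    g$communities[] <- seq_along(g$nodes)
    g$summary$modularity <- 0
    g$summary$community_method <- "singletons (edgeless)"
    return(g)
  }
  if (length(g$nodes) <= exact_limit) {
    cm <- igraph::cluster_optimal(ig)
    method <- "exact"
  } else {
    cm <- igraph::cluster_fast_greedy(ig)
    method <- "greedy"
  }
  g$communities[] <- as.integer(igraph::membership(cm))
  g$summary$modularity <- igraph::modularity(ig, igraph::membership(cm))
  g$summary$community_method <- method
  g
}

#' Compare the topologies of two Mapper graphs
#'
#' Summarises both graphs and scores the agreement of the sample
#' partitions they induce (each sample assigned to its largest containing
#' node, ties to the earlier node) with the adjusted Rand index.
#'
#' @param g_non_imputed,g_imputed `MapperGraph`s over the same samples.
#' @return List with `summary_non_imputed`, `summary_imputed`,
#'   `n_shared_samples` and `adjusted_rand_index` in `[-1, 1]`.
#' @export
compare_topologies <- function(g_non_imputed, g_imputed) {
  stopifnot(inherits(g_non_imputed, "MapperGraph"),
            inherits(g_imputed, "MapperGraph"))
  p1 <- sample_partition(g_non_imputed)
  p2 <- sample_partition(g_imputed)
  shared <- intersect(names(p1), names(p2))
  if (!length(shared)) stop("the two graphs share no samples", call. = FALSE)
  if (length(shared) < length(union(names(p1), names(p2)))) {
    message(sprintf("comparing on the %d shared samples", length(shared)))
  }
  list(summary_non_imputed = g_non_imputed$summary,
       summary_imputed = g_imputed$summary,
       n_shared_samples = length(shared),
       adjusted_rand_index =
         mclust::adjustedRandIndex(p1[shared], p2[shared]))
}

# each sample's largest containing node (ties -> earliest node)
sample_partition <- function(g) {
  best <- stats::setNames(rep(NA_character_, length(g$sample_universe)),
                          g$sample_universe)
  best_size <- stats::setNames(rep(-1L, length(g$sample_universe)),
                               g$sample_universe)
  for (nd in g$nodes) {
    sz <- length(nd$members)
    upd <- nd$members[best_size[nd$members] < sz]
    best[upd] <- nd$id
    best_size[upd] <- sz
  }
  best[!is.na(best)]
}

#' Write a MapperGraph to GraphML and a JSON node table
#'
#' @param g A `MapperGraph`.
#' @param graphml_path Output GraphML file.
#' @param json_path Optional JSON node-table path (members, bin,
#'   enrichment, community per node).
#' @return `graphml_path`, invisibly.
#' @export
write_mapper_graph <- function(g, graphml_path, json_path = NULL) {
  ig <- as_igraph(g)
  igraph::write_graph(ig, graphml_path, format = "graphml")
  if (!is.null(json_path)) {
    tab <- lapply(g$nodes, function(nd) {
      list(id = nd$id, members = nd$members, bin = nd$bin,
           enrichment = unname(g$node_enrichment[nd$id]),
           community = unname(g$communities[nd$id]))
    })
    jsonlite::write_json(list(summary = g$summary, nodes = tab), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(graphml_path)
}

#' Plot a Mapper graph with enrichment colouring
#'
#' Seeded force-directed layout; node colour encodes missingness
#' enrichment (blue low, red high), node size the member count. The
#' layout is cosmetic and not part of any equality contract.
#'
#' @param g A `MapperGraph`.
#' @param path Optional PNG path.
#' @param seed Layout seed, default 1.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_mapper <- function(g, path = NULL, seed = 1, main = "Mapper graph") {
  ig <- as_igraph(g)
  enr <- g$node_enrichment
  col <- if (all(is.na(enr))) rep("grey", length(enr)) else {
    pal <- grDevices::colorRampPalette(c("steelblue", "white", "firebrick"))(100)
    rng <- range(enr, na.rm = TRUE)
    idx <- if (diff(rng) == 0) rep(50L, length(enr)) else {
      pmax(1L, pmin(100L, as.integer(1 + 99 * (enr - rng[1]) / diff(rng))))
    }
    pal[idx]
  }
  sizes <- vapply(g$nodes, function(nd) length(nd$members), 1L)
  draw <- function() {
    set.seed(seed)
    lay <- igraph::layout_with_fr(ig)
    igraph::plot.igraph(ig, layout = lay, vertex.color = col,
                        vertex.size = 5 + 15 * sizes / max(sizes),
                        vertex.label.cex = 0.6, main = main)
  }
  render_png(draw, path, width = 800, height = 800)
}
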
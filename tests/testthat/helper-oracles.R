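# Independent brute-force oracles, coded directly from the definitions and
# kept free of the package's own code paths.

# KS D as an explicit sup over all ECDF breakpoints
brute_ks_D <- function(x, y) {
  breakpoints <- sort(unique(c(x, y)))
  max(vapply(breakpoints, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, 0))
}

# plain Euclidean distance by loops (complete data only)
brute_dist <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  D
}

# naive agglomerative single linkage returning the n-1 merge heights
brute_single_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- min(D[clusters[[a]], clusters[[b]]])
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# the histogram-gap cut, restated: first empty bin after an occupied one
brute_gap_cut <- function(heights, n_bins) {
  mx <- max(heights)
  if (mx <= 0 || n_bins < 2) return(NULL)
  width <- mx / n_bins
  occ <- rep(FALSE, n_bins)
  for (h in heights) occ[min(floor(h / width), n_bins - 1) + 1] <- TRUE
  started <- FALSE
  for (b in seq_len(n_bins)) {
    if (occ[b]) started <- TRUE
    else if (started) return((b - 1) * width)
  }
  NULL
}

# single-linkage clusters at a height cut = connected components of the
# threshold graph (edges where distance <= cut)
brute_cut_clusters <- function(ids, D, cut_h) {
  n <- length(ids)
  if (is.null(cut_h)) return(list(ids))
  adj <- D[ids, ids, drop = FALSE] <= cut_h
  label <- rep(0L, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (label[v] > 0) next
      label[v] <- comp
      queue <- c(queue, which(adj[v, ] & label == 0))
    }
  }
  split(ids, label)
}

# full brute-force Mapper on a complete matrix with eccentricity lenses
brute_mapper <- function(X, intervals, overlap, clustering_bins) {
  ids <- rownames(X)
  D <- brute_dist(X)
  l1 <- apply(D, 1, max)                      # L-infinity eccentricity
  l2 <- rowSums(D) / (nrow(D) - 1)            # L1 (mean) eccentricity
  axis <- function(v, n, g) {
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) return(cbind(low = lo, high = hi))
    L <- (hi - lo) / (n - (n - 1) * g)
    starts <- lo + (seq_len(n) - 1) * L * (1 - g)
    highs <- starts + L
    highs[n] <- hi  # max value joins the last interval by closure
    cbind(low = starts, high = highs)
  }
  a1 <- axis(l1, intervals[1], overlap)
  a2 <- axis(l2, intervals[2], overlap)
  node_sets <- list()
  for (j in seq_len(nrow(a2))) {
    for (i in seq_len(nrow(a1))) {
      members <- ids[l1 >= a1[i, "low"] & l1 <= a1[i, "high"] &
                     l2 >= a2[j, "low"] & l2 <= a2[j, "high"]]
      if (!length(members)) next
      clusters <- if (length(members) == 1) list(members) else {
        heights <- brute_single_linkage_heights(
          D[members, members, drop = FALSE])
        brute_cut_clusters(members, D,
                           brute_gap_cut(heights, clustering_bins))
      }
      for (cl in clusters) {
        node_sets[[length(node_sets) + 1]] <- sort(cl)
      }
    }
  }
  edges <- character(0)
  if (length(node_sets) >= 2) {
    for (u in seq_len(length(node_sets) - 1)) {
      for (v in (u + 1):length(node_sets)) {
        if (length(intersect(node_sets[[u]], node_sets[[v]]))) {
          key <- sort(c(paste(node_sets[[u]], collapse = ","),
                        paste(node_sets[[v]], collapse = ",")))
          edges <- c(edges, paste(key, collapse = "|"))
        }
      }
    }
  }
  list(node_keys = sort(vapply(node_sets, paste, "", collapse = ",")),
       edge_keys = sort(unique(edges)))
}

# canonical node/edge keys of a package MapperGraph, for oracle comparison
mapper_keys <- function(g) {
  node_sets <- lapply(g$nodes, function(nd) sort(nd$members))
  names(node_sets) <- vapply(g$nodes, `[[`, "", "id")
  edge_keys <- if (nrow(g$edges)) {
    apply(g$edges, 1, function(e) {
      paste(sort(c(paste(node_sets[[e[1]]], collapse = ","),
                   paste(node_sets[[e[2]]], collapse = ","))), collapse = "|")
    })
  } else character(0)
  list(node_keys = sort(unname(vapply(node_sets, paste, "", collapse = ","))),
       edge_keys = sort(unique(unname(edge_keys))))
}

# all set partitions of 1..n as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1))
    }
  }
  recurse(integer(0), 1L)
  out
}

# maximum modularity of an igraph over every node partition
brute_max_modularity <- function(ig) {
  parts <- all_partitions(igraph::vcount(ig))
  max(vapply(parts, function(p) igraph::modularity(ig, p), 0))
}
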
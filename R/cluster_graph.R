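# Cell-cluster graph: nuclei are grouped into local aggregates by flat-kernel
# mean shift on their centroids; cluster centroids become graph nodes and two
# clusters are linked when their separation d satisfies d^(-alpha) >= r.
# The 26 descriptors summarize the coarse, macro-level arrangement of these
# aggregates, complementing the per-nucleus global graphs. Graph metrics are
# computed directly from the adjacency / shortest-path matrices (the graphs
# have tens of nodes at most).

#' Cluster-graph configuration
#'
#' @param bandwidth Flat-kernel mean-shift bandwidth (px).
#' @param alpha Exponent of the decaying edge rule.
#' @param r Edge threshold: clusters u, v are linked iff d(u,v)^(-alpha) >= r,
#'   i.e. d <= r^(-1/alpha). The default (alpha = 0.5, r = 0.065, link radius
#'   ~237 px) links a minority (~10%) of cluster pairs at the default phantom
#'   density.
#' @export
cluster_graph_config <- function(bandwidth = 40, alpha = 0.5, r = 0.065) {
  stopifnot(bandwidth > 0, alpha > 0, r > 0)
  list(bandwidth = bandwidth, alpha = alpha, r = r)
}

#' Flat-kernel mean shift on 2-D points
#' @keywords internal
mean_shift_modes <- function(X, bandwidth, max_iter = 300, tol = 1e-4) {
  M <- X
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(M^2), rowSums(X^2), "+") - 2 * M %*% t(X)
    A <- D2 <= bandwidth^2
    Mnew <- (A %*% X) / rowSums(A)
    if (max(abs(Mnew - M)) < tol) { M <- Mnew; break }
    M <- Mnew
  }
  M
}

#' Build the cell-cluster graph
#'
#' @param ns A [nuclei_set()].
#' @param config A [cluster_graph_config()].
#' @return Object of class `cluster_graph`: `clusters` (list of
#'   `list(members, centroid)`), `edges` (data.frame from/to/length) and
#'   `image_size`. Deterministic for fixed input and config.
#' @export
build_cluster_graph <- function(ns, config = cluster_graph_config()) {
  stopifnot(inherits(ns, "nuclei_set"), length(ns$nuclei) >= 1)
  X <- centroids(ns)
  n <- nrow(X)
  if (n == 1) {
    assign <- 1L
  } else {
    M <- mean_shift_modes(X, config$bandwidth)
    # merge modes within bandwidth/2, greedily in point order (deterministic)
    assign <- integer(n)
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      if (nrow(centers) > 0) {
        d2 <- (centers[, 1] - M[i, 1])^2 + (centers[, 2] - M[i, 2])^2
        j <- which(d2 <= (config$bandwidth / 2)^2)
        if (length(j) > 0) { assign[i] <- j[1]; next }
      }
      centers <- rbind(centers, M[i, ])
      assign[i] <- nrow(centers)
    }
  }
  ids <- vapply(ns$nuclei, function(nu) nu$nucleus_id, character(1))
  k <- max(assign)
  clusters <- lapply(seq_len(k), function(c) {
    members <- which(assign == c)
    list(members = ids[members],
         centroid = colMeans(X[members, , drop = FALSE]))
  })
  cc <- t(vapply(clusters, function(cl) cl$centroid, numeric(2)))
  edges <- data.frame(from = integer(0), to = integer(0), length = numeric(0))
  if (k >= 2) {
    d_link <- config$r^(-1 / config$alpha)
    pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
    d <- sqrt((cc[pr[, 1], 1] - cc[pr[, 2], 1])^2 + (cc[pr[, 1], 2] - cc[pr[, 2], 2])^2)
    keep <- d <= d_link
    edges <- data.frame(from = pr[keep, 1], to = pr[keep, 2], length = d[keep])
  }
  structure(list(clusters = clusters, edges = edges,
                 image_size = ns$image_size),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("<cluster_graph>", length(x$clusters), "clusters,", nrow(x$edges), "edges\n")
  invisible(x)
}

# All-pairs shortest-path matrix (unweighted) by repeated BFS over the
# adjacency matrix; Inf between components.
#' @keywords internal
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s; lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- lev
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Node-weight-averaged eccentricity / diameter / radius / mean path length and
# central-point count, per connected component, from a shortest-path matrix.
#' @keywords internal
path_summary <- function(D) {
  n <- nrow(D)
  if (n == 0) {
    return(c(avg_ecc = 0, diam = 0, rad = 0, apl = 0, n_central = 0))
  }
  member <- integer(n); comp <- 0L
  for (i in seq_len(n)) {
    if (member[i] == 0) {
      comp <- comp + 1L
      member[is.finite(D[i, ])] <- comp
    }
  }
  ecc <- numeric(n); diam <- 0; rad <- 0; apl <- 0; n_central <- 0
  for (ci in seq_len(comp)) {
    vs <- which(member == ci)
    wgt <- length(vs) / n
    if (length(vs) == 1) {
      e <- 0; d <- 0; r <- 0; a <- 0
      n_central <- n_central + 1
    } else {
      sub <- D[vs, vs, drop = FALSE]
      e <- apply(sub, 1, max)
      d <- max(e); r <- min(e)
      a <- mean(sub[upper.tri(sub)])
      n_central <- n_central + sum(e == r)
    }
    ecc[vs] <- e
    diam <- diam + wgt * d; rad <- rad + wgt * r; apl <- apl + wgt * a
  }
  c(avg_ecc = mean(ecc), diam = diam, rad = rad, apl = apl,
    n_central = n_central, n_components = comp)
}

#' Cell-cluster graph features (26)
#'
#' Topological and spatial descriptors of the cluster graph: counts, degrees,
#' eccentricity/diameter/radius (also over the subgraph induced by the top 90%
#' of nodes by degree, ties broken by index), average path length, three
#' clustering coefficients (C = mean local transitivity with degree-<2 nodes
#' contributing 0; D = mean closed-neighborhood density
#' (k_i + E_i) / C(k_i + 1, 2); E = global transitivity, 3 x triangles over
#' connected triples), component structure, central points (nodes whose
#' eccentricity equals their component's radius), edge-length moments
#' (skewness/kurtosis as in e1071, type 3), and cluster-size statistics.
#' Path-type metrics are computed per connected component and
#' node-weight-averaged; an edgeless graph reports 0 for path/eccentricity
#' metrics by convention.
#'
#' @param cg A `cluster_graph` from [build_cluster_graph()].
#' @param image_size Optional (width, height); defaults to the one stored in `cg`.
#' @return Named numeric vector of length 26, in registry order.
#' @export
cluster_graph_features <- function(cg, image_size = cg$image_size) {
  stopifnot(inherits(cg, "cluster_graph"), length(cg$clusters) >= 1)
  reg <- feature_registry()
  nm <- reg$name[reg$category == "graph_cluster"]
  out <- stats::setNames(rep(0, length(nm)), nm)
  n <- length(cg$clusters)
  A <- matrix(0L, n, n)
  if (nrow(cg$edges) > 0) {
    A[cbind(cg$edges$from, cg$edges$to)] <- 1L
    A[cbind(cg$edges$to, cg$edges$from)] <- 1L
  }
  deg <- rowSums(A)
  D <- bfs_distances(A)
  pm <- path_summary(D)

  out["graph_cluster.node_count"] <- n
  out["graph_cluster.edge_count"] <- nrow(cg$edges)
  out["graph_cluster.avg_degree"] <- mean(deg)
  out["graph_cluster.avg_eccentricity"] <- pm["avg_ecc"]
  out["graph_cluster.diameter"] <- pm["diam"]
  out["graph_cluster.radius"] <- pm["rad"]

  keep_n <- ceiling(0.9 * n)
  top <- sort(order(-deg, seq_len(n))[seq_len(keep_n)])
  A90 <- A[top, top, drop = FALSE]
  pm90 <- path_summary(bfs_distances(A90))
  out["graph_cluster.avg_eccentricity_top90"] <- pm90["avg_ecc"]
  out["graph_cluster.diameter_top90"] <- pm90["diam"]
  out["graph_cluster.radius_top90"] <- pm90["rad"]

  out["graph_cluster.avg_path_length"] <- pm["apl"]

  # clustering coefficients
  loc <- numeric(n); dloc <- numeric(n)
  for (i in seq_len(n)) {
    k <- deg[i]
    if (k >= 1) {
      nb <- which(A[i, ] > 0)
      ei <- sum(A[nb, nb]) / 2
      if (k >= 2) loc[i] <- 2 * ei / (k * (k - 1))
      dloc[i] <- (k + ei) / choose(k + 1, 2)
    }
  }
  out["graph_cluster.clustering_c"] <- mean(loc)
  out["graph_cluster.clustering_d"] <- mean(dloc)
  tri <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(deg * (deg - 1)) / 2
  out["graph_cluster.clustering_e"] <- if (triples > 0) 3 * tri / triples else 0

  csize <- tabulate(apply(is.finite(D), 1, function(r) min(which(r))))
  csize <- csize[csize > 0]
  out["graph_cluster.n_components"] <- pm["n_components"]
  out["graph_cluster.giant_ratio"] <- max(csize) / n
  out["graph_cluster.pct_isolated"] <- 100 * sum(deg == 0) / n
  out["graph_cluster.pct_end_nodes"] <- 100 * sum(deg == 1) / n
  out["graph_cluster.n_central_points"] <- pm["n_central"]
  out["graph_cluster.pct_central_points"] <- 100 * pm["n_central"] / n

  el <- cg$edges$length
  if (length(el) >= 1) {
    out["graph_cluster.edge_len_mean"] <- mean(el)
    out["graph_cluster.edge_len_std"] <- if (length(el) > 1) stats::sd(el) else 0
    out["graph_cluster.edge_len_skewness"] <-
      if (length(el) > 2 && stats::sd(el) > 0) e1071::skewness(el) else 0
    out["graph_cluster.edge_len_kurtosis"] <-
      if (length(el) > 3 && stats::sd(el) > 0) e1071::kurtosis(el) else 0
  }
  sizes <- vapply(cg$clusters, function(cl) length(cl$members), numeric(1))
  out["graph_cluster.cluster_size_mean"] <- mean(sizes)
  out["graph_cluster.cluster_size_std"] <- if (n > 1) stats::sd(sizes) else 0
  out["graph_cluster.clusters_per_10kpx"] <-
    n / (as.numeric(image_size[1]) * image_size[2]) * 1e4
  out
}
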
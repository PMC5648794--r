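# Planar geometry over nuclear centroids: Delaunay triangulation
# (Bowyer-Watson), Voronoi cells (dual circumcenter construction) and the
# Euclidean minimum spanning tree. Implemented here because the
# architecture feature family is built directly on these structures.

#' Circumcenter and squared circumradius of a triangle
#' @keywords internal
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(list(center = c(Inf, Inf), r2 = Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. Points strictly inside a triangle's
#' circumcircle invalidate it; cocircular configurations keep an arbitrary but
#' deterministic diagonal.
#'
#' @param pts n x 2 matrix, n >= 3, not all collinear.
#' @return Integer matrix with 3 columns: vertex indices of each triangle.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  ctr <- colMeans(pts)
  span <- max(apply(pts, 2, function(z) diff(range(z))), 1)
  m <- 1000 * span
  super <- rbind(ctr + c(-m, -m), ctr + c(m, -m), ctr + c(0, m))
  P <- rbind(pts, super)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- circumcircle(super[1, ], super[2, ], super[3, ])
  ccx <- cc$center[1]; ccy <- cc$center[2]; r2 <- cc$r2
  eps <- 1e-10 * span^2
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- which((p[1] - ccx)^2 + (p[2] - ccy)^2 < r2 - eps)
    if (length(bad) == 0) {
      # numerically on a circumcircle boundary for all containing triangles;
      # fall back to inclusive test
      bad <- which((p[1] - ccx)^2 + (p[2] - ccy)^2 < r2 + eps)
      if (length(bad) == 0) stop("triangulation failure (degenerate input?)")
    }
    # boundary of the cavity: edges of bad triangles appearing exactly once
    e <- rbind(tris[bad, c(1, 2), drop = FALSE],
               tris[bad, c(2, 3), drop = FALSE],
               tris[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- names(which(table(key) == 1))
    e <- e[key %in% once, , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tris)), bad)
    tris <- tris[keep, , drop = FALSE]
    ccx <- ccx[keep]; ccy <- ccy[keep]; r2 <- r2[keep]
    for (k in seq_len(nrow(e))) {
      newt <- c(e[k, 1], e[k, 2], i)
      cc <- circumcircle(P[newt[1], ], P[newt[2], ], P[newt[3], ])
      tris <- rbind(tris, newt)
      ccx <- c(ccx, cc$center[1]); ccy <- c(ccy, cc$center[2]); r2 <- c(r2, cc$r2)
    }
  }
  keep <- rowSums(tris > n) == 0
  out <- tris[keep, , drop = FALSE]
  dimnames(out) <- NULL
  # canonical ordering for determinism
  out <- t(apply(out, 1, sort))
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

#' Unique undirected edges of a triangulation
#' @keywords internal
triangulation_edges <- function(tris) {
  e <- rbind(tris[, c(1, 2), drop = FALSE],
             tris[, c(2, 3), drop = FALSE],
             tris[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Voronoi cells of a planar point set
#'
#' Dual construction: the cell of a site that is not on the convex hull is the
#' polygon of circumcenters of its incident Delaunay triangles, ordered by
#' angle around the site (the cell is convex and contains its site, so the
#' angular order is the boundary order). Hull sites have unbounded cells and
#' are flagged with empty vertices. Cocircular configurations produce repeated
#' circumcenters, which are collapsed.
#'
#' @param pts n x 2 matrix of sites.
#' @param tris Optional precomputed [delaunay_triangulation()] of `pts`.
#' @return List with one element per site: `list(vertices, bounded)`.
#' @export
voronoi_cells <- function(pts, tris = NULL) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (is.null(tris)) tris <- delaunay_triangulation(pts)
  hull <- grDevices::chull(pts)
  ccs <- t(apply(tris, 1, function(t) {
    circumcircle(pts[t[1], ], pts[t[2], ], pts[t[3], ])$center
  }))
  span <- max(apply(pts, 2, function(z) diff(range(z))), 1)
  lapply(seq_len(n), function(i) {
    if (i %in% hull) {
      return(list(vertices = matrix(numeric(0), 0, 2), bounded = FALSE))
    }
    inc <- which(rowSums(tris == i) > 0)
    v <- ccs[inc, , drop = FALSE]
    ang <- atan2(v[, 2] - pts[i, 2], v[, 1] - pts[i, 1])
    v <- v[order(ang), , drop = FALSE]
    # collapse duplicate consecutive circumcenters (cocircular degeneracies)
    if (nrow(v) > 1) {
      d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
      dup <- rowSums(d^2) < (1e-9 * span)^2
      if (any(dup)) v <- v[!dup, , drop = FALSE]
    }
    if (nrow(v) < 3) return(list(vertices = v, bounded = FALSE))
    list(vertices = v, bounded = TRUE)
  })
}

#' Euclidean minimum spanning tree
#'
#' Prim's algorithm on the complete pairwise-distance graph. Equal-weight ties
#' are broken by lexicographic node index so the tree is deterministic.
#'
#' @param pts n x 2 matrix, n >= 2.
#' @return Data.frame with columns `from`, `to`, `length` (n - 1 rows).
#' @export
mst_edges <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points")
  D <- as.matrix(stats::dist(pts))
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best_d <- D[1, ]; best_from <- rep(1L, n)
  from <- integer(n - 1); to <- integer(n - 1); len <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    # ties: smallest distance, then smallest candidate index (order of which),
    # then smallest source index (maintained by strict < update below)
    v <- cand[which.min(best_d[cand])]
    from[k] <- best_from[v]; to[k] <- v; len[k] <- best_d[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_d
    best_d[upd] <- D[v, upd]
    best_from[upd] <- v
  }
  data.frame(from = pmin(from, to), to = pmax(from, to), length = len)
}
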
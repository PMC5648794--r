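# The 51 global-graph architecture descriptors: statistics of the Voronoi
# diagram, Delaunay triangulation and minimum spanning tree over nuclear
# centroids, plus local-density measurements. Sample (n-1) standard deviations
# are used throughout the package.

#' Disorder statistic
#'
#' `1 - 1 / (1 + sd/mean)`: a bounded coefficient-of-variation transform in
#' [0, 1), zero iff the values are constant, invariant to positive rescaling.
#' A single value, or mean zero, gives 0 by convention.
#'
#' @param values Non-negative numeric vector.
#' @return Scalar in [0, 1).
#' @export
disorder <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) return(NaN)
  m <- mean(values)
  if (m <= 0) return(0)
  s <- if (length(values) < 2) 0 else stats::sd(values)
  1 - 1 / (1 + s / m)
}

# {mean, std, min/max ratio, disorder} of a sample of non-negative values
#' @keywords internal
agg4 <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) return(c(NaN, NaN, NaN, NaN))
  s <- if (length(values) < 2) 0 else stats::sd(values)
  mm <- if (max(values) > 0) min(values) / max(values) else NaN
  c(mean(values), s, mm, disorder(values))
}

#' @keywords internal
agg3 <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) return(c(NaN, NaN, NaN))
  s <- if (length(values) < 2) 0 else stats::sd(values)
  c(mean(values), s, disorder(values))
}

#' Global graph architecture features (51)
#'
#' Voronoi (12): {mean, std, min/max ratio, disorder} of bounded-cell area,
#' perimeter and chord length (distances between consecutive cell vertices,
#' pooled over bounded cells). Delaunay (8): same four aggregates of unique
#' edge (triangle side) length and triangle area. MST (4): aggregates of edge
#' length. Density (27): {mean, std, disorder} of the distance to the 3rd, 5th
#' and 7th nearest neighbor; {mean, std, disorder} of the neighbor count within
#' 10, 20, 30, 40 and 50 px; nuclei count; nuclei per 10^4 px^2; fraction of
#' the image within 40 px of a centroid.
#'
#' Fewer than 4 non-collinear centroids yields all-NaN with a warning; a k-NN
#' feature with fewer than k+1 nuclei is NaN.
#'
#' @param ns A [nuclei_set()].
#' @return Named numeric vector of length 51, in registry order.
#' @export
global_graph_features <- function(ns) {
  reg <- feature_registry()
  nm <- reg$name[reg$category == "graph_global"]
  out <- stats::setNames(rep(NaN, length(nm)), nm)
  pts <- centroids(ns)
  n <- nrow(pts)
  collinear <- function(p) {
    if (nrow(p) < 3) return(TRUE)
    p0 <- sweep(p, 2, p[1, ])
    abs(p0[, 1] * p0[2, 2] - p0[, 2] * p0[2, 1]) < 1e-9
  }
  if (n < 4 || all(collinear(pts))) {
    warning("fewer than 4 non-collinear centroids; global graph features are NaN")
    return(out)
  }

  tris <- tryCatch(delaunay_triangulation(pts), error = function(e) NULL)

  # Voronoi: bounded cells only (dual construction over the triangulation)
  bounded <- list()
  if (!is.null(tris)) {
    vc <- voronoi_cells(pts, tris)
    bounded <- Filter(function(c) c$bounded && nrow(c$vertices) >= 3, vc)
  }
  if (length(bounded) > 0) {
    areas <- vapply(bounded, function(c) polygon_area(c$vertices), numeric(1))
    perims <- vapply(bounded, function(c) polygon_perimeter(c$vertices), numeric(1))
    chords <- unlist(lapply(bounded, function(c) {
      v <- c$vertices
      d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
      sqrt(rowSums(d^2))
    }))
    out[sprintf("graph_global.voronoi.area_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(areas)
    out[sprintf("graph_global.voronoi.perimeter_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(perims)
    out[sprintf("graph_global.voronoi.chord_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(chords)
  }

  # Delaunay
  if (!is.null(tris) && nrow(tris) > 0) {
    ed <- triangulation_edges(tris)
    side <- sqrt(rowSums((pts[ed[, 1], , drop = FALSE] - pts[ed[, 2], , drop = FALSE])^2))
    tarea <- apply(tris, 1, function(t) polygon_area(pts[t, , drop = FALSE]))
    out[sprintf("graph_global.delaunay.side_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(side)
    out[sprintf("graph_global.delaunay.area_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(tarea)
  }

  # MST
  mst <- mst_edges(pts)
  out[sprintf("graph_global.mst.edge_%s", c("mean", "std", "minmax_ratio", "disorder"))] <- agg4(mst$length)

  # Density
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  Ds <- apply(D, 1, sort)  # columns = per-point sorted neighbor distances
  for (k in c(3, 5, 7)) {
    v <- if (n >= k + 1) Ds[k, ] else rep(NaN, 3)
    out[sprintf("graph_global.density.dist_knn%d_%s", k, c("mean", "std", "disorder"))] <-
      if (n >= k + 1) agg3(Ds[k, ]) else c(NaN, NaN, NaN)
  }
  for (r in c(10, 20, 30, 40, 50)) {
    cnt <- rowSums(D <= r)
    out[sprintf("graph_global.density.neighbors_r%d_%s", r, c("mean", "std", "disorder"))] <- agg3(cnt)
  }
  w <- ns$image_size[1]; h <- ns$image_size[2]
  out["graph_global.density.nuclei_count"] <- n
  out["graph_global.density.nuclei_per_10kpx"] <- n / (w * h) * 1e4
  out["graph_global.density.area_fraction_r40"] <- disk_cover_fraction(pts, w, h, 40)
  out
}

# Fraction of pixel centres within radius r of any centroid.
#' @keywords internal
disk_cover_fraction <- function(pts, w, h, r) {
  covered <- matrix(FALSE, h, w)
  ri <- ceiling(r)
  for (i in seq_len(nrow(pts))) {
    cx <- pts[i, 1]; cy <- pts[i, 2]
    x0 <- max(0L, floor(cx - ri)); x1 <- min(w - 1L, ceiling(cx + ri))
    y0 <- max(0L, floor(cy - ri)); y1 <- min(h - 1L, ceiling(cy + ri))
    if (x1 < x0 || y1 < y0) next
    gx <- x0:x1; gy <- y0:y1
    dx2 <- (gx - cx)^2; dy2 <- (gy - cy)^2
    hit <- outer(dy2, dx2, "+") <= r^2
    covered[gy + 1L, gx + 1L] <- covered[gy + 1L, gx + 1L] | hit
  }
  mean(covered)
}
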
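#' Canonical registry of the 242 histomorphometric descriptors
#'
#' The registry is the single source of truth for feature naming and ordering.
#' Every extractor emits exactly the registry names of its category, in
#' registry order, so that feature tables, selection results and fitted models
#' are always column-compatible. Names are dotted lowercase paths prefixed by
#' the category: `graph_global` (51), `graph_cluster` (26), `shape` (100),
#' `orientation` (39) and `texture` (26).
#'
#' @return A data.frame with columns `name` and `category`, 242 rows, in the
#'   canonical order. Deterministic: repeated calls return identical objects.
#' @examples
#' reg <- feature_registry()
#' table(reg$category)
#' @export
feature_registry <- function() {
  aggr4 <- c("mean", "std", "minmax_ratio", "disorder")

  vor <- as.vector(t(outer(c("area", "perimeter", "chord"), aggr4,
                           function(a, b) paste0("graph_global.voronoi.", a, "_", b))))
  del <- as.vector(t(outer(c("side", "area"), aggr4,
                           function(a, b) paste0("graph_global.delaunay.", a, "_", b))))
  mst <- paste0("graph_global.mst.edge_", aggr4)
  aggr3 <- c("mean", "std", "disorder")
  knn <- as.vector(t(outer(c(3, 5, 7), aggr3,
                           function(a, b) paste0("graph_global.density.dist_knn", a, "_", b))))
  nbr <- as.vector(t(outer(c(10, 20, 30, 40, 50), aggr3,
                           function(a, b) paste0("graph_global.density.neighbors_r", a, "_", b))))
  dens <- paste0("graph_global.density.",
                 c("nuclei_count", "nuclei_per_10kpx", "area_fraction_r40"))
  graph_global <- c(vor, del, mst, knn, nbr, dens)

  graph_cluster <- paste0("graph_cluster.", c(
    "node_count", "edge_count", "avg_degree",
    "avg_eccentricity", "diameter", "radius",
    "avg_eccentricity_top90", "diameter_top90", "radius_top90",
    "avg_path_length",
    "clustering_c", "clustering_d", "clustering_e",
    "n_components", "giant_ratio", "pct_isolated", "pct_end_nodes",
    "n_central_points", "pct_central_points",
    "edge_len_mean", "edge_len_std", "edge_len_skewness", "edge_len_kurtosis",
    "cluster_size_mean", "cluster_size_std", "clusters_per_10kpx"))

  base25 <- c("area", "perimeter", "equiv_diameter", "min_radius", "max_radius",
              "mean_radius", "radius_std", "major_axis", "minor_axis",
              "eccentricity", "compactness", "solidity", "extent", "convexity",
              "bending_energy", paste0("fsd", 1:10))
  shape <- as.vector(t(outer(base25, c("mean", "std", "median", "minmax_ratio"),
                             function(a, b) paste0("shape.", a, ".", b))))

  stats13 <- cooccurrence_stat_names()
  orientation <- as.vector(t(outer(stats13, c("mean", "median", "std"),
                                   function(a, b) paste0("orientation.", a, ".", b))))
  texture <- as.vector(t(outer(stats13, c("mean", "std"),
                               function(a, b) paste0("texture.", a, ".", b))))

  data.frame(
    name = c(graph_global, graph_cluster, shape, orientation, texture),
    category = rep(c("graph_global", "graph_cluster", "shape", "orientation", "texture"),
                   c(length(graph_global), length(graph_cluster), length(shape),
                     length(orientation), length(texture))),
    stringsAsFactors = FALSE
  )
}

#' Names of the 13 second-order co-occurrence statistics
#'
#' Shared by the orientation-entropy and gray-level texture families.
#' @return Character vector of length 13.
#' @export
cooccurrence_stat_names <- function() {
  c("contrast_energy", "contrast_inv_moment", "contrast_avg", "contrast_var",
    "contrast_entropy", "intensity_avg", "intensity_var", "intensity_entropy",
    "entropy", "energy", "correlation", "info_corr1", "info_corr2")
}

#' Published descriptions of selected features
#'
#' Lookup table mapping canonical registry names to the descriptive phrasing
#' used for the seven most predictive descriptors in the reference study.
#' @return Named character vector (canonical name -> description).
#' @export
feature_descriptions <- function() {
  c(
    "graph_global.voronoi.area_minmax_ratio" =
      "Voronoi: Area Ratio Minimum / Maximum",
    "graph_global.density.neighbors_r40_mean" =
      "Arch: Average Nearest Neighbors in a 40 Pixel Radius",
    "shape.fsd8.minmax_ratio" = "Min/max ratio of Fourier Descriptor 8",
    "shape.fsd4.mean" = "Mean of Fourier Descriptor 4",
    "texture.contrast_var.std" =
      "Haralick standard deviation intensity contrast variance",
    "texture.contrast_energy.std" =
      "Haralick standard deviation intensity contrast energy",
    "texture.contrast_inv_moment.std" =
      "Haralick standard deviation intensity contrast inverse moment"
  )
}

#' Category of each registry feature name
#' @param names Character vector of canonical feature names.
#' @return Character vector of categories.
#' @keywords internal
feature_category <- function(names) {
  reg <- feature_registry()
  idx <- match(names, reg$name)
  if (anyNA(idx)) {
    stop("unknown feature name(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  reg$category[idx]
}
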
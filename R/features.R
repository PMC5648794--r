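#' Feature extraction configuration
#'
#' @param cluster [cluster_graph_config()] controlling the cell-cluster graph.
#' @param orientation_bins Bins for orientation co-occurrence (default 10).
#' @param gray_levels Gray levels for texture co-occurrence (default 16).
#' @export
feature_config <- function(cluster = cluster_graph_config(),
                           orientation_bins = 10L,
                           gray_levels = 16L) {
  list(cluster = cluster, orientation_bins = as.integer(orientation_bins),
       gray_levels = as.integer(gray_levels))
}

#' Extract the full 242-feature histomorphometric vector for one spot
#'
#' Runs all five families — global graph (51), cluster graph (26), shape (100),
#' orientation entropy (39) and gray-level texture (26) — and returns them in
#' registry order. Works identically on watershed output, imported label-mask
#' boundaries, or synthetic ground truth, since all families consume only the
#' boundary polygons (plus the image for texture).
#'
#' @param ns A [nuclei_set()].
#' @param img A [spot_image()]; required for the texture family (`NULL` leaves
#'   texture features NaN).
#' @param config A [feature_config()].
#' @return Named numeric vector of length 242.
#' @export
extract_features <- function(ns, img = NULL, config = feature_config()) {
  stopifnot(inherits(ns, "nuclei_set"))
  reg <- feature_registry()
  out <- stats::setNames(rep(NaN, nrow(reg)), reg$name)
  gg <- suppressWarnings(global_graph_features(ns))
  out[names(gg)] <- gg
  if (length(ns$nuclei) >= 1) {
    cg <- build_cluster_graph(ns, config$cluster)
    cf <- cluster_graph_features(cg)
    out[names(cf)] <- cf
    ofeat <- suppressWarnings(
      orientation_entropy_features(ns, cg, config$orientation_bins))
    out[names(ofeat)] <- ofeat
  }
  sf <- suppressWarnings(shape_features(ns))
  out[names(sf)] <- sf
  if (!is.null(img)) {
    tf <- suppressWarnings(texture_features(img, ns, config$gray_levels))
    out[names(tf)] <- tf
  }
  out
}
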
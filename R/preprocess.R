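# Color normalization and watershed nuclear segmentation.
#
# Normalization is a per-channel monotone spline through 11 matched quantiles
# (deciles) of source and template, a monotone histogram-matching variant that
# removes batch-level stain differences. Segmentation separates a
# hematoxylin-like channel by fixed H&E color-deconvolution vectors, smooths,
# thresholds (Otsu), and splits touching nuclei by marker-controlled growth on
# the distance transform.

#' Fit a monotone spline color-normalization map
#'
#' For each RGB channel, the deciles of the source are mapped onto the deciles
#' of the template by a monotone piecewise-cubic (Hyman-filtered) spline; the
#' resulting 0-255 lookup table is clamped and made non-decreasing. A constant
#' source channel yields an identity mapping with a warning.
#'
#' @param template,source [spot_image()] objects.
#' @return Object of class `normalization_map`: a 256 x 3 lookup table plus
#'   `template_id`.
#' @export
fit_normalization <- function(template, source) {
  stopifnot(inherits(template, "spot_image"), inherits(source, "spot_image"))
  probs <- seq(0, 1, by = 0.1)
  lut <- matrix(0L, 256, 3)
  for (ch in 1:3) {
    s <- as.vector(source$pixels[, , ch])
    t <- as.vector(template$pixels[, , ch])
    qs <- stats::quantile(s, probs, names = FALSE, type = 7)
    qt <- stats::quantile(t, probs, names = FALSE, type = 7)
    ux <- !duplicated(qs)
    if (sum(ux) < 2) {
      warning("constant channel ", ch, " in source; using identity mapping")
      lut[, ch] <- 0:255
      next
    }
    x <- qs[ux]
    y <- vapply(x, function(v) mean(qt[qs == v]), numeric(1))
    y <- cummax(y)
    f <- if (sum(ux) >= 3) {
      stats::splinefun(x, y, method = "hyman")
    } else {
      stats::approxfun(x, y, rule = 2)
    }
    v <- f(0:255)
    v[0:255 < x[1]] <- y[1] + (0:255)[0:255 < x[1]] - x[1]
    v[0:255 > x[length(x)]] <- y[length(y)] + (0:255)[0:255 > x[length(x)]] - x[length(x)]
    v <- pmin(pmax(v, 0), 255)
    lut[, ch] <- as.integer(round(cummax(v)))
  }
  structure(list(lut = lut, template_id = template$spot_id),
            class = "normalization_map")
}

#' @rdname fit_normalization
#' @param map A `normalization_map`.
#' @return For `apply_normalization`, the normalized [spot_image()].
#' @export
apply_normalization <- function(map, source) {
  stopifnot(inherits(map, "normalization_map"), inherits(source, "spot_image"))
  px <- source$pixels
  for (ch in 1:3) {
    px[, , ch] <- map$lut[px[, , ch] + 1L, ch]
  }
  spot_image(px, source$spot_id, source$microns_per_pixel)
}

# Fixed H&E color-deconvolution vectors (optical-density space); rows are
# hematoxylin, eosin and their residual, each normalized to unit length.
#' @keywords internal
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2)), r / sqrt(sum(r^2)))
  m
}

#' Hematoxylin channel by color deconvolution
#' @param img A [spot_image()].
#' @return h x w matrix of hematoxylin optical-density concentrations.
#' @export
hematoxylin_channel <- function(img) {
  p <- img$pixels
  od <- -log10((p + 1) / 256)
  d <- dim(p)
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- odm %*% solve(he_stain_matrix())
  matrix(conc[, 1], d[1], d[2])
}

#' Watershed segmentation configuration
#' @param smooth_sigma Gaussian smoothing of the hematoxylin channel (px).
#' @param min_peak_dist Minimum separation of distance-transform peaks (px).
#' @param min_area,max_area Area gate for retained nuclei (px^2).
#' @export
watershed_config <- function(smooth_sigma = 2, min_peak_dist = 10,
                             min_area = 80, max_area = 3000) {
  list(smooth_sigma = smooth_sigma, min_peak_dist = min_peak_dist,
       min_area = min_area, max_area = max_area)
}

#' Watershed nuclear segmentation
#'
#' Pipeline: hematoxylin deconvolution, Gaussian smoothing, Otsu foreground
#' threshold, Euclidean distance transform, peak markers at the configured
#' minimum separation, marker-controlled region growth, contour tracing, area
#' gate. An image with no appreciable hematoxylin contrast yields an empty set.
#'
#' @param img A [spot_image()].
#' @param config A [watershed_config()].
#' @return A [nuclei_set()].
#' @export
segment_watershed <- function(img, config = watershed_config()) {
  stopifnot(inherits(img, "spot_image"))
  h <- hematoxylin_channel(img)
  w <- dim(h)[2]; ht <- dim(h)[1]
  empty <- function() nuclei_set(img$spot_id, list(), c(w, ht))
  if (diff(range(h)) < 0.05) return(empty())
  eh <- EBImage::Image(t(h))  # EBImage dims: (x, y)
  eh <- EBImage::gblur(eh, sigma = config$smooth_sigma)
  rng <- range(EBImage::imageData(eh))
  nh <- (eh - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(nh, range = c(0, 1))
  fg <- nh > thr
  if (sum(fg) < config$min_area) return(empty())
  dist <- EBImage::distmap(fg)
  brush <- EBImage::makeBrush(2 * config$min_peak_dist + 1, shape = "disc")
  dil <- EBImage::dilate(dist, brush)
  peaks <- fg & (EBImage::imageData(dist) >= EBImage::imageData(dil)) &
    (EBImage::imageData(dist) > 1)
  # non-maximum suppression: plateaus of the quantized distance map can leave
  # several co-equal peaks inside one nucleus; keep greedy maxima at the
  # configured separation (ties by scan order for determinism)
  pc <- which(peaks, arr.ind = TRUE)
  if (nrow(pc) == 0) return(empty())
  pv <- EBImage::imageData(dist)[pc]
  ord <- order(-pv, pc[, 1], pc[, 2])
  pc <- pc[ord, , drop = FALSE]
  keep <- logical(nrow(pc))
  for (i in seq_len(nrow(pc))) {
    if (i == 1 || all((pc[keep, 1] - pc[i, 1])^2 + (pc[keep, 2] - pc[i, 2])^2 >=
                      config$min_peak_dist^2)) keep[i] <- TRUE
  }
  pc <- pc[keep, , drop = FALSE]
  seed_mat <- matrix(0L, nrow(peaks), ncol(peaks))
  seed_mat[pc] <- seq_len(nrow(pc))
  seeds <- EBImage::Image(seed_mat, dim = dim(fg))
  labels <- EBImage::propagate(dist, seeds = seeds, mask = fg, lambda = 1e4)
  lm <- t(EBImage::imageData(labels))  # back to (row = y, col = x)
  storage.mode(lm) <- "integer"
  ns <- mask_to_boundaries(lm, spot_id = img$spot_id,
                           min_area = config$min_area, max_area = config$max_area)
  ns
}

# Offset a traced pixel-centre contour outward by half a pixel so the polygon
# covers the full pixel footprint of the object.
#' @keywords internal
offset_contour <- function(v) {
  v <- polygon_ccw(v)
  n <- nrow(v)
  prev <- v[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- v[c(2:n, 1), , drop = FALSE]
  tang <- nxt - prev
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  nrm <- cbind(tang[, 2], -tang[, 1]) / len
  ctr <- colMeans(v)
  # orient normals outward
  outward <- rowSums((v - matrix(ctr, n, 2, byrow = TRUE)) * nrm)
  flip <- sum(outward) < 0
  if (flip) nrm <- -nrm
  v + 0.5 * nrm
}

#' Convert a label mask to nuclear boundaries
#'
#' Import path for segmentations produced elsewhere (e.g. learning-based
#' segmenters exporting label rasters). One polygon per label; contours are
#' traced along object pixels and offset outward by half a pixel so polygon
#' area tracks pixel count within ~5%. Labels with fewer than 8 boundary
#' pixels are dropped with a warning.
#'
#' @param mask Integer matrix (rows = y, cols = x), 0 = background.
#' @param spot_id Identifier for the resulting set.
#' @param min_area,max_area Optional pixel-count gate (NULL disables).
#' @return A [nuclei_set()].
#' @export
mask_to_boundaries <- function(mask, spot_id = "mask", min_area = NULL,
                               max_area = NULL) {
  storage.mode(mask) <- "integer"
  w <- ncol(mask); h <- nrow(mask)
  labs <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(labs) == 0) return(nuclei_set(spot_id, list(), c(w, h)))
  img <- EBImage::Image(t(mask))
  oc <- EBImage::ocontour(img)
  counts <- tabulate(as.vector(mask), nbins = max(labs))
  nuclei <- list()
  for (lb in labs) {
    cnt <- counts[lb]
    if (!is.null(min_area) && cnt < min_area) next
    if (!is.null(max_area) && cnt > max_area) next
    v <- oc[[as.character(lb)]]
    if (is.null(v)) v <- oc[[lb]]
    if (is.null(v) || nrow(unique(v)) < 8) {
      warning("label ", lb, " has fewer than 8 boundary pixels; dropped")
      next
    }
    v <- unique(v)  # ocontour can revisit pixels on thin structures
    v <- offset_contour(v)
    v[, 1] <- pmin(pmax(v[, 1], 0), w - 1e-6)
    v[, 2] <- pmin(pmax(v[, 2], 0), h - 1e-6)
    nb <- tryCatch(nucleus_boundary(sprintf("n%04d", lb), v, validate = FALSE),
                   error = function(e) NULL)
    if (is.null(nb)) {
      warning("label ", lb, " produced a degenerate contour; dropped")
      next
    }
    nuclei[[length(nuclei) + 1]] <- nb
  }
  nuclei_set(spot_id, nuclei, c(w, h))
}
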
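# Polygon primitives shared by the geometry, shape and rendering code.
# Coordinates are 0-based pixel coordinates, x = column, y = row, origin at the
# top-left of the image. Polygons are stored open (no repeated last vertex) and
# in canonical counter-clockwise orientation (positive shoelace sum).

#' Signed polygon area (shoelace)
#' @param v n x 2 matrix of vertices (x, y).
#' @return Signed area; positive for canonical orientation.
#' @keywords internal
polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  0.5 * sum(x * ys - xs * y)
}

#' @keywords internal
polygon_area <- function(v) abs(polygon_signed_area(v))

#' Polygon area-centroid
#' @keywords internal
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' @keywords internal
polygon_perimeter <- function(v) {
  d <- v - v[c(2:nrow(v), 1), ]
  sum(sqrt(rowSums(d^2)))
}

# Proper / improper segment intersection test used by the simplicity check.
# Returns TRUE when segment (p1,p2) and (q1,q2) intersect other than by
# sharing an endpoint.
#' @keywords internal
segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) || on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

#' Test that a polygon is simple (no self-intersections)
#' @keywords internal
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  # reject repeated consecutive vertices
  d <- v - v[c(2:n, 1), ]
  if (any(rowSums(d^2) < 1e-20)) return(FALSE)
  for (i in seq_len(n - 1)) {
    jmax <- if (i == 1) n - 1 else n   # edge n is adjacent to edge 1
    if (i + 2 > jmax) next
    for (j in seq(i + 2, jmax)) {
      p1 <- v[i, ]; p2 <- v[i %% n + 1, ]
      q1 <- v[j, ]; q2 <- v[j %% n + 1, ]
      if (segments_cross(p1, p2, q1, q2)) return(FALSE)
    }
  }
  TRUE
}

#' Canonicalize polygon orientation to counter-clockwise
#' @keywords internal
polygon_ccw <- function(v) {
  if (polygon_signed_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

#' Resample a closed boundary to equal arc-length spacing
#' @param v n x 2 vertex matrix.
#' @param n_points number of output samples.
#' @return n_points x 2 matrix.
#' @keywords internal
polygon_resample <- function(v, n_points = 128L) {
  vc <- rbind(v, v[1, ])
  seg <- sqrt(rowSums((vc[-1, , drop = FALSE] - vc[-nrow(vc), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate boundary: zero length")
  t_out <- seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
  j <- findInterval(t_out, s, rightmost.closed = TRUE)
  j[j > length(seg)] <- length(seg)
  w <- (t_out - s[j]) / seg[j]
  w[!is.finite(w)] <- 0   # zero-length segments
  cbind(vc[j, 1] + w * (vc[j + 1, 1] - vc[j, 1]),
        vc[j, 2] + w * (vc[j + 1, 2] - vc[j, 2]))
}

#' Rasterize a polygon to pixel coordinates
#'
#' Even-odd scanline fill: pixels whose integer-centre coordinate lies inside
#' the polygon.
#' @param v vertex matrix.
#' @return Two-column integer matrix of (x, y) pixel coordinates, possibly empty.
#' @keywords internal
polygon_pixels <- function(v) {
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
  ylo <- max(0, ceiling(min(y1))); yhi <- floor(max(y1))
  if (yhi < ylo) return(cbind(x = integer(0), y = integer(0)))
  ys <- ylo:yhi
  # all edge x scanline crossings at once (half-open rule: each row gets an
  # even crossing count, so consecutive sorted crossings pair into intervals)
  Y <- matrix(ys, n, length(ys), byrow = TRUE)
  H <- (y1 <= Y & y2 > Y) | (y2 <= Y & y1 > Y)
  idx <- which(H, arr.ind = TRUE)
  if (nrow(idx) == 0) return(cbind(x = integer(0), y = integer(0)))
  e <- idx[, 1]; r <- idx[, 2]
  cx <- x1[e] + (ys[r] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
  o <- order(r, cx)
  r <- r[o]; cx <- cx[o]
  odd <- seq(1, length(cx) - 1, by = 2)
  xa <- ceiling(cx[odd]); xb <- ceiling(cx[odd + 1]) - 1
  yv <- ys[r[odd]]
  len <- xb - xa + 1
  keep <- len > 0
  xa <- xa[keep]; len <- len[keep]; yv <- yv[keep]
  if (length(len) == 0) return(cbind(x = integer(0), y = integer(0)))
  xs <- sequence(len) - 1L + rep(as.integer(xa), len)
  out <- cbind(x = xs, y = rep(as.integer(yv), len))
  out[out[, 1] >= 0, , drop = FALSE]
}

#' Separable Gaussian blur of a matrix (replicated edges)
#' @keywords internal
gaussian_blur_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  pad <- function(M) rbind(M[rep(1L, r), , drop = FALSE], M,
                           M[rep(nrow(M), r), , drop = FALSE])
  a <- stats::filter(pad(m), k, sides = 2)
  a <- a[(r + 1):(r + nrow(m)), , drop = FALSE]
  b <- stats::filter(pad(t(a)), k, sides = 2)
  t(b[(r + 1):(r + ncol(m)), , drop = FALSE])
}

#' Construct a nucleus boundary object
#'
#' @param nucleus_id Identifier string.
#' @param vertices n x 2 numeric matrix of (x, y) vertices, n >= 8, forming a
#'   simple polygon with positive area.
#' @param validate Run the (O(n^2)) simplicity check. Generators that construct
#'   star-shaped polygons by design may skip it.
#' @return An object of class `nucleus_boundary` with fields `nucleus_id`,
#'   `vertices` (counter-clockwise) and `centroid` (polygon area-centroid).
#' @export
nucleus_boundary <- function(nucleus_id, vertices, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) >= 2 &&
      sum((vertices[1, ] - vertices[nrow(vertices), ])^2) < 1e-20) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]  # drop closing vertex
  }
  if (nrow(vertices) < 8) {
    stop("nucleus '", nucleus_id, "': polygon has fewer than 8 vertices")
  }
  if (validate && !polygon_is_simple(vertices)) {
    stop("nucleus '", nucleus_id, "': polygon is self-intersecting or degenerate")
  }
  if (polygon_area(vertices) <= 0) {
    stop("nucleus '", nucleus_id, "': polygon has non-positive area")
  }
  vertices <- polygon_ccw(vertices)
  structure(list(nucleus_id = as.character(nucleus_id),
                 vertices = unname(vertices),
                 centroid = polygon_centroid(vertices)),
            class = "nucleus_boundary")
}

#' Construct a nuclei set for one TMA spot
#'
#' @param spot_id Spot identifier.
#' @param nuclei List of [nucleus_boundary()] objects.
#' @param image_size Integer (width, height).
#' @return Object of class `nuclei_set`.
#' @export
nuclei_set <- function(spot_id, nuclei, image_size) {
  image_size <- as.integer(image_size)
  ids <- vapply(nuclei, function(n) n$nucleus_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate nucleus_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (n in nuclei) {
    v <- n$vertices
    if (any(v[, 1] < 0 | v[, 1] >= image_size[1] | v[, 2] < 0 | v[, 2] >= image_size[2])) {
      stop("nucleus '", n$nucleus_id, "': vertices outside image bounds")
    }
  }
  structure(list(spot_id = as.character(spot_id), nuclei = nuclei,
                 image_size = image_size),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat("<nuclei_set> spot", x$spot_id, "-", length(x$nuclei), "nuclei,",
      x$image_size[1], "x", x$image_size[2], "px\n")
  invisible(x)
}

#' Matrix of nuclear centroids
#' @param ns A `nuclei_set`.
#' @return n x 2 matrix (x, y).
#' @export
centroids <- function(ns) {
  if (length(ns$nuclei) == 0) return(matrix(numeric(0), 0, 2))
  t(vapply(ns$nuclei, function(n) n$centroid, numeric(2)))
}

#' Construct a spot image object
#'
#' @param pixels height x width x 3 array of 8-bit intensities (0-255).
#' @param spot_id Spot identifier.
#' @param microns_per_pixel Physical scale; recorded only, never used in
#'   feature computation (all distances are in pixels).
#' @return Object of class `spot_image`.
#' @export
spot_image <- function(pixels, spot_id, microns_per_pixel = 0.5) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("pixels must be an H x W x 3 array")
  if (d[1] < 64 || d[2] < 64) stop("image must be at least 64 x 64")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, spot_id = as.character(spot_id),
                 microns_per_pixel = microns_per_pixel),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<spot_image>", x$spot_id, "-", d[2], "x", d[1], "px RGB @",
      x$microns_per_pixel, "um/px\n")
  invisible(x)
}

#' Luminance (grayscale) channel of a spot image
#' @keywords internal
spot_luminance <- function(img) {
  p <- img$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}
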
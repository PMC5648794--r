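# Per-nucleus shape descriptors with Fourier shape descriptors, PCA-based
# nuclear orientation, the 13 second-order co-occurrence statistics shared by
# the orientation-entropy and gray-level texture families, and the spot-level
# aggregations that produce the 100 + 39 + 26 feature blocks.
# All entropic quantities use log base 2 with 0*log(0) = 0.

#' Fourier shape descriptors of a nuclear boundary
#'
#' The boundary is resampled to `n_points` equal arc-length samples; the
#' centroid-to-boundary radius signal r(t) is Fourier transformed and
#' FSDk = |c_k| / |c_0| for k = 1..n_fsd. Using radius magnitudes makes the
#' descriptors invariant to translation, rotation, scale and the choice of
#' start vertex.
#'
#' @param nb A [nucleus_boundary()] (or bare vertex matrix).
#' @param n_points Resampling resolution (default 128).
#' @param n_fsd Number of descriptors (default 10).
#' @return Numeric vector FSD1..FSDn.
#' @export
fourier_shape_descriptors <- function(nb, n_points = 128L, n_fsd = 10L) {
  v <- if (inherits(nb, "nucleus_boundary")) nb$vertices else as.matrix(nb)
  ctr <- polygon_centroid(v)
  # canonical start: the max-radius vertex, so the sampling grid (and hence the
  # descriptors) does not depend on which vertex the polygon happens to start at
  rad <- sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2)
  k <- which.max(rad)
  if (k > 1) v <- v[c(k:nrow(v), 1:(k - 1)), , drop = FALSE]
  rs <- polygon_resample(v, n_points)
  r <- sqrt((rs[, 1] - ctr[1])^2 + (rs[, 2] - ctr[2])^2)
  co <- stats::fft(r)
  mag <- Mod(co)
  if (mag[1] <= 0) stop("degenerate boundary: zero mean radius")
  mag[seq_len(n_fsd) + 1L] / mag[1]
}

#' Nuclear orientation by principal component analysis
#'
#' Angle of the first principal axis of the boundary vertex cloud, folded to
#' [0, 180) degrees. Near-isotropic nuclei (eigenvalue ratio below `iso_ratio`)
#' are flagged low-confidence.
#'
#' @param nb A [nucleus_boundary()].
#' @param iso_ratio Isotropy threshold on the eigenvalue ratio (default 1.05).
#' @return List: `angle_deg` in [0, 180) and logical `confident`.
#' @export
nucleus_orientation <- function(nb, iso_ratio = 1.05) {
  v <- if (inherits(nb, "nucleus_boundary")) nb$vertices else as.matrix(nb)
  if (nrow(v) < 8) stop("need at least 8 boundary points")
  vc <- sweep(v, 2, colMeans(v))
  cv <- crossprod(vc) / (nrow(v) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  ang <- ang %% 180
  ratio <- eg$values[1] / max(eg$values[2], .Machine$double.eps)
  list(angle_deg = ang, confident = ratio >= iso_ratio)
}

#' Per-nucleus base shape descriptors (25)
#'
#' area, perimeter, equivalent diameter, min/max/mean radius and radius SD
#' (centroid-to-boundary over 128 resampled points), major/minor axis
#' (4 * sqrt of the PCA eigenvalues of the boundary cloud), eccentricity,
#' compactness 4*pi*A/P^2, solidity (area / convex hull area), extent
#' (area / principal-axis box, major x minor), convexity (convex hull
#' perimeter / perimeter),
#' bending energy (mean squared turning angle per unit length of the resampled
#' boundary), and FSD1..FSD10.
#'
#' @param nb A [nucleus_boundary()].
#' @return Named numeric vector of length 25.
#' @export
nucleus_shape_profile <- function(nb) {
  v <- nb$vertices
  a <- polygon_area(v)
  p <- polygon_perimeter(v)
  ctr <- polygon_centroid(v)
  rs <- polygon_resample(v, 128L)
  r <- sqrt((rs[, 1] - ctr[1])^2 + (rs[, 2] - ctr[2])^2)
  vc <- sweep(v, 2, colMeans(v))
  ev <- eigen(crossprod(vc) / (nrow(v) - 1), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  hull <- v[grDevices::chull(v), , drop = FALSE]
  hull_a <- polygon_area(hull); hull_p <- polygon_perimeter(hull)
  # extent uses the principal-axis box (major x minor) rather than the
  # axis-aligned bounding box: rotation-invariant and well-conditioned even for
  # near-circular nuclei whose principal directions are degenerate
  bbox_a <- major * minor
  # turning angles of the equal-arc-length resampled boundary
  dv <- rs[c(2:nrow(rs), 1), ] - rs
  ang <- atan2(dv[, 2], dv[, 1])
  dang <- diff(c(ang, ang[1]))
  dang <- atan2(sin(dang), cos(dang))
  ds <- p / nrow(rs)
  bend <- mean((dang / ds)^2)
  c(area = a, perimeter = p, equiv_diameter = 2 * sqrt(a / pi),
    min_radius = min(r), max_radius = max(r), mean_radius = mean(r),
    radius_std = stats::sd(r), major_axis = major, minor_axis = minor,
    eccentricity = ecc, compactness = 4 * pi * a / p^2,
    solidity = if (hull_a > 0) a / hull_a else NaN,
    extent = if (bbox_a > 0) a / bbox_a else NaN,
    convexity = if (p > 0) hull_p / p else NaN,
    bending_energy = bend,
    stats::setNames(fourier_shape_descriptors(nb), paste0("fsd", 1:10)))
}

#' Spot-level shape features (100)
#'
#' Aggregates {mean, std, median, min/max ratio} of the 25 per-nucleus base
#' descriptors over all nuclei, in registry order. Per-nucleus failures skip
#' that nucleus with a warning; fewer than 2 valid nuclei yields NaNs.
#'
#' @param ns A [nuclei_set()].
#' @return Named numeric vector of length 100.
#' @export
shape_features <- function(ns) {
  reg <- feature_registry()
  nm <- reg$name[reg$category == "shape"]
  out <- stats::setNames(rep(NaN, length(nm)), nm)
  profs <- list()
  for (nu in ns$nuclei) {
    pr <- tryCatch(nucleus_shape_profile(nu), error = function(e) {
      warning("nucleus '", nu$nucleus_id, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(pr)) profs[[length(profs) + 1]] <- pr
  }
  if (length(profs) < 2) {
    warning("fewer than 2 valid nuclei; shape features are NaN")
    return(out)
  }
  M <- do.call(rbind, profs)
  for (b in colnames(M)) {
    x <- M[, b]
    x <- x[is.finite(x)]
    if (length(x) < 2) next
    mm <- if (max(x) > 0) min(x) / max(x) else NaN
    out[sprintf("shape.%s.%s", b, c("mean", "std", "median", "minmax_ratio"))] <-
      c(mean(x), stats::sd(x), stats::median(x), mm)
  }
  out
}

#' The 13 second-order co-occurrence statistics
#'
#' For a normalized symmetric co-occurrence matrix P over B levels, with
#' difference distribution p_d(k) = sum over |i-j| = k and sum distribution
#' p_s(k) over i + j: contrast energy = sum (i-j)^2 P; contrast inverse
#' moment = sum P / (1 + (i-j)^2); contrast average/variance/entropy are the
#' mean, variance and entropy of p_d; intensity average/variance/entropy those
#' of p_s; entropy and energy of P itself; correlation; and the two
#' information measures of correlation. Entropies in bits, 0 log 0 = 0.
#'
#' @param P Square, symmetric, non-negative matrix summing to 1.
#' @return Named numeric vector of length 13 ([cooccurrence_stat_names()]).
#' @export
cooccurrence_stats_13 <- function(P) {
  P <- as.matrix(P)
  B <- nrow(P)
  if (ncol(P) != B) stop("P must be square")
  if (any(P < 0)) stop("P must be non-negative")
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  if (max(abs(P - t(P))) > 1e-8) stop("P must be symmetric")
  i <- row(P); j <- col(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  kd <- 0:(B - 1)
  pd <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * B)
  ps <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  c_avg <- sum(kd * pd)
  c_var <- sum((kd - c_avg)^2 * pd)
  s_avg <- sum(ks * ps)
  s_var <- sum((ks - s_avg)^2 * ps)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(B) * px); muy <- sum(seq_len(B) * py)
  sx <- sqrt(sum((seq_len(B) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(B) - muy)^2 * py))
  corr <- if (sx * sy > 0) {
    (sum(outer(seq_len(B), seq_len(B)) * P) - mux * muy) / (sx * sy)
  } else 0
  hxy <- H(P)
  hx <- H(px); hy <- H(py)
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  pos2 <- pxy > 0
  hxy2 <- -sum(pxy[pos2] * log2(pxy[pos2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  stats::setNames(
    c(sum((i - j)^2 * P), sum(P / (1 + (i - j)^2)), c_avg, c_var, H(pd),
      s_avg, s_var, H(ps), hxy, sum(P^2), corr, imc1, imc2),
    cooccurrence_stat_names())
}

#' Orientation co-occurrence matrix of a set of angles
#'
#' Quantizes axial angles into `bins` equal bins over [0, 180) and accumulates
#' all unordered pairs symmetrically.
#' @param angles_deg Angles in degrees.
#' @param bins Number of bins (default 10).
#' @return Normalized symmetric bins x bins matrix.
#' @export
orientation_cooccurrence <- function(angles_deg, bins = 10L) {
  if (length(angles_deg) < 2) stop("need at least 2 angles")
  b <- pmin(floor((angles_deg %% 180) / (180 / bins)) + 1L, bins)
  # all unordered pairs, entered symmetrically: P = N N' - diag(N) for bin
  # counts N (off-diagonal N_u N_v; diagonal N_u (N_u - 1))
  N <- tabulate(b, nbins = bins)
  P <- N %*% t(N) - diag(N, bins)
  P / sum(P)
}

#' Orientation-entropy features (39)
#'
#' For each cluster of the cell-cluster graph with at least 2 member nuclei,
#' the orientations of the member nuclei are quantized and their pairwise
#' co-occurrence matrix summarized by the 13 second-order statistics; each
#' statistic is then aggregated by {mean, median, std} across clusters.
#' A spot with a single qualifying cluster reports 0 for the std aggregates
#' (no between-cluster variability observed); no qualifying cluster yields
#' NaNs with a warning.
#'
#' @param ns A [nuclei_set()].
#' @param cg Matching `cluster_graph`.
#' @param bins Orientation bins over [0, 180) (default 10).
#' @return Named numeric vector of length 39.
#' @export
orientation_entropy_features <- function(ns, cg, bins = 10L) {
  reg <- feature_registry()
  nm <- reg$name[reg$category == "orientation"]
  out <- stats::setNames(rep(NaN, length(nm)), nm)
  ids <- vapply(ns$nuclei, function(nu) nu$nucleus_id, character(1))
  ang <- vapply(ns$nuclei, function(nu) nucleus_orientation(nu)$angle_deg, numeric(1))
  names(ang) <- ids
  stat_rows <- list()
  for (cl in cg$clusters) {
    if (length(cl$members) < 2) next
    P <- orientation_cooccurrence(ang[cl$members], bins)
    stat_rows[[length(stat_rows) + 1]] <- cooccurrence_stats_13(P)
  }
  if (length(stat_rows) == 0) {
    warning("no cluster with >= 2 nuclei; orientation features are NaN")
    return(out)
  }
  M <- do.call(rbind, stat_rows)
  for (s in colnames(M)) {
    x <- M[, s]
    sdv <- if (length(x) > 1) stats::sd(x) else 0
    out[sprintf("orientation.%s.%s", s, c("mean", "median", "std"))] <-
      c(mean(x), stats::median(x), sdv)
  }
  out
}

#' Gray-level co-occurrence texture features (26)
#'
#' Luminance pixels inside each nuclear mask are quantized to `gray_levels` by
#' equal-width binning over the global range of nuclear pixels in the spot.
#' A symmetric co-occurrence matrix is accumulated over the four unit offsets
#' (0,1), (1,0), (1,1), (1,-1), normalized, and summarized by the 13 statistics
#' per nucleus; {mean, std} across nuclei give the 26 spot-level values.
#' Nuclei with masks under 16 px are skipped with a warning.
#'
#' @param img A [spot_image()].
#' @param ns Matching [nuclei_set()].
#' @param gray_levels Number of quantization levels (default 16).
#' @return Named numeric vector of length 26.
#' @export
texture_features <- function(img, ns, gray_levels = 16L) {
  reg <- feature_registry()
  nm <- reg$name[reg$category == "texture"]
  out <- stats::setNames(rep(NaN, length(nm)), nm)
  lum <- spot_luminance(img)
  h <- nrow(lum); w <- ncol(lum)
  masks <- lapply(ns$nuclei, function(nu) {
    pix <- polygon_pixels(nu$vertices)
    keep <- pix[, 1] >= 0 & pix[, 1] < w & pix[, 2] >= 0 & pix[, 2] < h
    pix[keep, , drop = FALSE]
  })
  all_vals <- unlist(lapply(masks, function(p) {
    if (nrow(p) == 0) numeric(0) else lum[cbind(p[, 2] + 1L, p[, 1] + 1L)]
  }))
  if (length(all_vals) == 0) {
    warning("no nuclear pixels; texture features are NaN")
    return(out)
  }
  rng <- range(all_vals)
  quant <- function(v) {
    if (rng[2] <= rng[1]) return(rep(1L, length(v)))
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * gray_levels) + 1L, gray_levels)
  }
  offsets <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))  # (dy, dx)
  stat_rows <- list()
  for (k in seq_along(masks)) {
    pix <- masks[[k]]
    if (nrow(pix) < 16) {
      warning("nucleus '", ns$nuclei[[k]]$nucleus_id, "' mask < 16 px; skipped")
      next
    }
    # local raster of quantized levels over the bounding box
    x0 <- min(pix[, 1]); y0 <- min(pix[, 2])
    bw <- max(pix[, 1]) - x0 + 1L; bh <- max(pix[, 2]) - y0 + 1L
    Q <- matrix(NA_integer_, bh, bw)
    Q[cbind(pix[, 2] - y0 + 1L, pix[, 1] - x0 + 1L)] <-
      quant(lum[cbind(pix[, 2] + 1L, pix[, 1] + 1L)])
    cnt <- matrix(0, gray_levels, gray_levels)
    for (o in seq_len(nrow(offsets))) {
      dy <- offsets[o, 1]; dx <- offsets[o, 2]
      ys <- seq_len(bh); xs <- seq_len(bw)
      ys_a <- ys[ys + dy >= 1 & ys + dy <= bh]
      xs_a <- xs[xs + dx >= 1 & xs + dx <= bw]
      if (length(ys_a) == 0 || length(xs_a) == 0) next
      A <- Q[ys_a, xs_a, drop = FALSE]
      Bm <- Q[ys_a + dy, xs_a + dx, drop = FALSE]
      ok <- !is.na(A) & !is.na(Bm)
      if (!any(ok)) next
      li <- (Bm[ok] - 1L) * gray_levels + A[ok]
      tab <- tabulate(li, nbins = gray_levels^2)
      cnt <- cnt + matrix(tab, gray_levels, gray_levels)
    }
    P <- cnt + t(cnt)  # symmetric accumulation over both pair orders
    if (sum(P) == 0) next
    stat_rows[[length(stat_rows) + 1]] <- cooccurrence_stats_13(P / sum(P))
  }
  if (length(stat_rows) == 0) {
    warning("no nucleus produced a co-occurrence matrix; texture features are NaN")
    return(out)
  }
  M <- do.call(rbind, stat_rows)
  for (s in colnames(M)) {
    x <- M[, s]
    sdv <- if (length(x) > 1) stats::sd(x) else 0
    out[sprintf("texture.%s.%s", s, c("mean", "std"))] <- c(mean(x), sdv)
  }
  out
}
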
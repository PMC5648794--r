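# Independent oracles and small fixtures shared across the suite. The oracles
# deliberately use different algorithms from the package implementation.

# --- geometry fixtures -------------------------------------------------------

make_ellipse <- function(a, b, angle_deg = 0, cx = 0, cy = 0, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  th <- angle_deg * pi / 180
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(th) - y * sin(th), cy + x * sin(th) + y * cos(th))
}

make_circle <- function(r, cx = 0, cy = 0, n = 64) make_ellipse(r, r, 0, cx, cy, n)

blank_pink_image <- function(w = 128, h = 128) {
  px <- array(0L, c(h, w, 3))
  px[, , 1] <- 233L; px[, , 2] <- 188L; px[, , 3] <- 208L
  spot_image(px, "blank")
}

# paint a polygon onto an image with a flat nuclear tone
paint_polygon <- function(img, v, rgb = c(75L, 48L, 137L)) {
  pix <- nucmorph:::polygon_pixels(v)
  ij <- cbind(pix[, 2] + 1L, pix[, 1] + 1L)
  for (ch in 1:3) img$pixels[cbind(ij, ch)] <- rgb[ch]
  img
}

# a nuclei_set from a list of vertex matrices
make_set <- function(polys, image_size = c(256, 256), spot_id = "fix") {
  nuclei <- lapply(seq_along(polys), function(i) {
    nucleus_boundary(sprintf("n%02d", i), polys[[i]])
  })
  nuclei_set(spot_id, nuclei, image_size)
}

# nuclei_set of identical small circles placed at given centroids
circles_at <- function(centers, r = 6, image_size = c(1600, 1600)) {
  polys <- lapply(seq_len(nrow(centers)), function(i) {
    make_circle(r, centers[i, 1], centers[i, 2], n = 32)
  })
  make_set(polys, image_size)
}

# --- geometric oracles -------------------------------------------------------

# O(n^4) empty-circumcircle Delaunay oracle (general-position inputs)
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  tris <- matrix(integer(0), 0, 3)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- nucmorph:::circumcircle(pts[i, ], pts[j, ], pts[k, ])
    if (!is.finite(cc$r2)) next
    d2 <- (pts[, 1] - cc$center[1])^2 + (pts[, 2] - cc$center[2])^2
    inside <- d2 < cc$r2 * (1 - 1e-12)
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) tris <- rbind(tris, c(i, j, k))
  }
  tris[order(tris[, 1], tris[, 2], tris[, 3]), , drop = FALSE]
}

# Voronoi cell area by Sutherland-Hodgman half-plane clipping of a large box
# (independent of the package's dual circumcenter construction)
oracle_voronoi_cell_area <- function(pts, i) {
  clip <- function(poly, o, nrm) {
    n <- nrow(poly)
    f <- (poly[, 1] - o[1]) * nrm[1] + (poly[, 2] - o[2]) * nrm[2]
    out <- matrix(numeric(0), 0, 2)
    for (k in seq_len(n)) {
      j <- k %% n + 1
      if (f[k] <= 0) out <- rbind(out, poly[k, ])
      if ((f[k] <= 0) != (f[j] <= 0)) {
        t <- f[k] / (f[k] - f[j])
        out <- rbind(out, poly[k, ] + t * (poly[j, ] - poly[k, ]))
      }
    }
    out
  }
  ctr <- colMeans(pts)
  m <- 200 * max(apply(pts, 2, function(z) diff(range(z))), 1)
  poly <- rbind(ctr + c(-m, -m), ctr + c(m, -m), ctr + c(m, m), ctr + c(-m, m))
  for (j in seq_len(nrow(pts))) {
    if (j == i) next
    poly <- clip(poly, (pts[i, ] + pts[j, ]) / 2, pts[j, ] - pts[i, ])
  }
  # near-hull sites can own cells larger than the artificial box; the oracle
  # cannot vouch for those, so it abstains (NA) rather than mis-measure
  if (max(abs(sweep(poly, 2, ctr))) > 0.9 * m) return(NA_real_)
  abs(nucmorph:::polygon_signed_area(poly))
}

# exhaustive minimum spanning tree (n <= 7): try all edge subsets of size n-1
oracle_mst_length <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  e <- which(upper.tri(D), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(e), n - 1, simplify = FALSE)) {
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in sel) {
      a <- find(e[k, 1]); b <- find(e[k, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(D[e[sel, , drop = FALSE]]))
  }
  best
}

# --- co-occurrence statistics oracle (literal term-wise transcription) -------

oracle_cooc_stats <- function(P) {
  B <- nrow(P)
  pd <- rep(0, B); ps <- rep(0, 2 * B - 1)
  ce <- 0; cim <- 0; ent <- 0; en <- 0
  for (i in 1:B) for (j in 1:B) {
    p <- P[i, j]
    ce <- ce + (i - j)^2 * p
    cim <- cim + p / (1 + (i - j)^2)
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j - 1] <- ps[i + j - 1] + p
    if (p > 0) ent <- ent - p * log2(p)
    en <- en + p^2
  }
  hh <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  kd <- 0:(B - 1); kssum <- 2:(2 * B)
  ca <- sum(kd * pd); cv <- sum((kd - ca)^2 * pd)
  ia <- sum(kssum * ps); iv <- sum((kssum - ia)^2 * ps)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:B) * px); my <- sum((1:B) * py)
  sx <- sqrt(sum(((1:B) - mx)^2 * px)); sy <- sqrt(sum(((1:B) - my)^2 * py))
  co <- 0
  for (i in 1:B) for (j in 1:B) co <- co + (i - mx) * (j - my) * P[i, j]
  corr <- if (sx * sy > 0) co / (sx * sy) else 0
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:B) for (j in 1:B) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy2 <- hxy2 - q * log2(q)
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
    }
  }
  hx <- hh(px); hy <- hh(py)
  c(contrast_energy = ce, contrast_inv_moment = cim, contrast_avg = ca,
    contrast_var = cv, contrast_entropy = hh(pd), intensity_avg = ia,
    intensity_var = iv, intensity_entropy = hh(ps), entropy = ent, energy = en,
    correlation = corr,
    info_corr1 = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    info_corr2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))))
}

random_sym_cooc <- function(B, seed) {
  set.seed(seed)
  M <- matrix(runif(B * B), B, B)
  P <- (M + t(M))
  P / sum(P)
}

# --- misc oracles ------------------------------------------------------------

# circular variance of axial data (angles in degrees over [0, 180))
axial_circular_variance <- function(angles_deg) {
  th <- 2 * angles_deg * pi / 180
  1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

# exact two-sided Fisher p by full enumeration over tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small synthetic cohort spec with lightweight nuclei, for survival-only tests
light_cohort_spec <- function(n_patients, seed,
                              survival = list(weibull_shape = 1.5,
                                              scale_recurrent_months = 20,
                                              scale_nonrecurrent_months = 80,
                                              censor_uniform_max_months = 120)) {
  small <- function(preset) {
    p <- phenotype_preset(preset)
    p$n_nuclei <- 10L
    p
  }
  cohort_spec(n_patients = n_patients, recurrence_fraction = 0.5,
              params_recurrent = small("recurrent"),
              params_nonrecurrent = small("nonrecurrent"),
              survival = survival, image_size = c(256, 256), seed = seed)
}
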
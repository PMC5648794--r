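test_that("Fourier shape descriptors are invariant and rank harmonics correctly", {
  circ <- make_circle(40, 64, 64, n = 128)
  expect_lt(max(fourier_shape_descriptors(circ)), 1e-3)

  ell <- make_ellipse(30, 15, 0, 0, 0, n = 128)
  f <- fourier_shape_descriptors(ell)
  expect_equal(which.max(f), 2)  # oracle: DFT of the radius signal peaks at k=2
  # direct DFT oracle for FSD2 on the same resampled radius signal
  v <- nucmorph:::polygon_resample(ell[c(which.max(rowSums(ell^2)):128,
                                         seq_len(which.max(rowSums(ell^2)) - 1)), ], 128)
  r <- sqrt(rowSums(v^2))
  co <- Mod(stats::fft(r))
  expect_equal(unname(f[2]), co[3] / co[1], tolerance = 1e-12)

  rot <- make_ellipse(30, 15, 37, 100, 50, n = 128)
  expect_equal(f, fourier_shape_descriptors(rot), tolerance = 1e-6)
  shift <- ell[c(40:128, 1:39), ]
  expect_equal(f, fourier_shape_descriptors(shift), tolerance = 1e-6)
  expect_equal(f, fourier_shape_descriptors(ell * 5.3), tolerance = 1e-6)
  expect_error(fourier_shape_descriptors(matrix(1, 10, 2)), "degenerate")
})

test_that("shape aggregates behave on constructed populations", {
  # ten identical circles
  ns <- circles_at(cbind(seq(50, 500, by = 50), 100), r = 10,
                   image_size = c(600, 200))
  f <- shape_features(ns)
  expect_length(f, 100)
  # identical nuclei: spreads vanish and min/max ratios are 1 for every base
  # descriptor of non-negligible magnitude (descriptors that are themselves
  # numerical zeros, e.g. circle eccentricity or FSDs, carry only float noise)
  for (b in unique(sub("^shape\\.([^.]+)\\..*$", "\\1", names(f)))) {
    m <- f[sprintf("shape.%s.mean", b)]
    if (!is.finite(m) || abs(m) < 1e-6) next
    expect_lt(abs(f[sprintf("shape.%s.std", b)]) / abs(m), 1e-9)
    expect_equal(unname(f[sprintf("shape.%s.minmax_ratio", b)]), 1,
                 tolerance = 1e-9)
  }

  # two circles with radii 10 and 20: area ratio 0.25 (pi r^2 by hand)
  ns2 <- make_set(list(make_circle(10, 100, 100, 64), make_circle(20, 200, 100, 64)),
                  c(300, 200))
  f2 <- shape_features(ns2)
  expect_equal(unname(f2["shape.area.minmax_ratio"]), 0.25, tolerance = 1e-3)
  expect_equal(unname(f2["shape.equiv_diameter.minmax_ratio"]), 0.5, tolerance = 1e-3)
})

test_that("shape features are invariant to spot translation and rotation", {
  set.seed(5)
  p <- phenotype_preset("recurrent")
  ns <- generate_nuclei(p, c(320, 320), seed = 5)
  polys <- lapply(ns$nuclei, function(nu) nu$vertices)
  rot <- function(v, a, dx, dy) {
    cbind(dx + v[, 1] * cos(a) - v[, 2] * sin(a),
          dy + v[, 1] * sin(a) + v[, 2] * cos(a))
  }
  polys2 <- lapply(polys, rot, a = 0.4, dx = 300, dy = 200)
  ns2 <- make_set(polys2, c(1200, 1200))
  f1 <- shape_features(ns)
  f2 <- shape_features(ns2)
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("PCA orientation recovers constructed axes and folds to [0, 180)", {
  o30 <- nucleus_orientation(make_ellipse(30, 10, 30))
  expect_equal(o30$angle_deg, 30, tolerance = 1)
  expect_true(o30$confident)
  o150 <- nucleus_orientation(make_ellipse(30, 10, 150))
  expect_equal(o150$angle_deg, 150, tolerance = 1)
  expect_false(nucleus_orientation(make_circle(20))$confident)
})

test_that("the 13 co-occurrence statistics match a literal-formula oracle", {
  B <- 4
  P_id <- diag(B) / B
  s <- cooccurrence_stats_13(P_id)
  expect_equal(unname(s["contrast_avg"]), 0)
  expect_equal(unname(s["contrast_var"]), 0)
  expect_equal(unname(s["contrast_energy"]), 0)
  P_unif <- matrix(1 / 16, 4, 4)
  expect_equal(unname(cooccurrence_stats_13(P_unif)["entropy"]), 4)
  for (s_ in 1:20) {
    P <- random_sym_cooc(4, s_)
    expect_equal(cooccurrence_stats_13(P), oracle_cooc_stats(P), tolerance = 1e-10)
  }
  expect_error(cooccurrence_stats_13(matrix(1, 4, 4)), "sum to 1")
})

test_that("orientation co-occurrence matrices are symmetric and normalized", {
  set.seed(8)
  for (i in 1:5) {
    ang <- runif(30, 0, 180)
    P <- orientation_cooccurrence(ang, 10)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
  }
})

test_that("aligned nuclei give zero orientation entropy; output is 39-long", {
  # all nuclei identical orientation -> single diagonal cell
  polys <- lapply(seq(60, 260, by = 40), function(x) {
    lapply(seq(60, 260, by = 40), function(y) make_ellipse(10, 5, 45, x, y, 32))
  })
  polys <- do.call(c, polys)
  ns <- make_set(polys, c(320, 320))
  cg <- build_cluster_graph(ns)
  f <- orientation_entropy_features(ns, cg)
  expect_length(f, 39)
  expect_equal(unname(f["orientation.entropy.mean"]), 0)
  expect_equal(unname(f["orientation.energy.mean"]), 1)
  expect_equal(unname(f["orientation.entropy.std"]), 0)
})

test_that("disordered clusters carry higher orientation entropy than aligned ones", {
  hits <- 0
  for (s in 1:20) {
    mk <- function(kappa, cx, seed) {
      p <- phenotype_params(
        n_nuclei = 50,
        clustering = list(process = "hardcore", parent_count = 1,
                          offspring_sd_px = 1, min_spacing_px = 10),
        orientation = list(mean_angle_deg = 45, vonmises_kappa = kappa),
        shape = list(mean_major_px = 8, mean_minor_px = 4, fourier_perturb_amp = 0))
      generate_nuclei(p, c(256, 256), seed = seed)
    }
    ns_a <- mk(50, 0, s); ns_d <- mk(0, 0, s + 1000)
    ent <- function(ns) {
      ang <- vapply(ns$nuclei, function(nu) nucleus_orientation(nu)$angle_deg,
                    numeric(1))
      # oracle: entropy of the brute-force pair histogram
      b <- pmin(floor(ang / 18) + 1, 10)
      cnt <- matrix(0, 10, 10)
      for (u in 1:(length(b) - 1)) for (v in (u + 1):length(b)) {
        cnt[b[u], b[v]] <- cnt[b[u], b[v]] + 1
        cnt[b[v], b[u]] <- cnt[b[v], b[u]] + 1
      }
      P <- cnt / sum(cnt)
      p <- P[P > 0]
      -sum(p * log2(p))
    }
    if (ent(ns_d) > ent(ns_a)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("texture features behave on flat and checkerboard nuclei", {
  # flat nuclei: contrast 0, energy 1, zero spread across nuclei
  p <- phenotype_params(n_nuclei = 12,
                        texture = list(base_intensity = 110, heterogeneity_sd = 0,
                                       blob_scale_px = 2))
  ns <- generate_nuclei(p, c(256, 256), seed = 3)
  img <- render_spot(ns, p, seed = 3)
  f <- texture_features(img, ns)
  expect_length(f, 26)
  expect_equal(unname(f["texture.contrast_avg.mean"]), 0)
  expect_equal(unname(f["texture.energy.mean"]), 1)
  expect_equal(unname(f["texture.contrast_avg.std"]), 0)

  # checkerboard nucleus: oracle by explicit pair enumeration on the patch
  img2 <- blank_pink_image(64, 64)
  vals <- matrix(0L, 64, 64)
  for (x in 2:9) for (y in 2:9) {
    v <- if ((x + y) %% 2 == 0) 60L else 180L
    img2$pixels[y + 1, x + 1, ] <- v
    vals[y + 1, x + 1] <- v
  }
  sq <- cbind(c(1.5, 5.5, 9.5, 9.5, 9.5, 5.5, 1.5, 1.5),
              c(1.5, 1.5, 1.5, 5.5, 9.5, 9.5, 9.5, 5.5))
  ns2 <- make_set(list(sq), c(64, 64))
  f2 <- suppressWarnings(texture_features(img2, ns2))
  # enumeration over the four offsets on the 8x8 patch
  lv <- function(v) if (v == 60) 1 else 16
  num <- 0; den <- 0
  for (x in 2:9) for (y in 2:9) {
    for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      xx <- x + o[2]; yy <- y + o[1]
      if (xx >= 2 && xx <= 9 && yy >= 2 && yy <= 9) {
        num <- num + abs(lv(vals[y + 1, x + 1]) - lv(vals[yy + 1, xx + 1]))
        den <- den + 1
      }
    }
  }
  expect_equal(unname(f2["texture.contrast_avg.mean"]), num / den, tolerance = 1e-12)
})

test_that("a full feature vector is complete and categorized correctly", {
  p <- phenotype_preset("recurrent")
  ns <- generate_nuclei(p, c(320, 320), seed = 17)
  img <- render_spot(ns, p, seed = 17)
  f <- extract_features(ns, img)
  expect_length(f, 242)
  expect_identical(names(f), feature_registry()$name)
  expect_true(all(is.finite(f)))
})
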
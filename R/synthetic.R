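# Synthetic TMA-spot phantoms. The generator emulates the contrasts the
# recurrence classifier is meant to detect: recurrent-like spots have
# aggregated (Neyman-Scott) nuclei with disordered orientations, irregular
# boundaries and heterogeneous chromatin texture; non-recurrent-like spots have
# evenly spaced (hard-core) nuclei, aligned orientations, smooth boundaries and
# homogeneous texture. All randomness flows through R's Mersenne-Twister via
# explicit seeds, so identical seeds give byte-identical outputs.

#' Phenotype parameters for the synthetic spot generator
#'
#' @param n_nuclei Number of nuclei to place.
#' @param clustering List: `process` ("hardcore" or "neyman_scott"),
#'   `parent_count` (Neyman-Scott cluster parents), `offspring_sd_px`
#'   (Gaussian scatter of offspring around a parent), `min_spacing_px`
#'   (minimum centroid separation).
#' @param orientation List: `mean_angle_deg` (preferred axis, degrees) and
#'   `vonmises_kappa` (concentration; 0 = uniform axis directions).
#' @param shape List: `mean_major_px`, `mean_minor_px` (ellipse semi-axes) and
#'   `fourier_perturb_amp` in [0, 1) — the total relative amplitude of radial
#'   harmonics 2-8 perturbing the ellipse; 0 gives exact discretized ellipses
#'   and any value < 1 keeps the polygon star-shaped, hence simple.
#' @param texture List: `base_intensity` (0-255 hematoxylin tone),
#'   `heterogeneity_sd` (gray-level SD of intranuclear texture) and
#'   `blob_scale_px` (correlation length of the texture field).
#' @return Object of class `phenotype_params`.
#' @export
phenotype_params <- function(n_nuclei = 70,
                             clustering = list(process = "hardcore",
                                               parent_count = 8,
                                               offspring_sd_px = 30,
                                               min_spacing_px = 14),
                             orientation = list(mean_angle_deg = 45,
                                                vonmises_kappa = 2),
                             shape = list(mean_major_px = 9,
                                          mean_minor_px = 5.5,
                                          fourier_perturb_amp = 0.15),
                             texture = list(base_intensity = 110,
                                            heterogeneity_sd = 15,
                                            blob_scale_px = 2)) {
  stopifnot(n_nuclei >= 1,
            clustering$process %in% c("hardcore", "neyman_scott"),
            clustering$min_spacing_px > 0,
            orientation$vonmises_kappa >= 0,
            shape$mean_major_px > 0, shape$mean_minor_px > 0,
            shape$fourier_perturb_amp >= 0, shape$fourier_perturb_amp < 1,
            texture$base_intensity >= 0, texture$base_intensity <= 255,
            texture$heterogeneity_sd >= 0, texture$blob_scale_px > 0)
  structure(list(n_nuclei = as.integer(n_nuclei), clustering = clustering,
                 orientation = orientation, shape = shape, texture = texture),
            class = "phenotype_params")
}

#' Built-in phenotype presets
#'
#' `"recurrent"`: Neyman-Scott clustering, near-uniform orientations
#' (kappa = 0.5), strong boundary perturbation (0.35), heterogeneous texture
#' (SD 25). `"nonrecurrent"`: hard-core spacing, aligned orientations
#' (kappa = 8), mild perturbation (0.08), homogeneous texture (SD 8).
#'
#' @param which `"recurrent"` or `"nonrecurrent"`.
#' @return A [phenotype_params()] object.
#' @export
phenotype_preset <- function(which = c("recurrent", "nonrecurrent")) {
  which <- match.arg(which)
  if (which == "recurrent") {
    phenotype_params(
      n_nuclei = 70,
      clustering = list(process = "neyman_scott", parent_count = 7,
                        offspring_sd_px = 28, min_spacing_px = 15),
      orientation = list(mean_angle_deg = 45, vonmises_kappa = 0.5),
      shape = list(mean_major_px = 10, mean_minor_px = 5.5,
                   fourier_perturb_amp = 0.35),
      texture = list(base_intensity = 100, heterogeneity_sd = 25,
                     blob_scale_px = 2))
  } else {
    phenotype_params(
      n_nuclei = 70,
      clustering = list(process = "hardcore", parent_count = 8,
                        offspring_sd_px = 30, min_spacing_px = 18),
      orientation = list(mean_angle_deg = 45, vonmises_kappa = 8),
      shape = list(mean_major_px = 9, mean_minor_px = 5.5,
                   fourier_perturb_amp = 0.08),
      texture = list(base_intensity = 110, heterogeneity_sd = 8,
                     blob_scale_px = 2))
  }
}

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0); 0 gives the uniform circle.
#' @return Angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Centroid placement ------------------------------------------------------

#' @keywords internal
place_hardcore <- function(n, lo, hi, min_spacing, max_tries) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    p <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - p[1])^2 + (pts[seq_len(placed), 2] - p[2])^2) >=
          min_spacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) return(pts)
    }
  }
  stop("could not place ", n, " nuclei at spacing ", min_spacing,
       "; use a larger image or fewer nuclei")
}

#' @keywords internal
place_neyman_scott <- function(n, lo, hi, parent_count, offspring_sd,
                               min_spacing, max_tries) {
  parents <- cbind(stats::runif(parent_count, lo[1], hi[1]),
                   stats::runif(parent_count, lo[2], hi[2]))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    k <- sample.int(parent_count, 1)
    p <- parents[k, ] + stats::rnorm(2, 0, offspring_sd)
    p <- pmin(pmax(p, lo), hi)
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - p[1])^2 + (pts[seq_len(placed), 2] - p[2])^2) >=
          min_spacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) return(pts)
    }
  }
  stop("could not place ", n, " nuclei at spacing ", min_spacing,
       "; use a larger image, fewer nuclei, or smaller spacing")
}

#' Generate a synthetic nuclei set
#'
#' Places `n_nuclei` centroids by the configured point process and draws each
#' nuclear boundary as a discretized ellipse (64 vertices) with a radial
#' Fourier perturbation over harmonics 2-8 whose total relative amplitude is
#' `fourier_perturb_amp`; the radius therefore stays positive and the polygon
#' simple. Orientations are axial von Mises draws: an angle is sampled from
#' vonMises(2 * mean_angle, kappa) and halved, giving axes in [0, 180) that are
#' uniform when kappa = 0.
#'
#' @param params A [phenotype_params()] object.
#' @param image_size Integer (width, height), default c(320, 320).
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return A [nuclei_set()].
#' @export
generate_nuclei <- function(params, image_size = c(320, 320), seed = 1) {
  stopifnot(inherits(params, "phenotype_params"))
  image_size <- as.integer(image_size)
  set.seed(seed)
  sh <- params$shape
  margin <- sh$mean_major_px * 1.6 * (1 + sh$fourier_perturb_amp) + 2
  lo <- c(margin, margin)
  hi <- c(image_size[1] - 1 - margin, image_size[2] - 1 - margin)
  if (any(hi <= lo)) stop("image too small for the requested nucleus size")
  cl <- params$clustering
  max_tries <- 400L * params$n_nuclei
  ctr <- if (cl$process == "hardcore") {
    place_hardcore(params$n_nuclei, lo, hi, cl$min_spacing_px, max_tries)
  } else {
    place_neyman_scott(params$n_nuclei, lo, hi, cl$parent_count,
                       cl$offspring_sd_px, cl$min_spacing_px, max_tries)
  }
  mu2 <- 2 * params$orientation$mean_angle_deg * pi / 180
  theta <- rvonmises(params$n_nuclei, mu2, params$orientation$vonmises_kappa) / 2
  m <- 64L
  t_ang <- seq(0, 2 * pi, length.out = m + 1L)[seq_len(m)]
  nuclei <- vector("list", params$n_nuclei)
  for (i in seq_len(params$n_nuclei)) {
    a <- sh$mean_major_px * exp(stats::rnorm(1, 0, 0.10))
    b <- sh$mean_minor_px * exp(stats::rnorm(1, 0, 0.10))
    r <- rep(1, m)
    if (sh$fourier_perturb_amp > 0) {
      co <- stats::rnorm(7) / (2:8)
      si <- stats::rnorm(7) / (2:8)
      tot <- sum(abs(co)) + sum(abs(si))
      if (tot > 0) {
        co <- co / tot * sh$fourier_perturb_amp
        si <- si / tot * sh$fourier_perturb_amp
      }
      for (k in 2:8) {
        r <- r + co[k - 1] * cos(k * t_ang) + si[k - 1] * sin(k * t_ang)
      }
    }
    ex <- a * r * cos(t_ang); ey <- b * r * sin(t_ang)
    ct <- cos(theta[i]); st <- sin(theta[i])
    v <- cbind(ctr[i, 1] + ex * ct - ey * st,
               ctr[i, 2] + ex * st + ey * ct)
    v[, 1] <- pmin(pmax(v[, 1], 0), image_size[1] - 1e-6)
    v[, 2] <- pmin(pmax(v[, 2], 0), image_size[2] - 1e-6)
    nuclei[[i]] <- nucleus_boundary(sprintf("n%03d", i), v, validate = FALSE)
  }
  nuclei_set(sprintf("synthetic_seed%d", seed), nuclei, image_size)
}

#' Render an H&E-like image of a nuclei set
#'
#' Pink (eosin-like) constant background; each nucleus is filled with a
#' bluish-purple tone that is a deterministic function of a per-pixel
#' hematoxylin intensity `v = base_intensity + field`, where `field` is
#' Gaussian noise smoothed to correlation length `blob_scale_px` and rescaled
#' to standard deviation `heterogeneity_sd` (zero SD gives flat nuclei).
#' Boundaries are not anti-aliased so per-nucleus statistics are exact.
#'
#' @param nuclei A [nuclei_set()].
#' @param params A [phenotype_params()]; only the `texture` block is used.
#' @param seed Integer seed for the texture field.
#' @return A [spot_image()].
#' @export
render_spot <- function(nuclei, params, seed = 1) {
  stopifnot(inherits(nuclei, "nuclei_set"))
  set.seed(seed)
  w <- nuclei$image_size[1]; h <- nuclei$image_size[2]
  tx <- params$texture
  field <- matrix(0, h, w)
  if (tx$heterogeneity_sd > 0) {
    noise <- matrix(stats::rnorm(h * w), h, w)
    sm <- gaussian_blur_matrix(noise, tx$blob_scale_px)
    s <- stats::sd(as.vector(sm))
    if (s > 0) field <- sm / s * tx$heterogeneity_sd
  }
  px <- array(0L, c(h, w, 3))
  px[, , 1] <- 233L; px[, , 2] <- 188L; px[, , 3] <- 208L
  for (nu in nuclei$nuclei) {
    pix <- polygon_pixels(nu$vertices)
    if (nrow(pix) == 0) next
    keep <- pix[, 1] >= 0 & pix[, 1] < w & pix[, 2] >= 0 & pix[, 2] < h
    pix <- pix[keep, , drop = FALSE]
    if (nrow(pix) == 0) next
    ij <- cbind(pix[, 2] + 1L, pix[, 1] + 1L)  # (row, col)
    v <- pmin(pmax(tx$base_intensity + field[ij], 0), 255)
    px[cbind(ij, 1L)] <- as.integer(round(0.45 * v + 25))
    px[cbind(ij, 2L)] <- as.integer(round(0.30 * v + 15))
    px[cbind(ij, 3L)] <- as.integer(round(0.75 * v + 55))
  }
  spot_image(px, nuclei$spot_id)
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (one spot each).
#' @param recurrence_fraction Fraction assigned the recurrent phenotype.
#' @param params_recurrent,params_nonrecurrent [phenotype_params()] for the two
#'   phenotypes; defaults are the built-in presets.
#' @param survival List with `weibull_shape`, `scale_recurrent_months`,
#'   `scale_nonrecurrent_months` (the recurrent scale must be smaller: earlier
#'   events) and `censor_uniform_max_months` for independent uniform censoring.
#' @param image_size Spot size in pixels (width, height).
#' @param seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 120,
                        recurrence_fraction = 0.5,
                        params_recurrent = phenotype_preset("recurrent"),
                        params_nonrecurrent = phenotype_preset("nonrecurrent"),
                        survival = list(weibull_shape = 1.5,
                                        scale_recurrent_months = 20,
                                        scale_nonrecurrent_months = 80,
                                        censor_uniform_max_months = 120),
                        image_size = c(320, 320),
                        seed = 1) {
  stopifnot(n_patients >= 2,
            recurrence_fraction > 0, recurrence_fraction < 1,
            survival$scale_recurrent_months < survival$scale_nonrecurrent_months,
            survival$weibull_shape > 0)
  structure(list(n_patients = as.integer(n_patients),
                 recurrence_fraction = recurrence_fraction,
                 params_recurrent = params_recurrent,
                 params_nonrecurrent = params_nonrecurrent,
                 survival = survival,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Assigns exactly `round(n_patients * recurrence_fraction)` patients the
#' recurrent phenotype (shuffled order), draws each patient's spot, and
#' simulates recurrence-free survival: event time ~ Weibull(shape, phenotype
#' scale), censoring time ~ Uniform(0, censor_max), `rfs_months` the minimum
#' and `event_observed` accordingly. Gender, T and N stage are drawn
#' independently of phenotype so that in downstream multivariable models the
#' image-based call is the only informative covariate.
#'
#' @param spec A [cohort_spec()].
#' @param render Render images (set `FALSE` when only geometry or survival
#'   structure is needed).
#' @return List with `images` (list of [spot_image()] or `NULL`s), `nuclei`
#'   (list of [nuclei_set()]) and `clinical` (data.frame: patient_id, batch,
#'   gender, t_stage, n_stage, stage, recurrence, rfs_months, event_observed).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  n_rec <- round(n * spec$recurrence_fraction)
  recurrent <- rep(FALSE, n)
  recurrent[sample.int(n, n_rec)] <- TRUE
  sv <- spec$survival
  scale <- ifelse(recurrent, sv$scale_recurrent_months, sv$scale_nonrecurrent_months)
  t_event <- stats::rweibull(n, shape = sv$weibull_shape, scale = scale)
  t_cens <- stats::runif(n, 0, sv$censor_uniform_max_months)
  rfs <- pmin(t_event, t_cens)
  observed <- t_event <= t_cens
  gender <- ifelse(stats::runif(n) < 0.5, "M", "F")
  t_stage <- ifelse(stats::runif(n) < 0.5, "T1", "T2")
  n_stage <- ifelse(stats::runif(n) < 0.65, "N0", "N1")
  stage <- ifelse(n_stage == "N1", "II", "I")
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  nuclei <- vector("list", n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (recurrent[i]) spec$params_recurrent else spec$params_nonrecurrent
    nuclei[[i]] <- generate_nuclei(p, spec$image_size, seed = sub_seeds[i])
    nuclei[[i]]$spot_id <- sprintf("pt%03d", i)
    if (render) {
      images[[i]] <- render_spot(nuclei[[i]], p, seed = sub_seeds[i])
      images[[i]]$spot_id <- sprintf("pt%03d", i)
    }
  }
  clinical <- data.frame(
    patient_id = sprintf("pt%03d", seq_len(n)),
    batch = 1L,
    gender = gender, t_stage = t_stage, n_stage = n_stage, stage = stage,
    recurrence = recurrent,
    rfs_months = rfs,
    event_observed = observed,
    stringsAsFactors = FALSE)
  list(images = images, nuclei = nuclei, clinical = clinical)
}

#' Feature table for a synthetic cohort, generated streamingly
#'
#' Generates each patient's spot, extracts the 242 features, and discards the
#' image before moving on, keeping memory flat for large cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param config A [feature_config()].
#' @return List with `features` (data.frame: spot_id + 242 columns) and
#'   `clinical` (as in [generate_cohort()]).
#' @export
cohort_feature_table <- function(spec, config = feature_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  n_rec <- round(n * spec$recurrence_fraction)
  recurrent <- rep(FALSE, n)
  recurrent[sample.int(n, n_rec)] <- TRUE
  sv <- spec$survival
  scale <- ifelse(recurrent, sv$scale_recurrent_months, sv$scale_nonrecurrent_months)
  t_event <- stats::rweibull(n, shape = sv$weibull_shape, scale = scale)
  t_cens <- stats::runif(n, 0, sv$censor_uniform_max_months)
  gender <- ifelse(stats::runif(n) < 0.5, "M", "F")
  t_stage <- ifelse(stats::runif(n) < 0.5, "T1", "T2")
  n_stage <- ifelse(stats::runif(n) < 0.65, "N0", "N1")
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  reg <- feature_registry()
  vals <- matrix(NA_real_, n, nrow(reg), dimnames = list(NULL, reg$name))
  for (i in seq_len(n)) {
    p <- if (recurrent[i]) spec$params_recurrent else spec$params_nonrecurrent
    ns <- generate_nuclei(p, spec$image_size, seed = sub_seeds[i])
    img <- render_spot(ns, p, seed = sub_seeds[i])
    vals[i, ] <- extract_features(ns, img, config)
  }
  features <- data.frame(spot_id = sprintf("pt%03d", seq_len(n)), vals,
                         check.names = FALSE, stringsAsFactors = FALSE)
  clinical <- data.frame(
    patient_id = sprintf("pt%03d", seq_len(n)), batch = 1L,
    gender = gender, t_stage = t_stage, n_stage = n_stage,
    stage = ifelse(n_stage == "N1", "II", "I"),
    recurrence = recurrent,
    rfs_months = pmin(t_event, t_cens),
    event_observed = t_event <= t_cens,
    stringsAsFactors = FALSE)
  list(features = features, clinical = clinical)
}
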
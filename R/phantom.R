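#' Voxel label codes used in phantom volumes
#'
#' Integer codes for the labelled compartments of a phantom body volume:
#' background (0), lean tissue (1), visceral adipose tissue (2), abdominal
#' subcutaneous adipose tissue (3), gluteofemoral adipose tissue (4) and
#' other fat (5).
#'
#' @format Named integer vector of length 6.
#' @export
DEPOT_LABELS <- c(background = 0L, lean = 1L, VAT = 2L, ASAT = 3L,
                  GFAT = 4L, other_fat = 5L)

# Tissue densities (kg/L) used to derive weight from labelled volumes.
DENSITY_LEAN <- 1.06
DENSITY_FAT <- 0.92

# Per-sex base geometry (mm at size_factor 1, scaled by height / 1750).
.base_geometry <- list(
  male = list(chest = c(175, 118), abdomen = c(172, 118),
              pelvis = c(190, 128), thigh_top = 88, knee = 52, ankle = 30,
              arm = 43, head = c(57, 70), neck = 45),
  female = list(chest = c(160, 108), abdomen = c(166, 112),
                pelvis = c(200, 138), thigh_top = 95, knee = 52, ankle = 28,
                arm = 38, head = c(54, 66), neck = 42)
)

# Longitudinal landmarks as fractions of standing height (from vertex).
.landmark_fracs <- list(
  head = c(0.005, 0.110), neck = c(0.110, 0.150), shoulder = c(0.150, 0.195),
  chest = c(0.195, 0.270), upper_transition = c(0.270, 0.290),
  abdomen = c(0.290, 0.500), lower_transition = c(0.500, 0.515),
  pelvis = c(0.515, 0.570), thigh = c(0.570, 0.760), gfat_end = 0.800,
  leg_end = 0.985, arms = c(0.160, 0.280), gluteal = c(0.515, 0.630)
)

#' Construct phantom parameters for a single synthetic body
#'
#' Describes one synthetic participant: sex, standing height, a global girth
#' scale, a latent fat-distribution axis shifting abdominal fat between the
#' visceral core and the subcutaneous ring (and, correspondingly, the
#' abdominal cross-section eccentricity at constant perimeter), a
#' gluteofemoral scale, and limb/torso proportion scalars.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_mm Standing height in mm, within \[1300, 2100\].
#' @param size_factor Positive global girth scale (1 = sex-typical build).
#' @param vat_asat_shape Real latent fat-distribution axis; positive values
#'   shift abdominal fat towards the visceral depot at fixed waist girth.
#' @param gfat_factor Positive gluteofemoral fat scale.
#' @param arm_prop,leg_prop,torso_prop Positive proportion scalars.
#' @param noise_sd Non-negative intensity noise SD for simulated scalar
#'   voxel values.
#' @param vat_l,asat_l,gfat_l Optional explicit depot volume targets in
#'   liters; when `NULL` they are derived from the latent factors.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(sex = c("male", "female"), height_mm = 1750,
                           size_factor = 1, vat_asat_shape = 0,
                           gfat_factor = 1, arm_prop = 1, leg_prop = 1,
                           torso_prop = 1, noise_sd = 0.05,
                           vat_l = NULL, asat_l = NULL, gfat_l = NULL) {
  sex <- match.arg(sex)
  stopifnot(is.finite(height_mm), height_mm >= 1300, height_mm <= 2100,
            size_factor > 0, is.finite(vat_asat_shape), gfat_factor > 0,
            arm_prop > 0, leg_prop > 0, torso_prop > 0, noise_sd >= 0)
  structure(list(sex = sex, height_mm = height_mm, size_factor = size_factor,
                 vat_asat_shape = vat_asat_shape, gfat_factor = gfat_factor,
                 arm_prop = arm_prop, leg_prop = leg_prop,
                 torso_prop = torso_prop, noise_sd = noise_sd,
                 vat_l = vat_l, asat_l = asat_l, gfat_l = gfat_l),
            class = "phantom_params")
}

#' Population-level configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of the study cohort: a ~51%
#' female two-sex population, sex-stratified depot volume targets
#' (male VAT/ASAT/GFAT 5.0/5.9/9.3 L, female 2.6/7.9/11.3 L with matching
#' SDs), heights and ages per sex, and a latent fat-distribution axis
#' independent of overall body size.
#'
#' @param female_fraction Fraction of females in the cohort.
#' @param depot_targets Named list per sex with `mean` and `sd` vectors
#'   (liters) for VAT, ASAT, GFAT.
#' @param height_mean_mm,height_sd_mm Named per-sex vectors.
#' @param age_mean,age_sd Named per-sex vectors (years).
#' @param sigma_size SD of log size_factor (global girth variation).
#' @param size_exponent Scaling exponent linking girth to depot volume.
#' @param sigma_resid Residual log-SD per depot; 0 makes depot volumes
#'   deterministic functions of the latent factors.
#' @param kappa_ecc Abdominal eccentricity change per unit of the latent
#'   fat-distribution axis (silhouette-visible signature).
#' @param kappa_shift Anterior belly shift (fraction of the abdominal
#'   anteroposterior semi-axis) per unit of the latent axis.
#' @param spacing Voxel spacing (z, y, x) in mm used when rasterising
#'   cohort volumes.
#' @param intensities Whether cohort phantoms carry simulated scalar voxel
#'   intensities (slower) or labels only.
#' @param noise_sd Intensity noise SD when `intensities` is `TRUE`.
#' @param n_centers Number of synthetic imaging centers.
#' @param center_effects Logit-scale intercept shifts per center.
#' @param impedance_noise_sd Measurement noise SD for bioimpedance values.
#' @param disease_effects Per-disease coefficient sets, see
#'   [default_disease_effects()].
#' @param follow_up_median_years Target median follow-up for incident
#'   disease simulation.
#' @return A list of class `population_config`.
#' @export
population_config <- function(
    female_fraction = 0.51,
    depot_targets = list(
      male = list(mean = c(VAT = 5.0, ASAT = 5.9, GFAT = 9.3),
                  sd = c(VAT = 2.3, ASAT = 2.5, GFAT = 2.6)),
      female = list(mean = c(VAT = 2.6, ASAT = 7.9, GFAT = 11.3),
                    sd = c(VAT = 1.5, ASAT = 3.3, GFAT = 3.2))),
    height_mean_mm = c(male = 1763, female = 1628),
    height_sd_mm = c(male = 66, female = 63.5),
    age_mean = c(male = 65.2, female = 63.8),
    age_sd = c(male = 7.7, female = 7.5),
    sigma_size = 0.10, size_exponent = 2.5, sigma_resid = 0.12,
    kappa_ecc = 0.08, kappa_shift = 0.05,
    spacing = c(6.0, 4.464, 4.464),
    intensities = FALSE, noise_sd = 0.05,
    n_centers = 3, center_effects = c(0, 0.05, -0.05),
    impedance_noise_sd = 10,
    disease_effects = default_disease_effects(),
    follow_up_median_years = 2.8) {
  stopifnot(female_fraction >= 0, female_fraction <= 1, sigma_size > 0,
            size_exponent > 0, sigma_resid >= 0, all(spacing > 0),
            length(center_effects) == n_centers)
  structure(as.list(environment()), class = "population_config")
}

# Log-scale variance decomposition for one sex given config targets.
.depot_loadings <- function(config, sex) {
  tg <- config$depot_targets[[sex]]
  size_comp <- config$size_exponent * config$sigma_size
  sig_tot <- sqrt(log(1 + (tg$sd / tg$mean)^2))
  load <- sqrt(pmax(sig_tot^2 - size_comp^2 - config$sigma_resid^2, 1e-4))
  sig_use2 <- size_comp^2 + load^2 + config$sigma_resid^2
  list(meanlog = log(tg$mean) - sig_use2 / 2,
       kappa = load, size_comp = size_comp)
}

# Deterministic depot targets from latent factors (no residual term).
.depot_targets_from_params <- function(params, config) {
  ld <- .depot_loadings(config, params$sex)
  lS <- log(params$size_factor) * config$size_exponent
  v <- params$vat_asat_shape
  c(VAT = exp(ld$meanlog[["VAT"]] + lS + ld$kappa[["VAT"]] * v),
    ASAT = exp(ld$meanlog[["ASAT"]] + lS - ld$kappa[["ASAT"]] * v),
    GFAT = exp(ld$meanlog[["GFAT"]] + lS) * params$gfat_factor)
}

# All derived geometry for one phantom: outer dimensions (mm), abdominal
# fat split, gluteofemoral shell fraction, and analytic capacities.
.phantom_geometry <- function(params, config = population_config()) {
  g <- .base_geometry[[params$sex]]
  hs <- params$height_mm / 1750
  S <- params$size_factor
  tp <- params$torso_prop
  v <- params$vat_asat_shape
  H <- params$height_mm
  lf <- .landmark_fracs

  chest <- g$chest * hs * S * tp
  # Abdominal outer ellipse: perimeter fixed by size, aspect modulated by
  # the fat-distribution axis (visceral builds are deeper/narrower).
  base_ab <- g$abdomen * hs * S * tp
  per <- ellipse_perimeter(base_ab[1], base_ab[2])
  aspect <- (base_ab[2] / base_ab[1]) * exp(config$kappa_ecc * v)
  a_ab <- per / ellipse_perimeter(1, aspect)
  b_ab <- aspect * a_ab
  gf_girth <- params$gfat_factor^0.3
  pelvis <- g$pelvis * hs * S * params$leg_prop * c(gf_girth, 1)
  thigh_top <- g$thigh_top * hs * S * params$leg_prop * gf_girth
  knee <- g$knee * hs * S * params$leg_prop
  ankle <- g$ankle * hs * S^0.25 * sqrt(params$leg_prop)
  arm <- g$arm * hs * S * params$arm_prop
  head <- g$head * hs * S^0.25
  neck <- g$neck * hs * S^0.25

  targets <- c(VAT = params$vat_l, ASAT = params$asat_l, GFAT = params$gfat_l)
  if (length(targets) < 3) targets <- .depot_targets_from_params(params, config)

  # Abdominal capacity and the VAT core / ASAT ring split realising the
  # target volumes at this girth.
  len_ab <- diff(lf$abdomen) * H
  cap_ab_l <- pi * a_ab * b_ab * len_ab / 1e6
  f_tot <- min((targets[["VAT"]] + targets[["ASAT"]]) / cap_ab_l, 0.90)
  phi <- targets[["VAT"]] / (targets[["VAT"]] + targets[["ASAT"]])
  ring_in <- sqrt(1 - f_tot * (1 - phi))
  cv <- min(sqrt(f_tot * phi), ring_in * 0.92)

  # Gluteofemoral shell fraction over pelvis + thigh slices.
  len_pv <- diff(lf$pelvis) * H
  len_th <- (lf$gfat_end - lf$thigh[1]) * H
  r_gfat_end <- thigh_top + (knee - thigh_top) *
    (lf$gfat_end - lf$thigh[1]) / diff(lf$thigh)
  mean_r2 <- (thigh_top^2 + thigh_top * r_gfat_end + r_gfat_end^2) / 3
  cap_g_l <- (pi * pelvis[1] * pelvis[2] * len_pv + 2 * pi * mean_r2 * len_th) / 1e6
  frac_g <- min(targets[["GFAT"]] / cap_g_l, 0.6975)
  tg <- 1 - sqrt(1 - frac_g)
  tg <- min(max(tg, 0.02), 0.45)

  list(chest = chest, a_ab = a_ab, b_ab = b_ab,
       belly_shift = config$kappa_shift * v * b_ab,
       pelvis = pelvis, thigh_top = thigh_top, knee = knee, ankle = ankle,
       arm = arm, head = head, neck = neck,
       cv = cv, ring_in = ring_in, tg = tg,
       targets = targets, cap_ab_l = cap_ab_l, cap_g_l = cap_g_l,
       waist_perimeter_mm = per)
}

#' Generate a labelled synthetic body volume
#'
#' Builds a 3-D body phantom as stacked elliptical cross-sections: a torso
#' with an interior VAT core and a subcutaneous ASAT ring on abdominal
#' slices, a GFAT shell over hips and thighs, two legs, two arms and a head.
#' The result is deterministic given `(params, seed)` and forms a single
#' 26-connected component.
#'
#' @param params A [phantom_params()] object.
#' @param spacing Voxel spacing (z, y, x) in mm.
#' @param seed Integer seed for intensity noise.
#' @param intensities If `TRUE`, simulate scalar voxel intensities (bright
#'   fat phase, darker lean tissue, noise per `params$noise_sd`).
#' @param config A [population_config()] supplying latent-axis couplings.
#' @return A `body_volume` object with `labels`, optional `voxels`,
#'   `spacing` and slice landmark annotations.
#' @export
generate_phantom <- function(params, spacing = c(3.0, 2.232, 2.232),
                             seed = 1L, intensities = FALSE,
                             config = population_config()) {
  stopifnot(inherits(params, "phantom_params"), all(spacing > 0))
  geo <- .phantom_geometry(params, config)
  H <- params$height_mm
  dz <- spacing[1]; dy <- spacing[2]; dx <- spacing[3]
  nz <- ceiling(H / dz)
  max_half_w <- max(geo$chest[1] + 2 * geo$arm, geo$pelvis[1],
                    geo$a_ab, geo$head[1]) + 4 * dx
  max_half_d <- max(geo$chest[2], geo$b_ab + abs(geo$belly_shift),
                    geo$pelvis[2], geo$head[2]) + 4 * dy
  nx <- ceiling(2 * max_half_w / dx)
  ny <- ceiling(2 * max_half_d / dy)
  cx0 <- nx * dx / 2
  cy0 <- ny * dy / 2
  lf <- .landmark_fracs
  frac <- (seq_len(nz) - 0.5) * dz / H
  L <- DEPOT_LABELS

  in_band <- function(b) which(frac >= b[1] & frac < b[2])
  rows <- list()
  add <- function(z, cx, cy, a, b, t1, l1, t2 = -1, l2 = -1, t3 = -1, l3 = -1) {
    if (!length(z)) return()
    rows[[length(rows) + 1L]] <<- cbind(z, cx, cy, a, b, t1, l1, t2, l2, t3, l3)
  }

  # Head (ellipsoidal taper) and neck.
  zi <- in_band(lf$head)
  if (length(zi)) {
    rel <- (frac[zi] - mean(lf$head)) / (diff(lf$head) / 2)
    sh <- sqrt(pmax(1 - rel^2, 0.06))
    add(zi, cx0, cy0, geo$head[1] * sh, geo$head[2] * sh, 1, L[["lean"]])
  }
  add(in_band(lf$neck), cx0, cy0, geo$neck, geo$neck, 1, L[["lean"]])

  # Torso outer profile: piecewise-linear half-width/depth over landmarks.
  tor_f <- c(lf$shoulder[1], lf$chest[1], lf$upper_transition[1],
             lf$abdomen[1], lf$lower_transition[1], lf$pelvis[1],
             lf$pelvis[2])
  tor_a <- c(geo$neck * 1.3, geo$chest[1], geo$chest[1], geo$a_ab, geo$a_ab,
             geo$pelvis[1], geo$pelvis[1])
  tor_b <- c(geo$neck * 1.2, geo$chest[2], geo$chest[2], geo$b_ab, geo$b_ab,
             geo$pelvis[2], geo$pelvis[2])
  tor_cy <- c(0, 0, 0, -geo$belly_shift, -geo$belly_shift, 0, 0) + cy0
  zi <- which(frac >= lf$shoulder[1] & frac < lf$pelvis[2])
  a_t <- stats::approx(tor_f, tor_a, frac[zi], rule = 2)$y
  b_t <- stats::approx(tor_f, tor_b, frac[zi], rule = 2)$y
  cy_t <- stats::approx(tor_f, tor_cy, frac[zi], rule = 2)$y
  reg_ab <- frac[zi] >= lf$abdomen[1] & frac[zi] < lf$abdomen[2]
  reg_pv <- frac[zi] >= lf$pelvis[1] & frac[zi] < lf$pelvis[2]
  # Abdominal slices: VAT core, lean wall, subcutaneous ASAT ring.
  add(zi[reg_ab], cx0, cy_t[reg_ab], a_t[reg_ab], b_t[reg_ab],
      geo$cv, L[["VAT"]], geo$ring_in, L[["lean"]], 1, L[["ASAT"]])
  # Pelvis: lean interior, gluteofemoral shell.
  add(zi[reg_pv], cx0, cy_t[reg_pv], a_t[reg_pv], b_t[reg_pv],
      1 - geo$tg, L[["lean"]], 1, L[["GFAT"]])
  # Remaining torso: lean with a thin "other fat" subcutaneous ring.
  oth <- !(reg_ab | reg_pv)
  add(zi[oth], cx0, cy_t[oth], a_t[oth], b_t[oth],
      0.95, L[["lean"]], 1, L[["other_fat"]])

  # Legs: two tapering ellipses; GFAT shell down to gfat_end.
  zi <- which(frac >= lf$thigh[1] & frac < lf$leg_end)
  if (length(zi)) {
    leg_f <- c(lf$thigh[1], lf$thigh[2], lf$leg_end)
    leg_r <- c(geo$thigh_top, geo$knee, geo$ankle)
    r_l <- stats::approx(leg_f, leg_r, frac[zi], rule = 2)$y
    x_leg <- 0.52 * geo$pelvis[1]
    has_g <- frac[zi] < lf$gfat_end
    for (s in c(-1, 1)) {
      add(zi[has_g], cx0 + s * x_leg, cy0, r_l[has_g], r_l[has_g],
          1 - geo$tg, L[["lean"]], 1, L[["GFAT"]])
      add(zi[!has_g], cx0 + s * x_leg, cy0, r_l[!has_g], r_l[!has_g],
          1, L[["lean"]])
    }
  }

  # Arms: circles overlapping the torso laterally (guarantees connectivity).
  zi <- in_band(lf$arms)
  if (length(zi)) {
    a_at <- stats::approx(tor_f, tor_a, frac[zi], rule = 2)$y
    for (s in c(-1, 1)) {
      add(zi, cx0 + s * (a_at + 0.75 * geo$arm), cy0, geo$arm, geo$arm,
          1, L[["lean"]])
    }
  }

  if (!length(rows)) stop("empty phantom")
  shapes <- do.call(rbind, rows)
  labels <- .paint_shapes(c(nz, ny, nx), shapes, spacing)
  # degenerate parameter sets rasterise to (near) nothing
  body_l <- sum(.label_summary(labels, dim(labels))$label_counts[2:6]) *
    prod(spacing) / 1e6
  if (body_l < 0.5) stop("empty phantom")

  voxels <- NULL
  if (isTRUE(intensities)) {
    base <- c(0.02, 0.55, 0.85, 0.85, 0.85, 0.85)[labels + 1L]
    voxels <- with_seed(seed, base + rnorm(length(base), 0, params$noise_sd))
    dim(voxels) <- dim(labels)
  }
  landmarks <- list(
    abdomen = range(in_band(lf$abdomen)),
    gluteal = range(which(frac >= lf$gluteal[1] & frac < lf$gluteal[2])))
  body_volume(voxels = voxels, spacing = spacing, labels = labels,
              landmarks = landmarks, params = params)
}

#' Construct a body volume container
#'
#' @param voxels Optional 3-D scalar array, axis order (z, y, x).
#' @param spacing Voxel spacing (z, y, x) in mm.
#' @param labels Optional 3-D integer array of [DEPOT_LABELS] codes, same
#'   shape as `voxels`.
#' @param landmarks Optional list of slice-index ranges (e.g. `abdomen`,
#'   `gluteal`) used by anthropometric measurement.
#' @param params Optional generating [phantom_params()].
#' @return A `body_volume` object.
#' @export
body_volume <- function(voxels = NULL, spacing, labels = NULL,
                        landmarks = NULL, params = NULL) {
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (!is.null(voxels) && !is.null(labels))
    stopifnot(identical(dim(voxels), dim(labels)))
  if (is.null(voxels) && is.null(labels))
    stop("need voxels or labels")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 labels = labels, landmarks = landmarks, params = params),
            class = "body_volume")
}

#' @export
print.body_volume <- function(x, ...) {
  d <- dim(x$labels %||% x$voxels)
  cat(sprintf("<body_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Measure true depot volumes from a labelled volume
#'
#' Each depot volume is the labelled voxel count times the voxel volume:
#' `count * dz * dy * dx / 1e6` liters.
#'
#' @param vol A labelled `body_volume`.
#' @return Named numeric vector `VAT_L`, `ASAT_L`, `GFAT_L`, `ratio`.
#' @export
measure_truth_depots <- function(vol) {
  stopifnot(inherits(vol, "body_volume"))
  if (is.null(vol$labels)) stop("labels required")
  vx_l <- prod(vol$spacing) / 1e6
  counts <- .label_summary(vol$labels, dim(vol$labels))$label_counts
  vat <- counts[DEPOT_LABELS[["VAT"]] + 1L] * vx_l
  asat <- counts[DEPOT_LABELS[["ASAT"]] + 1L] * vx_l
  gfat <- counts[DEPOT_LABELS[["GFAT"]] + 1L] * vx_l
  c(VAT_L = vat, ASAT_L = asat, GFAT_L = gfat,
    ratio = vat_asat_ratio(vat, asat))
}

#' VAT/ASAT ratio from depot volumes
#'
#' @param vat_l,asat_l Depot volumes in liters.
#' @return `vat_l / asat_l`; errors when `asat_l` is zero.
#' @export
vat_asat_ratio <- function(vat_l, asat_l) {
  if (any(asat_l == 0)) stop("ratio undefined")
  vat_l / asat_l
}

#' Measure anthropometrics from a labelled volume
#'
#' Derives height from the occupied slice extent, weight from per-label
#' voxel volumes and tissue densities (lean 1.06 kg/L, fat 0.92 kg/L),
#' waist and hip circumference as marching-squares contour perimeters of the
#' body mask at the widest abdominal and gluteal slices, plus BMI, the
#' waist-to-hip ratio, and five noisy bioimpedance measures driven by lean
#' volume over height squared.
#'
#' @param vol A labelled `body_volume`.
#' @param impedance_noise_sd Measurement noise SD for the impedance values.
#' @return One-row `data.frame` of anthropometric fields.
#' @export
measure_anthropometrics <- function(vol, impedance_noise_sd = 10) {
  stopifnot(inherits(vol, "body_volume"))
  if (is.null(vol$labels)) stop("labels required")
  lab <- vol$labels
  dz <- vol$spacing[1]
  summ <- .label_summary(lab, dim(lab))
  slice_area <- summ$slice_counts
  occupied <- which(slice_area > 0)
  if (!length(occupied)) stop("empty volume")
  height_cm <- length(occupied) * dz / 10
  vx_l <- prod(vol$spacing) / 1e6
  counts <- summ$label_counts
  lean_l <- counts[2] * vx_l
  fat_l <- sum(counts[3:6]) * vx_l
  weight_kg <- DENSITY_LEAN * lean_l + DENSITY_FAT * fat_l

  lm <- vol$landmarks
  if (is.null(lm)) {
    nz <- dim(lab)[1]
    lm <- list(abdomen = round(c(nz / 3, 2 * nz / 3)),
               gluteal = round(c(nz / 2, 3 * nz / 4)))
  }
  widest <- function(zr) {
    zr <- max(1, zr[1]):min(dim(lab)[1], zr[2])
    if (!length(zr)) stop("no slices in measurement range")
    areas <- slice_area[zr]
    if (all(areas == 0)) stop("no abdominal slices")
    zr[which.max(areas)]
  }
  z_w <- widest(lm$abdomen)
  z_h <- widest(lm$gluteal)
  waist_cm <- contour_perimeter(lab[z_w, , ] != 0L, vol$spacing[2:3]) / 10
  hip_cm <- contour_perimeter(lab[z_h, , ] != 0L, vol$spacing[2:3]) / 10

  bmi <- weight_kg / (height_cm / 100)^2
  lean_idx <- lean_l / (height_cm / 100)^2
  imp <- .impedance_from_lean(lean_idx, impedance_noise_sd)
  out <- data.frame(height_cm = height_cm, weight_kg = weight_kg, BMI = bmi,
                    waist_cm = waist_cm, hip_cm = hip_cm,
                    WHR = waist_cm / hip_cm)
  out[paste0("imp", 1:5)] <- as.list(imp)
  out
}

# Five affine bioimpedance channels of the lean-volume index.
.impedance_from_lean <- function(lean_idx, noise_sd) {
  alpha <- c(560, 540, 500, 330, 640)
  beta <- c(-8, -7.5, -8.5, -5, -10)
  alpha + beta * lean_idx + rnorm(5, 0, noise_sd)
}

#' Default per-disease coefficient sets for disease simulation
#'
#' Per-sex odds ratios and hazard ratios per SD of the VAT/ASAT ratio, BMI
#' and age, with baseline prevalences matching the study population (male
#' T2D 6.5%, CAD 7.9%, hypertension 37.0%, hypercholesterolemia 27.7%;
#' female 3.1%, 2.0%, 24.6%, 15.4%). Incident hazards are nonzero for
#' type 2 diabetes and coronary artery disease only.
#'
#' @return Named list of per-disease coefficient lists.
#' @export
default_disease_effects <- function() {
  list(
    t2d = list(prev = c(male = 0.065, female = 0.031),
               or_ratio = c(male = 1.78, female = 1.97),
               or_bmi = 1.6, or_age = 1.3,
               base_hazard = 0.0022,
               hr_ratio = c(male = 1.33, female = 1.51),
               hr_bmi = 1.4, hr_age = 1.2),
    cad = list(prev = c(male = 0.079, female = 0.020),
               or_ratio = c(male = 1.22, female = 1.21),
               or_bmi = 1.25, or_age = 1.6,
               base_hazard = 0.005,
               hr_ratio = c(male = 1.19, female = 1.09),
               hr_bmi = 1.2, hr_age = 1.5),
    htn = list(prev = c(male = 0.370, female = 0.246),
               or_ratio = c(male = 1.31, female = 1.23),
               or_bmi = 1.7, or_age = 1.4,
               base_hazard = 0, hr_ratio = 1, hr_bmi = 1, hr_age = 1),
    chol = list(prev = c(male = 0.277, female = 0.154),
                or_ratio = c(male = 1.2, female = 1.2),
                or_bmi = 1.3, or_age = 1.3,
                base_hazard = 0, hr_ratio = 1, hr_bmi = 1, hr_age = 1))
}

# Resolve a possibly sex-specific coefficient for a vector of sexes.
.sex_coef <- function(x, sex) {
  if (length(x) == 1) return(rep(unname(x), length(sex)))
  unname(x[sex])
}

#' Simulate prevalent and incident disease labels for a cohort
#'
#' Prevalent disease follows a logistic model in sex-standardized VAT/ASAT
#' ratio, BMI and age (plus a small imaging-center intercept). Incident
#' event times are exponential with the analogous log-hazard, administratively
#' censored at a per-participant uniform follow-up whose realized median
#' matches `follow_up_median_years`. Prevalent cases are excluded from the
#' incident risk set.
#'
#' @param cohort Cohort `data.frame` with `sex`, `age_years`, `BMI`,
#'   `ratio` and optionally `center` columns.
#' @param effects Per-disease coefficient sets, see
#'   [default_disease_effects()].
#' @param follow_up_median_years Target median follow-up (years).
#' @param seed Integer seed.
#' @param center_effects Logit intercept shift per imaging center.
#' @return `cohort` with per-disease `_prev`, `_inc`, `_fu`, `_time` columns.
#' @export
simulate_diseases <- function(cohort, effects = default_disease_effects(),
                              follow_up_median_years = 2.8, seed = 1L,
                              center_effects = c(0, 0.05, -0.05)) {
  stopifnot(all(c("sex", "age_years", "BMI", "ratio") %in% names(cohort)))
  for (eff in effects) {
    vals <- unlist(eff[c("prev", "or_ratio", "or_bmi", "or_age",
                         "base_hazard", "hr_ratio", "hr_bmi", "hr_age")])
    if (any(!is.finite(vals))) stop("nonfinite coefficients")
  }
  n <- nrow(cohort)
  z_ratio <- standardize_exposure(cohort$ratio, cohort$sex)
  z_bmi <- standardize_exposure(cohort$BMI, cohort$sex)
  z_age <- standardize_exposure(cohort$age_years, cohort$sex)
  cent <- if ("center" %in% names(cohort)) {
    center_effects[(as.integer(factor(cohort$center)) - 1L) %%
                     length(center_effects) + 1L]
  } else rep(0, n)

  with_seed(seed, {
    for (d in names(effects)) {
      eff <- effects[[d]]
      lp <- qlogis(.sex_coef(eff$prev, cohort$sex)) +
        log(.sex_coef(eff$or_ratio, cohort$sex)) * z_ratio +
        log(.sex_coef(eff$or_bmi, cohort$sex)) * z_bmi +
        log(.sex_coef(eff$or_age, cohort$sex)) * z_age + cent
      prev <- rbinom(n, 1, plogis(lp))
      rate <- .sex_coef(eff$base_hazard, cohort$sex) *
        exp(log(.sex_coef(eff$hr_ratio, cohort$sex)) * z_ratio +
            log(.sex_coef(eff$hr_bmi, cohort$sex)) * z_bmi +
            log(.sex_coef(eff$hr_age, cohort$sex)) * z_age)
      tt <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-300)), Inf)
      cens <- runif(n, 0, 2 * follow_up_median_years)
      inc <- as.integer(tt <= cens & prev == 0)
      fu <- ifelse(prev == 1, NA_real_, cens)
      time <- ifelse(prev == 1, NA_real_, pmin(tt, cens))
      cohort[[paste0(d, "_prev")]] <- prev
      cohort[[paste0(d, "_inc")]] <- ifelse(prev == 1, 0L, inc)
      cohort[[paste0(d, "_fu")]] <- fu
      cohort[[paste0(d, "_time")]] <- time
    }
  })
  cohort
}

#' Sample a tabular synthetic population (no voxel volumes)
#'
#' Draws the latent factors (sex, height, girth scale, fat-distribution
#' axis, gluteofemoral scale) and computes depot volumes and anthropometrics
#' analytically from the phantom geometry; fast enough for cohort sizes in
#' the tens of thousands. Depot columns from this path coincide with
#' voxel-measured values up to rasterisation error.
#'
#' @param n Number of participants (>= 2).
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return `data.frame` with identifiers, latent factors, depot volumes,
#'   anthropometrics and center assignments (no disease columns).
#' @export
sample_population <- function(n, config = population_config(), seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  with_seed(seed, {
    sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
    height_mm <- unname(pmin(pmax(rnorm(n, config$height_mean_mm[sex],
                                        config$height_sd_mm[sex]), 1350), 2050))
    age <- unname(pmin(pmax(rnorm(n, config$age_mean[sex],
                                  config$age_sd[sex]), 45), 82))
    size_factor <- exp(rnorm(n, 0, config$sigma_size))
    shape <- rnorm(n)
    # gluteofemoral latent folded into a multiplicative factor
    g_load <- vapply(c("male", "female"), function(s)
      .depot_loadings(config, s)$kappa[["GFAT"]], numeric(1))
    gfat_factor <- unname(exp(rnorm(n, 0, 1) * g_load[sex] +
                                rnorm(n, 0, config$sigma_resid)))
    res_v <- rnorm(n, 0, config$sigma_resid)
    res_a <- rnorm(n, 0, config$sigma_resid)
    center <- sample.int(config$n_centers, n, replace = TRUE)

    out <- data.frame(id = sprintf("P%05d", seq_len(n)), sex = sex,
                      age_years = age, height_mm = height_mm,
                      size_factor = size_factor, vat_asat_shape = shape,
                      gfat_factor = gfat_factor, center = center,
                      stringsAsFactors = FALSE)
    geo_rows <- lapply(seq_len(n), function(i) {
      p <- phantom_params(sex = sex[i], height_mm = height_mm[i],
                          size_factor = size_factor[i],
                          vat_asat_shape = shape[i],
                          gfat_factor = gfat_factor[i])
      ld <- .depot_loadings(config, sex[i])
      lS <- log(size_factor[i]) * config$size_exponent
      p$vat_l <- exp(ld$meanlog[["VAT"]] + lS + ld$kappa[["VAT"]] * shape[i] +
                       res_v[i])
      p$asat_l <- exp(ld$meanlog[["ASAT"]] + lS - ld$kappa[["ASAT"]] * shape[i] +
                        res_a[i])
      p$gfat_l <- exp(ld$meanlog[["GFAT"]] + lS) * gfat_factor[i]
      geo <- .phantom_geometry(p, config)
      abd <- .realized_abdominal(geo, height_mm[i])
      c(vat = unname(abd[["VAT"]]),
        asat = unname(abd[["ASAT"]]),
        gfat = unname(.realized_gfat(geo, height_mm[i])),
        waist = geo$waist_perimeter_mm / 10,
        hip = ellipse_perimeter(geo$pelvis[1], geo$pelvis[2]) / 10,
        body_l = .analytic_body_volume_l(p, geo))
    })
    geo_mat <- do.call(rbind, geo_rows)
    out$VAT_L <- geo_mat[, "vat"]
    out$ASAT_L <- geo_mat[, "asat"]
    out$GFAT_L <- geo_mat[, "gfat"]
    out$ratio <- vat_asat_ratio(out$VAT_L, out$ASAT_L)
    fat_l <- out$VAT_L + out$ASAT_L + out$GFAT_L +
      0.05 * geo_mat[, "body_l"]  # thin "other fat" ring
    lean_l <- pmax(geo_mat[, "body_l"] - fat_l, 1)
    out$height_cm <- height_mm / 10
    out$weight_kg <- DENSITY_LEAN * lean_l + DENSITY_FAT * fat_l
    out$BMI <- out$weight_kg / (out$height_cm / 100)^2
    out$waist_cm <- geo_mat[, "waist"] + rnorm(n, 0, 1)
    out$hip_cm <- geo_mat[, "hip"] + rnorm(n, 0, 1)
    out$WHR <- out$waist_cm / out$hip_cm
    lean_idx <- lean_l / (out$height_cm / 100)^2
    imp <- t(vapply(lean_idx, .impedance_from_lean, numeric(5),
                    noise_sd = config$impedance_noise_sd))
    colnames(imp) <- paste0("imp", 1:5)
    cbind(out, as.data.frame(imp))
  })
}

# Realized abdominal depot volumes (L) after clamping, analytic.
.realized_abdominal <- function(geo, height_mm) {
  len_ab <- diff(.landmark_fracs$abdomen) * height_mm
  area <- pi * geo$a_ab * geo$b_ab
  c(VAT = geo$cv^2 * area * len_ab / 1e6,
    ASAT = (1 - geo$ring_in^2) * area * len_ab / 1e6)
}

.realized_gfat <- function(geo, height_mm) {
  frac_g <- 1 - (1 - geo$tg)^2
  frac_g * geo$cap_g_l
}

# Total analytic body volume (L) from the slice profile.
.analytic_body_volume_l <- function(params, geo) {
  lf <- .landmark_fracs
  H <- params$height_mm
  seg <- function(band, area) diff(band) * H * area / 1e6
  head_v <- seg(lf$head, pi * geo$head[1] * geo$head[2]) * 2 / 3
  neck_v <- seg(lf$neck, pi * geo$neck^2)
  chest_v <- seg(c(lf$shoulder[1], lf$abdomen[1]),
                 pi * mean(c(geo$neck * 1.3, geo$chest[1], geo$chest[1])) *
                   mean(c(geo$neck * 1.2, geo$chest[2], geo$chest[2])))
  ab_v <- seg(lf$abdomen, pi * geo$a_ab * geo$b_ab)
  pv_v <- seg(c(lf$lower_transition[1], lf$pelvis[2]),
              pi * geo$pelvis[1] * geo$pelvis[2])
  thigh_r2 <- (geo$thigh_top^2 + geo$thigh_top * geo$knee + geo$knee^2) / 3
  thigh_v <- seg(lf$thigh, 2 * pi * thigh_r2)
  calf_r2 <- (geo$knee^2 + geo$knee * geo$ankle + geo$ankle^2) / 3
  calf_v <- seg(c(lf$thigh[2], lf$leg_end), 2 * pi * calf_r2)
  arm_v <- seg(lf$arms, 2 * pi * geo$arm^2) * 0.6  # part is inside torso
  head_v + neck_v + chest_v + ab_v + pv_v + thigh_v + calf_v + arm_v
}

#' Generate a full synthetic cohort with volumes and silhouettes
#'
#' Samples a population, rasterises a labelled phantom per participant,
#' measures true depot volumes and anthropometrics from the voxels, builds
#' two-panel silhouettes, and simulates disease labels. Optionally writes
#' NIfTI volumes, silhouette PNGs and the cohort CSV to `dir`.
#'
#' @param n Cohort size (>= 2).
#' @param config A [population_config()].
#' @param seed Integer seed controlling every stochastic stage.
#' @param dir Optional output directory.
#' @param silhouettes Build silhouettes (needed for model training).
#' @param keep_volumes Keep voxel volumes in the returned object (memory
#'   heavy; off by default).
#' @param write_nifti Write per-participant NIfTI volumes when `dir` is set.
#' @param progress Print progress every 500 participants.
#' @return List with `cohort` (data.frame), `silhouettes` (list of
#'   `silhouette_image`), optionally `volumes`.
#' @export
generate_cohort <- function(n, config = population_config(), seed = 1L,
                            dir = NULL, silhouettes = TRUE,
                            keep_volumes = FALSE, write_nifti = FALSE,
                            progress = FALSE) {
  if (n < 2) stop("n must be >= 2")
  pop <- sample_population(n, config, seed)
  sils <- if (silhouettes) vector("list", n) else NULL
  vols <- if (keep_volumes) vector("list", n) else NULL
  meas <- vector("list", n)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (silhouettes) dir.create(file.path(dir, "silhouettes"),
                                showWarnings = FALSE)
    if (write_nifti) dir.create(file.path(dir, "volumes"),
                                showWarnings = FALSE)
  }
  imp_seeds <- with_seed(seed + 1L, sample.int(2^30, n))
  for (i in seq_len(n)) {
    p <- phantom_params(sex = pop$sex[i], height_mm = pop$height_mm[i],
                        size_factor = pop$size_factor[i],
                        vat_asat_shape = pop$vat_asat_shape[i],
                        gfat_factor = pop$gfat_factor[i],
                        noise_sd = config$noise_sd,
                        vat_l = pop$VAT_L[i], asat_l = pop$ASAT_L[i],
                        gfat_l = pop$GFAT_L[i])
    vol <- generate_phantom(p, spacing = config$spacing, seed = imp_seeds[i],
                            intensities = config$intensities, config = config)
    depots <- measure_truth_depots(vol)
    anth <- with_seed(imp_seeds[i],
                      measure_anthropometrics(vol, config$impedance_noise_sd))
    meas[[i]] <- c(depots, unlist(anth))
    if (silhouettes) {
      sil <- volume_to_silhouette(vol)
      attr(sil, "id") <- pop$id[i]
      sils[[i]] <- sil
      if (!is.null(dir))
        write_silhouette(sil, file.path(dir, "silhouettes",
                                        paste0(pop$id[i], ".png")))
    }
    if (keep_volumes) vols[[i]] <- vol
    if (!is.null(dir) && write_nifti)
      write_body_volume(vol, file.path(dir, "volumes",
                                       paste0(pop$id[i], ".nii.gz")))
    if (progress && i %% 500 == 0) message("phantom ", i, "/", n)
  }
  mm <- do.call(rbind, meas)
  cohort <- pop
  for (cc in c("VAT_L", "ASAT_L", "GFAT_L", "ratio", "height_cm",
               "weight_kg", "BMI", "waist_cm", "hip_cm", "WHR",
               paste0("imp", 1:5)))
    cohort[[cc]] <- unname(mm[, cc])
  cohort <- simulate_diseases(cohort, config$disease_effects,
                              config$follow_up_median_years, seed + 2L,
                              config$center_effects)
  if (!is.null(dir)) {
    write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    yaml::write_yaml(list(n = n, seed = seed,
                          config_hash = object_hash(config),
                          version = silfat_version()),
                     file.path(dir, "cohort_manifest.yaml"))
  }
  list(cohort = cohort, silhouettes = sils, volumes = vols)
}

#' Write a body volume as NIfTI with spacing in the header
#'
#' @param vol A `body_volume`; labels are written when voxels are absent.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_body_volume <- function(vol, path) {
  stopifnot(inherits(vol, "body_volume"))
  arr <- vol$voxels %||% vol$labels
  # NIfTI stores x fastest: permute (z,y,x) -> (x,y,z)
  arr_xyz <- aperm(arr, c(3, 2, 1))
  img <- RNifti::asNifti(arr_xyz)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a body volume
#'
#' The array is reoriented to axis order (z, y, x) with spacing taken from
#' the header.
#'
#' @param path NIfTI file path.
#' @param labelled Treat integer-valued data as a label array.
#' @return A `body_volume`.
#' @export
read_body_volume <- function(path, labelled = NULL) {
  img <- RNifti::readNifti(path)
  sp <- rev(RNifti::pixdim(img)[1:3])
  arr <- aperm(as.array(img), c(3, 2, 1))
  if (is.null(labelled))
    labelled <- all(arr == round(arr)) && max(arr) <= 8
  if (labelled) {
    storage.mode(arr) <- "integer"
    body_volume(spacing = sp, labels = arr)
  } else {
    body_volume(voxels = arr, spacing = sp)
  }
}
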
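test_that("phantom generation is deterministic and single-component", {
  p <- phantom_params("male")
  sp <- c(6, 4.464, 4.464)
  v1 <- generate_phantom(p, spacing = sp, seed = 5)
  v2 <- generate_phantom(p, spacing = sp, seed = 5)
  expect_identical(v1$labels, v2$labels)
  for (sex in c("male", "female")) {
    v <- generate_phantom(phantom_params(sex), spacing = sp)
    expect_equal(silfat:::.count_components_3d(v$labels > 0L, dim(v$labels)), 1)
  }
})

test_that("doubling size_factor enlarges every occupied cross-section", {
  sp <- c(6, 4.464, 4.464)
  v1 <- generate_phantom(phantom_params("male", size_factor = 1), spacing = sp)
  v2 <- generate_phantom(phantom_params("male", size_factor = 2), spacing = sp)
  a1 <- rowSums(v1$labels != 0L, dims = 1)
  a2 <- rowSums(v2$labels != 0L, dims = 1)
  occ <- a1 > 0
  expect_true(all(a2[occ] > a1[occ]))
})

test_that("fat-distribution axis shifts VAT/ASAT at nearly fixed waist", {
  sp <- c(3, 2.232, 2.232)
  shapes <- seq(-1.5, 1.5, length.out = 20)
  ratio <- waist <- numeric(20)
  for (i in seq_along(shapes)) {
    v <- generate_phantom(phantom_params("male", vat_asat_shape = shapes[i]),
                          spacing = sp)
    ratio[i] <- measure_truth_depots(v)[["ratio"]]
    waist[i] <- measure_anthropometrics(v)$waist_cm
  }
  expect_true(all(diff(ratio) > 0))
  expect_true(all(abs(waist - waist[10]) / waist[10] < 0.01))
})

test_that("depot truth volumes follow the voxel-count formula exactly", {
  lab <- array(0L, c(10, 20, 20))
  lab[1:5, 1:10, 1:20] <- DEPOT_LABELS[["VAT"]]   # 1000 voxels
  lab[6, , ] <- DEPOT_LABELS[["ASAT"]]
  vol <- body_volume(spacing = c(3.0, 2.232, 2.232), labels = lab)
  d <- measure_truth_depots(vol)
  expect_equal(d[["VAT_L"]], 1000 * 3.0 * 2.232 * 2.232 / 1e6,
               tolerance = 1e-6 / d[["VAT_L"]])
  expect_identical(d[["GFAT_L"]], 0)
  lab[lab == DEPOT_LABELS[["ASAT"]]] <- 0L
  vol0 <- body_volume(spacing = c(3.0, 2.232, 2.232), labels = lab)
  expect_error(measure_truth_depots(vol0), "ratio undefined")
})

test_that("per-label volumes conserve total body volume to 1e-9 relative", {
  v <- generate_phantom(phantom_params("female"), spacing = c(6, 4.464, 4.464))
  vx <- prod(v$spacing) / 1e6
  total <- sum(v$labels != 0L) * vx
  per_label <- vapply(DEPOT_LABELS[-1], function(l)
    sum(v$labels == l) * vx, numeric(1))
  expect_equal(sum(per_label), total, tolerance = 1e-9)
})

test_that("depot volumes are monotone in their generating factors", {
  sp <- c(6, 4.464, 4.464)
  sizes <- c(0.8, 1.0, 1.2)
  meas <- function(...) measure_truth_depots(
    generate_phantom(phantom_params("female", ...), spacing = sp))
  by_size <- vapply(sizes, function(s) meas(size_factor = s), numeric(4))
  for (j in 1:3) expect_true(all(diff(by_size[j, ]) >= 0))
  by_gfat <- vapply(c(0.7, 1, 1.4), function(g) meas(gfat_factor = g),
                    numeric(4))
  expect_true(all(diff(by_gfat["GFAT_L", ]) >= 0))
  by_shape <- vapply(c(-1, 0, 1), function(v) meas(vat_asat_shape = v),
                     numeric(4))
  expect_true(all(diff(by_shape["VAT_L", ]) >= 0))
})

test_that("anthropometric measurement recovers a cylinder's circumference", {
  vol <- cylinder_volume(radius_mm = 150)
  a <- measure_anthropometrics(vol)
  expect_equal(a$waist_cm, 2 * pi * 15, tolerance = 1.5 / (2 * pi * 15))
  expect_equal(a$BMI, a$weight_kg / (a$height_cm / 100)^2, tolerance = 1e-9)
})

test_that("anthropometrics obey the linear-scaling law", {
  v <- generate_phantom(phantom_params("male"), spacing = c(6, 4.464, 4.464))
  v2 <- body_volume(spacing = v$spacing * 2, labels = v$labels,
                    landmarks = v$landmarks)
  a1 <- measure_anthropometrics(v)
  a2 <- measure_anthropometrics(v2)
  expect_equal(a2$height_cm, 2 * a1$height_cm)
  expect_equal(a2$weight_kg, 8 * a1$weight_kg)
  expect_equal(a2$BMI, 2 * a1$BMI)
  # worked BMI arithmetic at population-typical male values
  expect_equal(round(83.8 / 1.763^2, 2), 26.96)
})

test_that("degenerate parameters raise an empty-phantom error", {
  expect_error(generate_phantom(phantom_params("male", size_factor = 1e-6),
                                spacing = c(6, 4.464, 4.464)),
               "empty phantom")
})

test_that("null disease model matches its target prevalence", {
  pop <- sample_population(5000, seed = 42)
  eff <- list(dz = list(prev = 0.05, or_ratio = 1, or_bmi = 1, or_age = 1,
                        base_hazard = 0, hr_ratio = 1, hr_bmi = 1,
                        hr_age = 1))
  co <- simulate_diseases(pop, eff, seed = 7, center_effects = c(0, 0, 0))
  p_hat <- mean(co$dz_prev)
  expect_lt(abs(p_hat - 0.05), 3.5 * sqrt(0.05 * 0.95 / 5000))
  expect_identical(sum(co$dz_inc), 0L)   # zero baseline hazard, no events
  expect_true(all(co$dz_time <= co$dz_fu + 1e-12, na.rm = TRUE))
  expect_true(all(co$dz_prev[co$dz_inc == 1] == 0))
})

test_that("nonfinite disease coefficients are rejected", {
  pop <- sample_population(10, seed = 1)
  eff <- default_disease_effects()
  eff$t2d$or_bmi <- Inf
  expect_error(simulate_diseases(pop, eff), "nonfinite")
})

test_that("cohorts are reproducible and match configured structure", {
  g1 <- generate_cohort(10, seed = 3, silhouettes = FALSE)
  g2 <- generate_cohort(10, seed = 3, silhouettes = FALSE)
  expect_identical(serialize(g1$cohort, NULL, version = 2),
                   serialize(g2$cohort, NULL, version = 2))
  expect_error(generate_cohort(1), "n must be >= 2")
  co <- g1$cohort
  expect_equal(co$BMI, co$weight_kg / (co$height_cm / 100)^2,
               tolerance = 1e-6)
  expect_equal(co$ratio, co$VAT_L / co$ASAT_L)
  expect_true(all(co$VAT_L > 0 & co$ASAT_L > 0 & co$GFAT_L > 0))
})

test_that("population marginals track Table-style targets", {
  pop <- sample_population(4000, seed = 9)
  cfg <- population_config()
  for (s in c("male", "female")) {
    m <- pop[pop$sex == s, ]
    tg <- cfg$depot_targets[[s]]$mean
    expect_lt(abs(mean(m$VAT_L) - tg[["VAT"]]) / tg[["VAT"]], 0.15)
    expect_lt(abs(mean(m$ASAT_L) - tg[["ASAT"]]) / tg[["ASAT"]], 0.15)
    expect_lt(abs(mean(m$GFAT_L) - tg[["GFAT"]]) / tg[["GFAT"]], 0.15)
    expect_lt(abs(cor(m$BMI, m$ratio)), 0.3)
  }
})

test_that("NIfTI round trip preserves labels and spacing", {
  v <- generate_phantom(phantom_params("female"), spacing = c(6, 4.464, 4.464))
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_body_volume(v, tmp)
  v2 <- read_body_volume(tmp)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_identical(v2$labels, v$labels)
})
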
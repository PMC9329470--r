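# Shared fixtures, built in code.

# Binary ellipse slice (ny x nx), semi-axes in pixels.
ellipse_slice <- function(ny, nx, a, b, cy = ny / 2, cx = nx / 2) {
  yy <- outer((seq_len(ny) - cy)^2 / b^2, rep(1, nx))
  xx <- outer(rep(1, ny), (seq_len(nx) - cx)^2 / a^2)
  matrix(as.integer(yy + xx <= 1), ny, nx)
}

# Labelled cylinder body volume of given radius (mm) for anthropometrics.
cylinder_volume <- function(radius_mm = 150, nz = 30, spacing = c(10, 2.232, 2.232)) {
  half <- radius_mm + 5 * spacing[2]
  ny <- ceiling(2 * half / spacing[2])
  nx <- ceiling(2 * half / spacing[3])
  yy <- (seq_len(ny) - 0.5) * spacing[2] - ny * spacing[2] / 2
  xx <- (seq_len(nx) - 0.5) * spacing[3] - nx * spacing[3] / 2
  disc <- outer(yy^2, rep(1, nx)) + outer(rep(1, ny), xx^2) <= radius_mm^2
  lab <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) lab[z, , ] <- as.integer(disc)
  body_volume(spacing = spacing, labels = lab,
              landmarks = list(abdomen = c(5, 25), gluteal = c(5, 25)))
}

# Random silhouettes (ellipse blobs) with targets linear in foreground count.
linear_signal_silhouettes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    sils <- lapply(seq_len(n), function(i) {
      a <- runif(1, 40, 110)
      b <- runif(1, 30, 115)
      ellipse_slice(237, 256, a, b)
    })
    cnt <- vapply(sils, sum, numeric(1))
    Y <- cbind(2 + 0.001 * cnt, 1 + 0.0005 * cnt,
               3 - 0.0002 * cnt, 0.5 + 0.0001 * cnt)
    list(silhouettes = sils, Y = Y, count = cnt)
  })
}

# Tabular cohort with disease labels for epidemiology tests (no voxels).
epi_cohort <- function(n, seed = 1, effects = default_disease_effects(),
                       config = population_config()) {
  pop <- sample_population(n, config, seed = seed)
  simulate_diseases(pop, effects, config$follow_up_median_years,
                    seed = seed + 1L)
}

# One shared shape-driven cohort + nested-CV run, built once per session.
.silfat_cache <- new.env(parent = emptyenv())

shape_driven_run <- function() {
  if (!is.null(.silfat_cache$run)) return(.silfat_cache$run)
  cfg <- population_config(sigma_resid = 0)
  gen <- generate_cohort(2000, cfg, seed = 11)
  co <- gen$cohort
  X <- silhouette_matrix(gen$silhouettes)
  Y <- as.matrix(co[, c("VAT_L", "ASAT_L", "GFAT_L", "ratio")])
  folds <- assign_folds(co$id, seed = 12)
  pred <- run_nested_cv(X, Y, co$id, folds = folds, seed = 13)
  .silfat_cache$run <- list(cohort = co, X = X, Y = Y, folds = folds,
                            pred = pred)
  .silfat_cache$run
}
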
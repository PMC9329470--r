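test_that("R2 and MAE follow their defining formulas", {
  y <- c(1, 2, 3, 4)
  yhat <- c(1.1, 1.9, 3.2, 3.8)
  m <- r2_mae(y, yhat)
  expect_equal(m[["R2"]], 1 - 0.10 / 5)   # SSE = 0.10, SST = 5
  expect_equal(m[["MAE"]], 0.15)
  expect_equal(r2_mae(y, y), c(R2 = 1, MAE = 0))
  expect_equal(r2_mae(y, rep(mean(y), 4))[["R2"]], 0)
  expect_error(r2_mae(rep(2, 5), 1:5), "zero variance")
})

test_that("comparator OLS matches the normal-equation oracle", {
  set.seed(21)
  n <- 40
  cohort <- data.frame(
    id = sprintf("c%02d", 1:n), sex = "male",
    age_years = runif(n, 45, 80), BMI = runif(n, 20, 35))
  cohort$VAT_L <- 1 + 0.05 * cohort$age_years + 0.3 * cohort$BMI + rnorm(n, 0, 0.5)
  folds <- assign_folds(cohort$id, seed = 22)
  fit <- fit_comparator(cohort, comparator_spec("BMI"), "VAT", folds)
  # oracle: closed-form (X'X)^{-1} X'y per outer model, same fold logic
  for (m in 0:4) {
    roles <- fold_roles(folds, m)
    tr <- folds$partition %in% roles$train
    va <- folds$partition == roles$val
    Xtr <- cbind(1, cohort$age_years[tr], cohort$BMI[tr])
    beta <- solve(t(Xtr) %*% Xtr, t(Xtr) %*% cohort$VAT_L[tr])
    Xva <- cbind(1, cohort$age_years[va], cohort$BMI[va])
    expect_equal(fit$pred[va], drop(Xva %*% beta), tolerance = 1e-10)
  }
})

test_that("comparator edge cases: perfect, null, and collinear designs", {
  set.seed(23)
  n <- 5000
  cohort <- data.frame(
    id = sprintf("c%04d", 1:n),
    sex = rep(c("male", "female"), length.out = n),
    age_years = runif(n, 45, 80), BMI = runif(n, 20, 35),
    VAT_L = rnorm(n))
  folds <- assign_folds(cohort$id, seed = 24)
  # target equal to a covariate: out-of-fold R2 = 1
  cohort2 <- cohort
  cohort2$VAT_L <- cohort2$BMI
  fit1 <- fit_comparator(cohort2, comparator_spec("BMI"), "VAT", folds)
  expect_equal(r2_mae(fit1$truth, fit1$pred)[["R2"]], 1, tolerance = 1e-9)
  # target independent of covariates: R2 near zero
  fit0 <- fit_comparator(cohort, comparator_spec("BMI"), "VAT", folds)
  expect_lt(abs(r2_mae(fit0$truth, fit0$pred)[["R2"]]), 0.02)
  # collinear design errors and names the offending column
  cohort3 <- cohort
  cohort3$BMI2 <- 2 * cohort3$BMI
  expect_error(
    fit_comparator(cohort3, comparator_spec("custom",
                                            c("age_years", "BMI", "BMI2")),
                   "VAT", folds),
    "collinear.*BMI2")
})

test_that("bootstrap interval defaults and degenerate behaviour", {
  expect_equal(eval(formals(bootstrap_ci)$B), 1000L)
  y <- rnorm(50)
  ci <- bootstrap_ci(y, y, B = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))
  expect_warning(bootstrap_ci(y, y + rnorm(50), B = 50, seed = 1),
                 "B < 100")
  ci2 <- bootstrap_ci(y, y + rnorm(50, 0, 0.5), B = 500, seed = 2)
  expect_lte(ci2[["lower"]], ci2[["upper"]])
})

test_that("paired model comparison is null for identical models", {
  set.seed(25)
  y <- rnorm(300)
  yhat <- y + rnorm(300, 0, 0.4)
  cmp <- compare_models(y, yhat, yhat, B = 300, seed = 3)
  expect_equal(cmp$delta_r2, 0)
  expect_lte(cmp$ci[["lower"]], 0)
  expect_gte(cmp$ci[["upper"]], 0)
  expect_error(compare_models(y, yhat[-1], yhat), "mismatched ids")
})

test_that("comparator covariate sets expand per their definitions", {
  expect_equal(comparator_spec("BMI")$covariates, c("age_years", "BMI"))
  expect_equal(comparator_spec("Waist")$covariates,
               c("age_years", "waist_cm"))
  expect_equal(comparator_spec("Anthro")$covariates,
               c("age_years", "weight_kg", "height_cm", "BMI", "waist_cm",
                 "hip_cm", "WHR", paste0("imp", 1:5)))
  expect_equal(comparator_spec("Silhouette")$covariates,
               c("age_years", ".sil_pred"))
  expect_error(comparator_spec("custom"), "covariates")
})
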
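#' Comparator model specification
#'
#' Named covariate sets for the sex-stratified linear benchmark models:
#' `BMI` (age + BMI), `Waist` (age + waist circumference), `WHR`
#' (age + waist-to-hip ratio), `Anthro` (age + weight + height + BMI +
#' waist + hip + WHR + five bioimpedance measures), `Silhouette` (age +
#' the silhouette-model prediction of the target), or `custom` with a
#' user-supplied covariate list.
#'
#' @param name One of `"BMI"`, `"Waist"`, `"WHR"`, `"Anthro"`,
#'   `"Silhouette"`, `"custom"`.
#' @param covariates Covariate column names when `name = "custom"`.
#' @return A `comparator_spec` object.
#' @export
comparator_spec <- function(name = c("BMI", "Waist", "WHR", "Anthro",
                                     "Silhouette", "custom"),
                            covariates = NULL) {
  name <- match.arg(name)
  cov <- switch(name,
    BMI = c("age_years", "BMI"),
    Waist = c("age_years", "waist_cm"),
    WHR = c("age_years", "WHR"),
    Anthro = c("age_years", "weight_kg", "height_cm", "BMI", "waist_cm",
               "hip_cm", "WHR", paste0("imp", 1:5)),
    Silhouette = c("age_years", ".sil_pred"),
    custom = covariates)
  if (is.null(cov)) stop("custom spec needs covariates")
  structure(list(name = name, covariates = cov), class = "comparator_spec")
}

# Map a target name to cohort truth column and silhouette prediction column.
.target_columns <- function(target) {
  target <- match.arg(target, c("VAT", "ASAT", "GFAT", "ratio"))
  list(truth = switch(target, VAT = "VAT_L", ASAT = "ASAT_L",
                      GFAT = "GFAT_L", ratio = "ratio"),
       pred = switch(target, VAT = "VAT_pred", ASAT = "ASAT_pred",
                     GFAT = "GFAT_pred", ratio = "ratio_pred"))
}

#' Fit a comparator model under the shared nested cross-validation folds
#'
#' Ordinary least squares, fitted sex-stratified on each outer model's
#' training partitions and evaluated on its validation partition only, so
#' comparator and silhouette predictions obey the same out-of-fold
#' discipline.
#'
#' @param cohort Cohort data.frame (must contain the spec covariates, `sex`
#'   and the target column; the `Silhouette` spec additionally requires
#'   `predictions`).
#' @param spec A [comparator_spec()].
#' @param target `"VAT"`, `"ASAT"`, `"GFAT"` or `"ratio"`.
#' @param folds A [assign_folds()] result aligned with `cohort$id`.
#' @param predictions Optional `prediction_table` supplying the silhouette
#'   predictions for the `Silhouette` spec.
#' @return data.frame `id`, `truth`, `pred`, `model`, `sex`.
#' @export
fit_comparator <- function(cohort, spec, target, folds, predictions = NULL) {
  stopifnot(inherits(spec, "comparator_spec"),
            identical(folds$id, cohort$id))
  tc <- .target_columns(target)
  dat <- cohort
  covs <- spec$covariates
  if (".sil_pred" %in% covs) {
    if (is.null(predictions)) stop("Silhouette spec needs predictions")
    dat$.sil_pred <- predictions[[tc$pred]][match(dat$id, predictions$id)]
  }
  miss <- setdiff(c(covs, tc$truth, "sex"), names(dat))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!complete.cases(dat[c(covs, tc$truth)])))
    stop("incomplete covariates")
  k <- attr(folds, "k")
  out <- vector("list", k)
  for (m in seq_len(k) - 1L) {
    roles <- fold_roles(folds, m)
    tr <- folds$partition %in% roles$train
    va <- folds$partition == roles$val
    pred <- rep(NA_real_, sum(va))
    for (s in unique(dat$sex)) {
      tr_s <- tr & dat$sex == s
      va_s <- dat$sex[va] == s
      Xtr <- as.matrix(cbind(1, dat[tr_s, covs, drop = FALSE]))
      qx <- qr(Xtr)
      if (qx$rank < ncol(Xtr)) {
        bad <- colnames(Xtr)[qx$pivot[(qx$rank + 1):ncol(Xtr)]]
        stop("rank-deficient design; collinear columns: ",
             paste(bad, collapse = ", "))
      }
      beta <- qr.coef(qx, dat[[tc$truth]][tr_s])
      Xva <- as.matrix(cbind(1, dat[va, covs, drop = FALSE][va_s, , drop = FALSE]))
      pred[va_s] <- drop(Xva %*% beta)
    }
    out[[m + 1L]] <- data.frame(id = dat$id[va], truth = dat[[tc$truth]][va],
                                pred = pred, model = m, sex = dat$sex[va],
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[match(cohort$id, res$id), ]
  rownames(res) <- NULL
  res
}

#' Coefficient of determination and mean absolute error
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `MAE = mean(abs(y - yhat))`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Named vector `R2`, `MAE`.
#' @export
r2_mae <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2,
            all(is.finite(y)), all(is.finite(yhat)))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero variance in y")
  c(R2 = 1 - sum((y - yhat)^2) / sst, MAE = mean(abs(y - yhat)))
}

# Vectorised R2 over a matrix of resample indices (columns = resamples).
.boot_r2 <- function(y, yhat, idx) {
  ym <- matrix(y[idx], nrow(idx), ncol(idx))
  pm <- matrix(yhat[idx], nrow(idx), ncol(idx))
  mu <- colMeans(ym)
  sst <- colSums(ym^2) - nrow(idx) * mu^2
  sse <- colSums((ym - pm)^2)
  ifelse(sst > 0, 1 - sse / sst, NA_real_)
}

#' Percentile bootstrap confidence interval for R-squared
#'
#' Paired resampling of (y, yhat) with `B` resamples (default 1000).
#'
#' @param y,yhat Observed and predicted values.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Named vector `lower`, `upper`.
#' @export
bootstrap_ci <- function(y, yhat, B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(length(y) == length(yhat), length(y) >= 10)
  if (B < 100) warning("B < 100 resamples; interval will be unstable")
  n <- length(y)
  r2s <- with_seed(seed, {
    out <- numeric(B)
    done <- 0L
    while (done < B) {
      b <- min(200L, B - done)
      idx <- matrix(sample.int(n, n * b, replace = TRUE), n, b)
      out[done + seq_len(b)] <- .boot_r2(y, yhat, idx)
      done <- done + b
    }
    out
  })
  a <- (1 - level) / 2
  stats::setNames(quantile(r2s, c(a, 1 - a), na.rm = TRUE, names = FALSE),
                  c("lower", "upper"))
}

#' Point metrics with bootstrap confidence interval
#'
#' @inheritParams bootstrap_ci
#' @return List with `R2`, `MAE`, `ci` (95% bootstrap CI for R2), `n`, `B`.
#' @export
model_metrics <- function(y, yhat, B = 1000L, seed = 1L) {
  pm <- r2_mae(y, yhat)
  list(R2 = unname(pm["R2"]), MAE = unname(pm["MAE"]),
       ci = bootstrap_ci(y, yhat, B = B, seed = seed),
       n = length(y), B = B)
}

#' Paired bootstrap comparison of two models
#'
#' Computes the difference in R-squared between two prediction sets on the
#' same participants, with a percentile interval over paired resamples
#' (identical bootstrap indices for both models).
#'
#' @param y Observed values.
#' @param yhat_a,yhat_b Predictions of models A and B for the same `y`.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List with `delta_r2` (point estimate A - B), `ci`, `B`.
#' @export
compare_models <- function(y, yhat_a, yhat_b, B = 1000L, seed = 1L,
                           level = 0.95) {
  if (length(yhat_a) != length(y) || length(yhat_b) != length(y))
    stop("mismatched ids: predictions must cover the same participants")
  d0 <- unname(r2_mae(y, yhat_a)["R2"] - r2_mae(y, yhat_b)["R2"])
  n <- length(y)
  deltas <- with_seed(seed, {
    out <- numeric(B)
    done <- 0L
    while (done < B) {
      b <- min(200L, B - done)
      idx <- matrix(sample.int(n, n * b, replace = TRUE), n, b)
      out[done + seq_len(b)] <- .boot_r2(y, yhat_a, idx) -
        .boot_r2(y, yhat_b, idx)
      done <- done + b
    }
    out
  })
  a <- (1 - level) / 2
  list(delta_r2 = d0,
       ci = stats::setNames(quantile(deltas, c(a, 1 - a), na.rm = TRUE,
                                     names = FALSE), c("lower", "upper")),
       B = B)
}

#' Benchmark a set of comparator models against silhouette predictions
#'
#' Fits each named comparator under the shared folds and reports R2, MAE
#' and bootstrap CIs per target, pooled and sex-stratified.
#'
#' @param cohort Cohort data.frame.
#' @param predictions A `prediction_table` from [run_nested_cv()].
#' @param folds Shared [assign_folds()] result.
#' @param specs Character vector of comparator names.
#' @param targets Targets to evaluate.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return data.frame of metrics, one row per model x target x stratum.
#' @export
benchmark_models <- function(cohort, predictions, folds,
                             specs = c("BMI", "Waist", "Anthro", "Silhouette"),
                             targets = c("VAT", "ASAT", "GFAT", "ratio"),
                             B = 1000L, seed = 1L) {
  rows <- list()
  for (tg in targets) {
    tc <- .target_columns(tg)
    for (spn in specs) {
      fit <- fit_comparator(cohort, comparator_spec(spn), tg, folds,
                            predictions = predictions)
      strata <- list(pooled = rep(TRUE, nrow(fit)),
                     male = fit$sex == "male", female = fit$sex == "female")
      for (st in names(strata)) {
        sel <- strata[[st]]
        if (sum(sel) < 10) next
        mm <- model_metrics(fit$truth[sel], fit$pred[sel], B = B, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          model = spn, target = tg, stratum = st, R2 = mm$R2, MAE = mm$MAE,
          ci_lower = mm$ci[["lower"]], ci_upper = mm$ci[["upper"]],
          n = mm$n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
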
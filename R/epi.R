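#' Sex-stratified standardization of an exposure
#'
#' Centers and scales the exposure within each stratum, so effect sizes are
#' reported per stratum-specific standard deviation.
#'
#' @param values Numeric exposure values.
#' @param stratum Stratum labels (typically sex), same length.
#' @return Numeric z-scores.
#' @export
standardize_exposure <- function(values, stratum) {
  stopifnot(length(values) == length(stratum))
  out <- numeric(length(values))
  for (s in unique(stratum)) {
    sel <- stratum == s
    sdev <- sd(values[sel])
    if (!is.finite(sdev) || sdev == 0) stop("zero SD within stratum ", s)
    out[sel] <- (values[sel] - mean(values[sel])) / sdev
  }
  out
}

# Covariate sets for the adjusted models.
.adjustment_covs <- function(adjustment = c("base", "bmi", "bmi_waist",
                                            "none")) {
  adjustment <- match.arg(adjustment)
  switch(adjustment,
         none = character(0),
         base = c("age_years", "center"),
         bmi = c("age_years", "center", "BMI"),
         bmi_waist = c("age_years", "center", "BMI", "waist_cm"))
}

.assoc_formula <- function(disease_col, covs, has_center) {
  if (!has_center) covs <- setdiff(covs, "center")
  covs <- sub("^center$", "factor(center)", covs)
  rhs <- if (length(covs)) paste(c(".z_exposure", covs), collapse = " + ")
         else ".z_exposure"
  as.formula(paste(disease_col, "~", rhs))
}

#' Association of an exposure with prevalent disease
#'
#' Sex-stratified logistic regression of the prevalent-disease flag on the
#' sex-standardized exposure, adjusted for age and imaging center
#' (`"base"`), additionally BMI (`"bmi"`), or BMI and waist circumference
#' (`"bmi_waist"`). Effects are odds ratios per stratum SD with Wald 95%
#' confidence intervals.
#'
#' @param cohort Cohort data.frame with `sex`, the exposure and covariates,
#'   and a `<disease>_prev` column.
#' @param disease Disease name (e.g. `"t2d"`).
#' @param exposure Exposure column name (e.g. `"ratio_pred"`).
#' @param adjustment `"base"`, `"bmi"`, `"bmi_waist"`, or `"none"` (crude
#'   model without covariates).
#' @param standardize Standardize the exposure within stratum (the `OR/SD`
#'   reporting unit); set `FALSE` to report per unit of the raw exposure.
#' @return data.frame of class `association_result`, one row per sex.
#' @export
fit_prevalent <- function(cohort, disease, exposure,
                          adjustment = c("base", "bmi", "bmi_waist", "none"),
                          standardize = TRUE) {
  adjustment <- match.arg(adjustment)
  dcol <- paste0(disease, "_prev")
  stopifnot(dcol %in% names(cohort), exposure %in% names(cohort))
  covs <- .adjustment_covs(adjustment)
  fml <- .assoc_formula(dcol, covs, "center" %in% names(cohort))
  rows <- lapply(unique(cohort$sex), function(s) {
    d <- cohort[cohort$sex == s, ]
    d$.z_exposure <- if (standardize) as.numeric(scale(d[[exposure]]))
                     else d[[exposure]]
    cases <- sum(d[[dcol]])
    fit <- glm(fml, family = binomial(), data = d)
    if (!fit$converged || any(abs(coef(fit)) > 15))
      stop("separation or non-convergence in logistic fit (", disease,
           ", ", s, ")")
    b <- coef(fit)[".z_exposure"]
    se <- sqrt(vcov(fit)[".z_exposure", ".z_exposure"])
    data.frame(disease = disease, exposure = exposure, stratum = s,
               adjustment = adjustment, type = "prevalent",
               effect = exp(b), ci_lower = exp(b - qnorm(0.975) * se),
               ci_upper = exp(b + qnorm(0.975) * se),
               n = nrow(d), events = cases,
               low_power = cases < 20, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("association_result", "data.frame"))
}

#' Association of an exposure with incident disease
#'
#' Sex-stratified Cox proportional-hazards model (Efron ties) for incident
#' events, excluding prevalent cases from the risk set. Effects are hazard
#' ratios per stratum SD with Wald 95% confidence intervals.
#'
#' @inheritParams fit_prevalent
#' @return data.frame of class `association_result`, one row per sex.
#' @export
fit_incident <- function(cohort, disease, exposure,
                         adjustment = c("base", "bmi", "bmi_waist")) {
  adjustment <- match.arg(adjustment)
  pcol <- paste0(disease, "_prev")
  icol <- paste0(disease, "_inc")
  tcol <- paste0(disease, "_time")
  stopifnot(all(c(pcol, icol, tcol) %in% names(cohort)))
  covs <- setdiff(.adjustment_covs(adjustment), "center")
  if ("center" %in% names(cohort)) covs <- c(covs, "strata(center)")
  rows <- lapply(unique(cohort$sex), function(s) {
    d_all <- cohort[cohort$sex == s, ]
    # standardize on the full sex stratum: excluding prevalent cases first
    # would shrink the exposure SD (prevalence selects the upper tail) and
    # systematically attenuate the per-SD hazard ratio
    d_all$.z_exposure <- as.numeric(scale(d_all[[exposure]]))
    d <- d_all[d_all[[pcol]] == 0, ]
    events <- sum(d[[icol]])
    if (events == 0) stop("zero events for ", disease, " in ", s)
    fml <- as.formula(paste0("survival::Surv(", tcol, ", ", icol,
                             ") ~ .z_exposure + ",
                             paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = d, ties = "efron")
    b <- coef(fit)[".z_exposure"]
    se <- sqrt(vcov(fit)[".z_exposure", ".z_exposure"])
    data.frame(disease = disease, exposure = exposure, stratum = s,
               adjustment = adjustment, type = "incident",
               effect = exp(b), ci_lower = exp(b - qnorm(0.975) * se),
               ci_upper = exp(b + qnorm(0.975) * se),
               n = nrow(d), events = events,
               low_power = events < 10, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("association_result", "data.frame"))
}

#' Quintile exposure groups within strata
#'
#' Sex-stratified empirical quintiles with ties broken by stable rank,
#' collapsed to the bottom quintile, quintiles 2-4, and the top quintile.
#'
#' @param exposure Numeric exposure values.
#' @param stratum Stratum labels (typically sex).
#' @return Factor with levels `Q1`, `Q2-4`, `Q5`.
#' @export
quintile_groups <- function(exposure, stratum) {
  stopifnot(length(exposure) == length(stratum))
  out <- character(length(exposure))
  for (s in unique(stratum)) {
    sel <- which(stratum == s)
    if (length(sel) < 5) stop("need at least 5 observations per stratum")
    q <- ceiling(5 * rank(exposure[sel], ties.method = "first") /
                   length(sel))
    out[sel] <- ifelse(q == 1, "Q1", ifelse(q == 5, "Q5", "Q2-4"))
  }
  factor(out, levels = c("Q1", "Q2-4", "Q5"))
}

#' BMI and waist-circumference categories
#'
#' @param bmi Numeric BMI values.
#' @param breaks Category bounds (normal/overweight/obese/severely obese).
#' @return Factor of BMI categories; values below the first break are `NA`.
#' @export
bmi_categories <- function(bmi, breaks = c(18.5, 25, 30, 40)) {
  cut(bmi, c(breaks, Inf),
      labels = c("normal", "overweight", "obese", "severe"),
      right = FALSE)
}

#' Standardized disease prevalence within BMI x waist x quintile cells
#'
#' Marginal standardization (g-computation): a sex-stratified logistic
#' model of prevalent disease on the exposure quintile group, BMI category,
#' waist category and age is fitted; each participant's probability is then
#' predicted under counterfactual membership of every cell and averaged,
#' yielding the standardized prevalence per cell. Confidence intervals are
#' obtained by bootstrap over participants. With `adjust = "none"` the raw
#' within-cell prevalence is returned instead.
#'
#' @param cohort Cohort data.frame with `sex`, `BMI`, `waist_cm`,
#'   `age_years` and a `<disease>_prev` column.
#' @param disease Disease name.
#' @param exposure Exposure column used for quintile grouping.
#' @param bmi_breaks BMI category bounds.
#' @param waist_cutoffs Elevated-waist cutoffs (cm), named per sex;
#'   optionally a per-sex list of per-BMI-category cutoffs.
#' @param adjust `"model"` for g-computation or `"none"` for raw cell
#'   prevalence.
#' @param B Bootstrap resamples for the CI (only with `adjust = "model"`).
#' @param seed Integer seed.
#' @return data.frame: sex, BMI category, waist category, quintile group,
#'   standardized prevalence, CI bounds and cell size. Empty cells are
#'   reported with `NA` prevalence.
#' @export
standardized_prevalence <- function(cohort, disease, exposure,
                                    bmi_breaks = c(18.5, 25, 30, 40),
                                    waist_cutoffs = c(male = 102, female = 88),
                                    adjust = c("model", "none"),
                                    B = 200L, seed = 1L) {
  adjust <- match.arg(adjust)
  dcol <- paste0(disease, "_prev")
  stopifnot(dcol %in% names(cohort))
  d <- cohort
  d$.bmi_cat <- bmi_categories(d$BMI, bmi_breaks)
  cutoff <- function(sex, bmi_cat) {
    wc <- waist_cutoffs[[sex]]
    if (is.list(wc) || length(wc) > 1) wc[[as.character(bmi_cat)]] else wc
  }
  d$.waist_cat <- factor(ifelse(
    d$waist_cm > mapply(cutoff, d$sex, as.character(d$.bmi_cat)),
    "elevated", "normal"), levels = c("normal", "elevated"))
  d$.q <- quintile_groups(d[[exposure]], d$sex)
  d <- d[!is.na(d$.bmi_cat), ]

  cells <- expand.grid(sex = unique(d$sex),
                       bmi_cat = levels(d$.bmi_cat),
                       waist_cat = levels(d$.waist_cat),
                       quintile_group = levels(d$.q),
                       stringsAsFactors = FALSE)
  est_one <- function(ds) {
    # returns a function cell -> standardized prevalence for one sex subset
    if (adjust == "none") {
      function(b, w, q) {
        sel <- ds$.bmi_cat == b & ds$.waist_cat == w & ds$.q == q
        if (!any(sel)) return(NA_real_)
        mean(ds[[dcol]][sel])
      }
    } else {
      fml <- as.formula(paste(dcol, "~ .q + .bmi_cat + .waist_cat +",
                              "age_years"))
      fit <- glm(fml, family = binomial(), data = ds)
      function(b, w, q) {
        nd <- ds
        nd$.bmi_cat <- factor(b, levels = levels(ds$.bmi_cat))
        nd$.waist_cat <- factor(w, levels = levels(ds$.waist_cat))
        nd$.q <- factor(q, levels = levels(ds$.q))
        mean(predict(fit, newdata = nd, type = "response"))
      }
    }
  }
  out <- cells
  out$prevalence <- NA_real_
  out$ci_lower <- NA_real_
  out$ci_upper <- NA_real_
  out$n_cell <- 0L
  for (s in unique(d$sex)) {
    ds <- d[d$sex == s, ]
    f <- est_one(ds)
    boots <- NULL
    if (adjust == "model") {
      boots <- with_seed(seed, lapply(seq_len(B), function(b) {
        dsb <- ds[sample.int(nrow(ds), replace = TRUE), ]
        est_one(dsb)
      }))
    }
    for (i in which(out$sex == s)) {
      b <- out$bmi_cat[i]; w <- out$waist_cat[i]; q <- out$quintile_group[i]
      sel <- ds$.bmi_cat == b & ds$.waist_cat == w & ds$.q == q
      out$n_cell[i] <- sum(sel)
      if (out$n_cell[i] == 0) next  # empty cell: reported as missing
      out$prevalence[i] <- f(b, w, q)
      if (!is.null(boots)) {
        bv <- vapply(boots, function(fb) fb(b, w, q), numeric(1))
        out$ci_lower[i] <- quantile(bv, 0.025, na.rm = TRUE)
        out$ci_upper[i] <- quantile(bv, 0.975, na.rm = TRUE)
      }
    }
  }
  out
}
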
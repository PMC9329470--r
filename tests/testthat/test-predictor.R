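test_that("fold assignment partitions the cohort per the rotation scheme", {
  f <- assign_folds(paste0("p", 1:10), seed = 1)
  expect_equal(unname(table(f$partition)), rep(2L, 5), ignore_attr = TRUE)
  expect_error(assign_folds(letters[1:6], k_outer = 1), "k_outer")
  expect_error(assign_folds(c("a", "a", "b", "c", "d")), "duplicate")
  # partition sizes differ by at most one at the study cohort size
  f2 <- assign_folds(seq_len(40032), seed = 2)
  expect_setequal(unique(unname(table(f2$partition))), c(8006L, 8007L))
  # validation partitions across the five models tile the cohort exactly
  vals <- vapply(0:4, function(m) fold_roles(f2, m)$val, numeric(1))
  expect_setequal(vals, 0:4)
  roles <- fold_roles(f2, 1)
  expect_equal(length(roles$train), 3)
  expect_false(roles$test %in% roles$train)
  expect_false(roles$val %in% c(roles$train, roles$test))
})

test_that("the network can overfit a tiny sample (capacity smoke test)", {
  d <- linear_signal_silhouettes(32, seed = 3)
  X <- silhouette_matrix(d$silhouettes)
  Y <- d$Y + withr::with_seed(4, matrix(rnorm(32 * 4, 0, 0.01), 32, 4))
  net <- silnet_config(max_epochs = 250L, patience = 0L)
  m <- train_silnet(X, Y, net = net, seed = 5)
  expect_gte(m$train_loss[1] / tail(m$train_loss, 1), 100)
})

test_that("training is deterministic given the seed", {
  d <- linear_signal_silhouettes(40, seed = 6)
  X <- silhouette_matrix(d$silhouettes)
  net <- silnet_config(max_epochs = 5L, patience = 0L)
  m1 <- train_silnet(X, d$Y, net = net, seed = 9)
  m2 <- train_silnet(X, d$Y, net = net, seed = 9)
  expect_identical(serialize(m1$weights, NULL, version = 2),
                   serialize(m2$weights, NULL, version = 2))
})

test_that("a signal fully determined by the silhouette is recovered", {
  d <- linear_signal_silhouettes(500, seed = 10)
  X <- silhouette_matrix(d$silhouettes)
  tr <- 1:400
  va <- 401:500
  Xtr <- X[, tr]; attr(Xtr, "input_dim") <- attr(X, "input_dim")
  Xva <- X[, va]; attr(Xva, "input_dim") <- attr(X, "input_dim")
  m <- train_silnet(Xtr, d$Y[tr, ], Xva, d$Y[va, ], seed = 11)
  p <- predict(m, Xva)
  for (j in 1:4)
    expect_gte(r2_mae(d$Y[va, j], p[, j])[["R2"]], 0.95)
})

test_that("mean-ensembling averages model outputs and never hurts MSE", {
  d <- linear_signal_silhouettes(120, seed = 12)
  X <- silhouette_matrix(d$silhouettes)
  ens <- train_fold(X, d$Y, net = silnet_config(max_epochs = 15L),
                    inner_k = 2L, seed = 13)
  expect_error(ensemble_predict(list(), X), "empty model list")
  p1 <- predict(ens[[1]], X)
  expect_equal(ensemble_predict(ens[1], X), p1)
  # two constant pseudo-models average to the midpoint
  const_model <- function(val) structure(list(val = val), class = "const_mod")
  assign("predict.const_mod",
         function(object, X, ...) matrix(object$val, ncol(X), 4),
         envir = globalenv())
  withr::defer(rm("predict.const_mod", envir = globalenv()))
  out <- ensemble_predict(list(const_model(1), const_model(3)), X)
  expect_true(all(out == 2))
  # convexity: ensemble MSE no worse than the worst member, per task
  dval <- linear_signal_silhouettes(80, seed = 14)
  Xv <- silhouette_matrix(dval$silhouettes)
  pe <- ensemble_predict(ens, Xv)
  per_model <- lapply(ens, function(m) predict(m, Xv))
  for (j in 1:4) {
    mse_e <- mean((dval$Y[, j] - pe[, j])^2)
    mse_max <- max(vapply(per_model, function(p)
      mean((dval$Y[, j] - p[, j])^2), numeric(1)))
    expect_lte(mse_e, mse_max + 1e-9)
  }
})

test_that("nested CV yields one leakage-free prediction per participant", {
  d <- linear_signal_silhouettes(80, seed = 15)
  X <- silhouette_matrix(d$silhouettes)
  ids <- sprintf("s%03d", 1:80)
  pred <- run_nested_cv(X, d$Y, ids, net = silnet_config(max_epochs = 6L),
                        inner_k = 2L, seed = 16)
  expect_s3_class(pred, "prediction_table")
  expect_equal(nrow(pred), 80)
  expect_identical(pred$id, ids)
  expect_true(all(is.finite(as.matrix(
    pred[, c("VAT_pred", "ASAT_pred", "GFAT_pred", "ratio_pred")]))))
  expect_true(audit_folds(pred))
  folds <- attr(pred, "folds")
  for (i in seq_len(nrow(pred))) {
    roles <- attr(pred, "provenance")[[pred$model[i] + 1L]]
    expect_false(folds$partition[match(pred$id[i], folds$id)] %in%
                   roles$train)
  }
})
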
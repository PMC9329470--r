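#' Assign participants to nested cross-validation partitions
#'
#' The cohort is split into `k_outer` non-overlapping partitions of sizes
#' differing by at most one. Outer model `m` (0-based) trains on partitions
#' `m, m+1, ..., m+k-3` (mod k), uses partition `m+k-2` for testing/model
#' selection and collects unbiased predictions on validation partition
#' `m+k-1`; across the `k` models the validation partitions tile the whole
#' cohort.
#'
#' @param ids Character or integer participant identifiers.
#' @param k_outer Number of outer partitions (default 5).
#' @param seed Integer seed.
#' @return A `fold_assignment` object: data.frame `id`, `partition`
#'   (0-based) with attributes `k` and `seed`.
#' @export
assign_folds <- function(ids, k_outer = 5L, seed = 1L) {
  if (k_outer < 2) stop("k_outer must be >= 2")
  n <- length(ids)
  if (n < k_outer) stop("need at least k_outer ids")
  if (anyDuplicated(ids)) stop("duplicate ids")
  part <- with_seed(seed, sample(rep(seq_len(k_outer) - 1L, length.out = n)))
  structure(data.frame(id = ids, partition = part, stringsAsFactors = FALSE),
            k = k_outer, seed = seed,
            class = c("fold_assignment", "data.frame"))
}

#' Partition roles for one outer model
#'
#' @param folds A `fold_assignment`.
#' @param m Outer model index, 0-based.
#' @return List with `train`, `test`, `val` partition indices (0-based).
#' @export
fold_roles <- function(folds, m) {
  k <- attr(folds, "k")
  stopifnot(m >= 0, m < k)
  list(train = (m + 0:(k - 3)) %% k,
       test = (m + k - 2) %% k,
       val = (m + k - 1) %% k)
}

#' Configuration of the multi-task silhouette regressor
#'
#' A compact convolutional trunk: the 237 x 256 silhouette is zero-padded
#' to 240 rows and block-averaged by `pool` to the network input, then
#' passed through `length(channels)` blocks of 3x3 convolution + ReLU +
#' 2x2 average pooling, a fully connected ReLU layer, and a linear head
#' with one output per task (VAT, ASAT, GFAT, VAT/ASAT ratio).
#'
#' @param pool Integer block-average factor applied to the silhouette.
#' @param channels Output channels per conv block.
#' @param dense Fully connected layer width.
#' @param lr Adam learning rate.
#' @param batch Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); 0 disables early stopping.
#' @param loss_weights Per-task loss weights (standardized targets).
#' @param derive_ratio If `TRUE`, the ratio output is derived as
#'   predicted VAT / predicted ASAT rather than taken from its own head.
#' @return List of class `silnet_config`.
#' @export
silnet_config <- function(pool = 4L, channels = c(4L, 8L, 16L), dense = 32L,
                          lr = 1e-3, batch = 64L, max_epochs = 30L,
                          patience = 5L, loss_weights = rep(1, 4),
                          derive_ratio = FALSE) {
  stopifnot(pool >= 1, length(channels) >= 1, dense >= 1, lr > 0,
            length(loss_weights) == 4)
  structure(list(pool = as.integer(pool), channels = as.integer(channels),
                 dense = as.integer(dense), lr = lr,
                 batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 loss_weights = as.numeric(loss_weights),
                 derive_ratio = isTRUE(derive_ratio)),
            class = "silnet_config")
}

# Input dimensions implied by the pooling factor for 237 x 256 silhouettes.
.silnet_input_dim <- function(pool, sil_dim = c(237L, 256L)) {
  c(ceiling(sil_dim[1] / pool), ceiling(sil_dim[2] / pool))
}

#' Convert silhouettes to the network input matrix
#'
#' Zero-pads each silhouette to a multiple of the pooling factor and
#' block-averages, producing one column per sample in `[0, 1]`.
#'
#' @param silhouettes List of `silhouette_image` (or binary matrices of a
#'   common shape).
#' @param pool Block-average factor.
#' @return Numeric matrix, `prod(input_dim)` rows x n columns, with
#'   attribute `input_dim`.
#' @export
silhouette_matrix <- function(silhouettes, pool = 4L) {
  stopifnot(length(silhouettes) >= 1)
  d <- dim(silhouettes[[1]])
  hw <- .silnet_input_dim(pool, d)
  pr <- hw[1] * pool; pc <- hw[2] * pool
  # block-average via sparse-free matrix products
  R <- matrix(0, hw[1], pr)
  for (i in seq_len(hw[1])) R[i, ((i - 1) * pool + 1):(i * pool)] <- 1 / pool
  C <- matrix(0, pc, hw[2])
  for (j in seq_len(hw[2])) C[((j - 1) * pool + 1):(j * pool), j] <- 1 / pool
  X <- matrix(0, prod(hw), length(silhouettes))
  padded <- matrix(0, pr, pc)
  for (i in seq_along(silhouettes)) {
    s <- silhouettes[[i]]
    if (!identical(dim(s), d)) stop("silhouettes differ in shape")
    padded[] <- 0
    padded[seq_len(d[1]), seq_len(d[2])] <- s
    X[, i] <- as.numeric(R %*% padded %*% C)
  }
  attr(X, "input_dim") <- hw
  X
}

# Internal architecture descriptor consumed by the C++ engine.
.silnet_arch <- function(net, input_dim) {
  list(H = as.integer(input_dim[1]), W = as.integer(input_dim[2]),
       C0 = 1L, channels = net$channels, dense = net$dense, tasks = 4L,
       loss_weights = net$loss_weights)
}

# He-initialised weights, drawn from R's RNG for seed discipline.
.silnet_init <- function(arch, seed) {
  with_seed(seed, {
    cin <- c(arch$C0, arch$channels[-length(arch$channels)])
    conv_W <- conv_b <- vector("list", length(arch$channels))
    for (i in seq_along(arch$channels)) {
      fan_in <- cin[i] * 9
      conv_W[[i]] <- matrix(rnorm(arch$channels[i] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                            arch$channels[i], fan_in)
      conv_b[[i]] <- rep(0, arch$channels[i])
    }
    h <- arch$H; w <- arch$W
    for (i in seq_along(arch$channels)) { h <- h %/% 2L; w <- w %/% 2L }
    flat <- h * w * arch$channels[length(arch$channels)]
    list(conv_W = conv_W, conv_b = conv_b,
         dense_W = matrix(rnorm(arch$dense * flat, sd = sqrt(2 / flat)),
                          arch$dense, flat),
         dense_b = rep(0, arch$dense),
         head_W = matrix(rnorm(4 * arch$dense, sd = sqrt(1 / arch$dense)),
                         4, arch$dense),
         head_b = rep(0, 4))
  })
}

#' Train a single silhouette regressor
#'
#' Low-level trainer: fits one multi-task network on standardized targets
#' with Adam, optionally early-stopping on a validation set. Deterministic
#' given the seed.
#'
#' @param X Input matrix from [silhouette_matrix()] (columns = samples).
#' @param Y Target matrix, n x 4 (VAT_L, ASAT_L, GFAT_L, ratio).
#' @param Xval,Yval Optional validation data for early stopping.
#' @param net A [silnet_config()].
#' @param seed Integer seed.
#' @param scaler Optional list `mean`, `sd` for target standardization;
#'   computed from `Y` when `NULL`.
#' @return A `silnet_model`: weights, architecture, scaler, training
#'   history.
#' @export
train_silnet <- function(X, Y, Xval = NULL, Yval = NULL,
                         net = silnet_config(), seed = 1L, scaler = NULL) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 4, nrow(Y) == ncol(X))
  input_dim <- attr(X, "input_dim") %||% .silnet_input_dim(net$pool)
  arch <- .silnet_arch(net, input_dim)
  if (is.null(scaler))
    scaler <- list(mean = colMeans(Y), sd = pmax(apply(Y, 2, sd), 1e-8))
  Ys <- t((t(Y) - scaler$mean) / scaler$sd)
  w0 <- .silnet_init(arch, seed)
  Yvs <- NULL
  if (!is.null(Xval)) {
    Yval <- as.matrix(Yval)
    Yvs <- t((t(Yval) - scaler$mean) / scaler$sd)
  }
  fit <- .sn_train(w0, X, t(Ys), Xval, if (is.null(Yvs)) NULL else t(Yvs),
                   arch, list(lr = net$lr, batch = net$batch,
                              max_epochs = net$max_epochs,
                              patience = net$patience,
                              seed = as.integer(seed)))
  if (any(!is.finite(fit$train_loss)))
    stop("non-finite training loss; lower the learning rate")
  structure(list(weights = fit$weights, arch = arch, scaler = scaler,
                 net = net, train_loss = fit$train_loss,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch),
            class = "silnet_model")
}

#' Predict with a single silhouette regressor
#'
#' @param object A `silnet_model`.
#' @param X Input matrix (columns = samples).
#' @param ... Unused.
#' @return n x 4 matrix in physical units.
#' @export
predict.silnet_model <- function(object, X, ...) {
  Yh <- t(.sn_forward(object$weights, X, object$arch))
  out <- t(t(Yh) * object$scaler$sd + object$scaler$mean)
  colnames(out) <- c("VAT_L", "ASAT_L", "GFAT_L", "ratio")
  if (isTRUE(object$net$derive_ratio))
    out[, "ratio"] <- out[, "VAT_L"] / pmax(out[, "ASAT_L"], 1e-6)
  out
}

#' Train the inner cross-validation models for one outer fold
#'
#' Splits the outer-fold training data into `inner_k` inner folds and
#' trains `inner_k` networks, each on `inner_k - 1` inner folds with early
#' stopping on the held-out inner fold. Targets are standardized with
#' training-split statistics only.
#'
#' @param X Input matrix (columns = samples) for the outer training split.
#' @param Y Target matrix, n x 4.
#' @param net A [silnet_config()].
#' @param inner_k Number of inner folds (>= 2).
#' @param seed Integer seed.
#' @return A `silnet_ensemble`: list of `silnet_model`s.
#' @export
train_fold <- function(X, Y, net = silnet_config(), inner_k = 3L, seed = 1L) {
  if (inner_k < 2) stop("inner_k must be >= 2")
  Y <- as.matrix(Y)
  n <- ncol(X)
  stopifnot(nrow(Y) == n, n >= 2 * inner_k)
  scaler <- list(mean = colMeans(Y), sd = pmax(apply(Y, 2, sd), 1e-8))
  inner <- with_seed(seed, sample(rep(seq_len(inner_k), length.out = n)))
  input_dim <- attr(X, "input_dim")
  models <- lapply(seq_len(inner_k), function(j) {
    tr <- inner != j
    Xtr <- X[, tr, drop = FALSE]
    Xva <- X[, !tr, drop = FALSE]
    attr(Xtr, "input_dim") <- input_dim
    attr(Xva, "input_dim") <- input_dim
    train_silnet(Xtr, Y[tr, , drop = FALSE], Xva, Y[!tr, , drop = FALSE],
                 net = net, seed = seed + j, scaler = scaler)
  })
  structure(models, class = "silnet_ensemble")
}

#' Mean-ensemble prediction
#'
#' The final prediction is the arithmetic mean of the inner
#' cross-validation models' outputs, de-standardized to physical units.
#'
#' @param models A `silnet_ensemble` or list of `silnet_model`s.
#' @param X Input matrix (columns = samples).
#' @return n x 4 prediction matrix.
#' @export
ensemble_predict <- function(models, X) {
  if (!length(models)) stop("empty model list")
  preds <- lapply(models, function(m) predict(m, X))
  Reduce(`+`, preds) / length(preds)
}

#' Run the full nested cross-validation
#'
#' Trains `k` outer models (each an inner-CV mean-ensemble), collects
#' out-of-fold predictions on each model's validation partition, and
#' returns one unbiased prediction per participant.
#'
#' @param X Input matrix from [silhouette_matrix()] for the whole cohort.
#' @param Y Target matrix, n x 4 (VAT_L, ASAT_L, GFAT_L, ratio).
#' @param ids Participant identifiers aligned with columns of `X`.
#' @param folds Optional [assign_folds()] result; created when `NULL`.
#' @param net A [silnet_config()].
#' @param inner_k Inner cross-validation folds.
#' @param seed Integer seed.
#' @param progress Print per-fold progress messages.
#' @return A `prediction_table` data.frame: `id`, predictions for the four
#'   targets, `model` and `val_partition`, with fold provenance and
#'   per-fold test metrics in attributes.
#' @export
run_nested_cv <- function(X, Y, ids, folds = NULL, net = silnet_config(),
                          inner_k = 3L, seed = 1L, progress = FALSE) {
  Y <- as.matrix(Y)
  n <- length(ids)
  stopifnot(ncol(X) == n, nrow(Y) == n)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("missing silhouette or target data")
  if (is.null(folds)) folds <- assign_folds(ids, seed = seed)
  stopifnot(identical(folds$id, ids))
  k <- attr(folds, "k")
  input_dim <- attr(X, "input_dim")
  rows <- vector("list", k)
  prov <- vector("list", k)
  metrics <- vector("list", k)
  for (m in seq_len(k) - 1L) {
    roles <- fold_roles(folds, m)
    tr <- folds$partition %in% roles$train
    te <- folds$partition == roles$test
    va <- folds$partition == roles$val
    Xtr <- X[, tr, drop = FALSE]
    attr(Xtr, "input_dim") <- input_dim
    ens <- train_fold(Xtr, Y[tr, , drop = FALSE], net = net,
                      inner_k = inner_k, seed = seed + 100L * (m + 1L))
    Xte <- X[, te, drop = FALSE]; attr(Xte, "input_dim") <- input_dim
    Xva <- X[, va, drop = FALSE]; attr(Xva, "input_dim") <- input_dim
    pte <- ensemble_predict(ens, Xte)
    pva <- ensemble_predict(ens, Xva)
    metrics[[m + 1L]] <- vapply(1:4, function(j)
      r2_mae(Y[te, j], pte[, j])[["R2"]], numeric(1))
    rows[[m + 1L]] <- data.frame(
      id = ids[va], VAT_pred = pva[, 1], ASAT_pred = pva[, 2],
      GFAT_pred = pva[, 3], ratio_pred = pva[, 4],
      model = m, val_partition = roles$val, stringsAsFactors = FALSE)
    prov[[m + 1L]] <- roles
    if (progress)
      message(sprintf("outer model %d/%d: test R2(VAT) = %.3f",
                      m + 1L, k, metrics[[m + 1L]][1]))
  }
  out <- do.call(rbind, rows)
  out <- out[match(ids, out$id), ]
  rownames(out) <- NULL
  stopifnot(!anyNA(out$id), identical(out$id, ids))
  mm <- do.call(rbind, metrics)
  colnames(mm) <- c("VAT_L", "ASAT_L", "GFAT_L", "ratio")
  structure(out, provenance = prov, folds = folds, test_r2 = mm,
            inner_k = inner_k,
            class = c("prediction_table", "data.frame"))
}

#' Audit a prediction table for training/validation leakage
#'
#' Verifies that no participant's out-of-fold prediction was produced by a
#' model whose training partitions contain that participant, and that the
#' validation partitions tile the cohort exactly once.
#'
#' @param pred A `prediction_table` from [run_nested_cv()].
#' @return `TRUE` (invisibly) when the audit passes; errors otherwise.
#' @export
audit_folds <- function(pred) {
  folds <- attr(pred, "folds")
  prov <- attr(pred, "provenance")
  stopifnot(!is.null(folds), !is.null(prov))
  part <- folds$partition[match(pred$id, folds$id)]
  for (i in seq_len(nrow(pred))) {
    roles <- prov[[pred$model[i] + 1L]]
    if (part[i] %in% roles$train)
      stop("leakage: participant ", pred$id[i],
           " predicted by a model trained on it")
    if (part[i] != roles$val)
      stop("participant ", pred$id[i], " not in its validation partition")
  }
  if (anyDuplicated(pred$id) || !setequal(pred$id, folds$id))
    stop("validation partitions do not tile the cohort")
  invisible(TRUE)
}
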
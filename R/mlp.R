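# A deliberately small multilayer perceptron (17-3-1 by default), trained
# from scratch with full-batch backpropagation: per-pattern gradient-descent
# deltas are accumulated over an epoch and the summed delta applied once per
# epoch. Sigmoid activations at hidden and output layers; targets live on
# [0, 1] (9-point ratings mapped via (rating - 1)/8).

#' MLP configuration
#'
#' @param n_inputs input-layer width (17 retained descriptors by default).
#' @param n_hidden hidden units (default 3).
#' @param learning_rate gradient-descent step on the summed batch delta.
#' @param epochs training epochs (700 by default; slower-converging targets
#'   may need 1000).
#' @param init_range weights and biases initialized uniformly in
#'   `[-init_range, init_range]`.
#' @param mse_target convergence reference (reported, not an early stop).
#' @param seed weight-initialization seed.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(n_inputs = 17L, n_hidden = 3L, learning_rate = 0.2,
                       epochs = 700L, init_range = 0.05,
                       mse_target = 0.008, seed = 1L) {
  stopifnot(n_hidden >= 1, learning_rate >= 0, epochs >= 0)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 init_range = init_range, mse_target = mse_target,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the network by full-batch backpropagation
#'
#' One epoch = one pass over all training patterns; the per-pattern deltas
#' (gradient of the half squared error) are summed and applied once at the
#' end of the epoch, so presentation order within an epoch is irrelevant.
#' The reported trace and final MSE are `mean((target - output)^2)`.
#'
#' @param X training inputs in \[0, 1\], rows = patterns, columns ordered as
#'   at prediction time.
#' @param y training targets in \[0, 1\].
#' @param config an [mlp_config()]; `config$n_inputs` must match `ncol(X)`.
#' @return object of class `mlp_model`: `W1` (inputs x hidden), `b1`, `W2`
#'   (hidden), `b2`, `trace` (per-epoch MSE), `final_mse`, `config`.
#' @export
mlp_train <- function(X, y, config = mlp_config(n_inputs = ncol(X))) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == config$n_inputs, length(y) == nrow(X))
  ir <- config$init_range
  init <- with_seed(config$seed,
                    stats::runif((config$n_inputs + 2) * config$n_hidden + 1,
                                 -ir, ir))
  nh <- config$n_hidden
  W1 <- matrix(init[seq_len(config$n_inputs * nh)], config$n_inputs, nh)
  off <- config$n_inputs * nh
  b1 <- init[off + seq_len(nh)]
  W2 <- init[off + nh + seq_len(nh)]
  b2 <- init[off + 2 * nh + 1]
  lr <- config$learning_rate
  trace <- numeric(config$epochs)
  mse0 <- NULL
  for (epoch in seq_len(config$epochs)) {
    H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
    o <- sigmoid(drop(H %*% W2) + b2)
    err <- o - y
    trace[epoch] <- mean(err^2)
    if (is.null(mse0)) mse0 <- trace[1]
    if (!is.finite(trace[epoch]) || trace[epoch] > 10 * mse0) {
      stop("training diverged (MSE ", signif(trace[epoch], 3),
           "); reduce the learning rate")
    }
    d_o <- err * o * (1 - o)                 # summed-batch output delta
    gW2 <- drop(crossprod(H, d_o))
    gb2 <- sum(d_o)
    d_h <- (d_o %o% W2) * H * (1 - H)
    gW1 <- crossprod(X, d_h)
    gb1 <- colSums(d_h)
    W1 <- W1 - lr * gW1
    b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2
    b2 <- b2 - lr * gb2
  }
  H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
  o <- sigmoid(drop(H %*% W2) + b2)
  rownames(W1) <- colnames(X)
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace,
                 final_mse = mean((o - y)^2), config = config),
            class = "mlp_model")
}

#' Forward pass
#'
#' @param object an `mlp_model`.
#' @param newdata matrix with columns ordered as at training.
#' @param ... unused.
#' @return predictions in (0, 1).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$W1)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         nrow(object$W1))
  }
  H <- sigmoid(sweep(X %*% object$W1, 2, object$b1, "+"))
  drop(sigmoid(drop(H %*% object$W2) + object$b2))
}

#' Build the cross-validation fold plan
#'
#' With `n = 5k + 2` stimuli, a seeded shuffle assigns `5k` of them to five
#' disjoint folds of `k`; the two left-over stimuli are appended to every
#' test set, so each fold is tested on `k + 2` stimuli after training on the
#' other four folds.
#'
#' @param stimulus_ids character vector of ids, `length %% 5 == 2`.
#' @param seed partition seed.
#' @return object of class `fold_plan`: `folds` (list of 5 id vectors),
#'   `extras` (2 ids), `seed`.
#' @export
make_fold_plan <- function(stimulus_ids, seed = 1L) {
  n <- length(stimulus_ids)
  if (n %% 5 != 2) {
    stop("need n = 5k + 2 stimuli (got ", n,
         "); the two left-overs are shared across test sets")
  }
  shuffled <- with_seed(seed, sample(stimulus_ids))
  k <- (n - 2) %/% 5
  folds <- split(shuffled[seq_len(5 * k)], rep(seq_len(5), each = k))
  structure(list(folds = unname(folds), extras = shuffled[5 * k + 1:2],
                 seed = seed),
            class = "fold_plan")
}

#' Cross-validate the network over a fold plan
#'
#' For each fold the network is trained (with a fold-specific
#' initialization seed derived from `config$seed`) on the stimuli of the
#' other four folds and tested on the fold plus the two shared extras;
#' test-set RMSE per fold and their mean are reported, together with the
#' per-fold models for contribution analysis.
#'
#' @param X range-normalized descriptor matrix with stimulus ids as row
#'   names (or a data frame with `stimulus_id`).
#' @param y named response vector on \[0, 1\] (names = stimulus ids).
#' @param plan a [make_fold_plan()].
#' @param config an [mlp_config()].
#' @return object of class `mlp_cv`: `fold_rmse`, `mean_rmse`, `models`,
#'   `plan`, `config`.
#' @export
crossvalidate_mlp <- function(X, y, plan, config = mlp_config()) {
  m <- as_descriptor_matrix(X)
  stopifnot(inherits(plan, "fold_plan"), !is.null(rownames(m)))
  if (is.null(names(y))) names(y) <- rownames(m)
  fold_rmse <- numeric(5)
  models <- vector("list", 5)
  for (f in 1:5) {
    test_ids <- c(plan$folds[[f]], plan$extras)
    train_ids <- setdiff(rownames(m), test_ids)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- mlp_train(m[train_ids, , drop = FALSE], y[train_ids], cfg)
    pred <- predict(fit, m[test_ids, , drop = FALSE])
    fold_rmse[f] <- sqrt(mean((y[test_ids] - pred)^2))
    models[[f]] <- fit
  }
  structure(list(fold_rmse = fold_rmse, mean_rmse = mean(fold_rmse),
                 models = models, plan = plan, config = config),
            class = "mlp_cv")
}

#' @export
print.mlp_cv <- function(x, ...) {
  cat("<mlp_cv: per-fold RMSE ",
      paste(sprintf("%.4f", x$fold_rmse), collapse = " "),
      sprintf(", mean %.4f>\n", x$mean_rmse), sep = "")
  invisible(x)
}

#' Signed connection-weight feature contributions
#'
#' Milne-style analysis of a trained network: the contribution of input `i`
#' is `sum_j (W1[i, j] / sum_i' |W1[i', j]|) * W2[j]` — each hidden unit's
#' input weights are normalized by their absolute sum, weighted by that
#' unit's output weight, and summed over hidden units. Contributions are
#' expressed as signed percentages of the total absolute contribution, so
#' the absolute percentages sum to 100. Hidden units whose input weights are
#' all zero are skipped.
#'
#' @param model an `mlp_model`.
#' @return named numeric vector of signed percentages.
#' @export
milne_contributions <- function(model) {
  W1 <- model$W1
  W2 <- model$W2
  contrib <- numeric(nrow(W1))
  for (j in seq_along(W2)) {
    denom <- sum(abs(W1[, j]))
    if (denom == 0) next
    contrib <- contrib + W1[, j] / denom * W2[j]
  }
  total <- sum(abs(contrib))
  if (total == 0) stop("all contributions are zero")
  stats::setNames(100 * contrib / total, rownames(W1))
}

#' Average contributions across the cross-validation fold models
#'
#' @param cv an `mlp_cv`.
#' @return named numeric vector: per-descriptor mean signed percentage over
#'   the five fold models.
#' @export
cv_contributions <- function(cv) {
  rowMeans(sapply(cv$models, milne_contributions))
}

#' Fit metrics for a cross-validated network
#'
#' Mirrors the PLS report: R^2 is the training-set R^2 averaged over the
#' five folds; Q^2 = 1 - PRESS/TSS with PRESS accumulated from the held-out
#' predictions of the five disjoint folds (the two shared extras are
#' excluded so every stimulus is predicted exactly once) and TSS about the
#' mean of those stimuli; RMSE is the mean of the per-fold test RMSEs.
#'
#' @param cv an `mlp_cv`.
#' @param X the range-normalized descriptor matrix used for training.
#' @param y named response vector on \[0, 1\].
#' @return named vector: `r2`, `q2`, `rmse`.
#' @export
mlp_cv_metrics <- function(cv, X, y) {
  m <- as_descriptor_matrix(X)
  if (is.null(names(y))) names(y) <- rownames(m)
  r2s <- numeric(5)
  press <- 0
  fold_ids <- unlist(cv$plan$folds)
  for (f in 1:5) {
    test_ids <- c(cv$plan$folds[[f]], cv$plan$extras)
    train_ids <- setdiff(rownames(m), test_ids)
    fit <- cv$models[[f]]
    r2s[f] <- model_metrics(y[train_ids],
                            predict(fit, m[train_ids, , drop = FALSE]))["r2"]
    hold <- cv$plan$folds[[f]]
    press <- press + sum((y[hold] -
                            predict(fit, m[hold, , drop = FALSE]))^2)
  }
  tss <- sum((y[fold_ids] - mean(y[fold_ids]))^2)
  c(r2 = mean(r2s), q2 = 1 - press / tss, rmse = cv$mean_rmse)
}
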
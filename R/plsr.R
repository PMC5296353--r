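# Single-response partial least-squares regression (PLS1, NIPALS-style
# deflation) with eigenvalue-threshold component selection and five-fold
# cross-validated fit/prediction metrics.

#' Fit a single-response PLS regression
#'
#' Predictors are z-scored (mean 0, SD 1) and the response centered
#' internally. Components are extracted by iterative deflation: the weight
#' vector is the normalized covariance of the (deflated) predictors with the
#' response, scores are predictor projections, and predictor/response
#' loadings are score regressions. Regression coefficients on the original
#' predictor scale are recovered from the weight and loading matrices.
#'
#' @param X numeric matrix or descriptor data frame, stimuli in rows.
#' @param y numeric response (mean ratings), length `nrow(X)`.
#' @param n_components number of latent components.
#' @return object of class `plsr_model`: weights `W`, predictor loadings
#'   `P`, response loadings `q`, score variances `eigenvalues`, scores `Tm`,
#'   coefficients (standardized scale), centering/scaling vectors.
#' @export
fit_plsr <- function(X, y, n_components) {
  m <- as_descriptor_matrix(X)
  n <- nrow(m)
  p <- ncol(m)
  stopifnot(length(y) == n, n >= n_components + 1)
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  if (any(sdev == 0)) stop("constant predictor column")
  Z <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  ybar <- mean(y)
  r <- y - ybar
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  E <- Z
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, r))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("predictor matrix rank is below the requested component count")
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(E, tt)) / tt2
    qq <- sum(r * tt) / tt2
    E <- E - tcrossprod(tt, pp)
    r <- r - tt * qq
    W[, a] <- w
    P[, a] <- pp
    q[a] <- qq
    Tm[, a] <- tt
  }
  B <- drop(W %*% solve(crossprod(P, W), q))
  names(B) <- colnames(m)
  dimnames(W) <- dimnames(P) <- list(colnames(m),
                                     paste0("comp", seq_len(n_components)))
  structure(list(W = W, P = P, q = q,
                 eigenvalues = apply(Tm, 2, stats::var),
                 Tm = Tm, coefficients = B, x_center = mu,
                 x_scale = sdev, y_center = ybar,
                 n_components = n_components),
            class = "plsr_model")
}

#' Predict from a PLS model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix/data frame with the training predictor columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  m <- as_descriptor_matrix(newdata)
  sel <- names(object$x_center)
  if (!is.null(sel) && !is.null(colnames(m))) {
    m <- m[, sel, drop = FALSE]
  }
  Z <- sweep(sweep(m, 2, object$x_center), 2, object$x_scale, "/")
  drop(Z %*% object$coefficients) + object$y_center
}

#' Select the number of PLS components by the eigenvalue-1 rule
#'
#' Fits up to `max_components` and counts the leading components whose score
#' variance (the component eigenvalue on the standardized predictors) is at
#' least 1; a minimum of one component is always selected.
#'
#' @param X predictors (stimuli x descriptors).
#' @param y response.
#' @param max_components upper bound (defaults to the predictor count).
#' @return integer component count.
#' @export
select_n_components <- function(X, y, max_components = NULL) {
  m <- as_descriptor_matrix(X)
  A <- min(max_components %||% ncol(m), ncol(m), nrow(m) - 1)
  ev <- tryCatch(fit_plsr(m, y, A)$eigenvalues,
                 error = function(e) {
                   # rank-deficient: refit with as many components as exist
                   k <- qr(scale(m))$rank
                   fit_plsr(m, y, min(A, k))$eigenvalues
                 })
  below <- which(ev < 1)
  if (length(below) == 0) return(length(ev))
  max(1L, below[1] - 1L)
}

#' Cross-validated PLS fit report
#'
#' Fits the full model (component count chosen by the eigenvalue-1 rule
#' unless given), computes training R^2 and RMSE, and five-fold
#' cross-validated Q^2 = 1 - PRESS/TSS, with PRESS accumulated over the
#' held-out folds and TSS about the whole-sample mean (per-fold baseline
#' available via `tss_per_fold`). Folds are a seeded random partition into
#' near-equal parts. Per-component partial R^2 is the incremental explained
#' variance in fitting order.
#'
#' @param X predictors.
#' @param y response.
#' @param n_components component count; `NULL` to auto-select.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param tss_per_fold if `TRUE`, PRESS baselines use training-fold means.
#' @return object of class `plsr_report`: `r2`, `q2`, `rmse`,
#'   `n_components`, `partial_r2`, `loadings` (descriptor x component),
#'   `model`, `fold_assignment`, `seed`.
#' @export
crossvalidate_plsr <- function(X, y, n_components = NULL, folds = 5,
                               seed = 1L, tss_per_fold = FALSE) {
  m <- as_descriptor_matrix(X)
  n <- nrow(m)
  stopifnot(n >= 10)
  if (is.null(n_components)) n_components <- select_n_components(m, y)
  fit <- fit_plsr(m, y, n_components)
  pred <- predict(fit, m)
  mets <- model_metrics(y, pred)

  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  if (min(table(fold_id)) < 2) stop("a fold has fewer than 2 stimuli")
  press <- 0
  tss <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    cvfit <- fit_plsr(m[!test, , drop = FALSE], y[!test], n_components)
    cvpred <- predict(cvfit, m[test, , drop = FALSE])
    press <- press + sum((y[test] - cvpred)^2)
    base <- if (tss_per_fold) mean(y[!test]) else mean(y)
    tss <- tss + sum((y[test] - base)^2)
  }
  partial <- vapply(seq_len(n_components), function(a) {
    fa <- fit_plsr(m, y, a)
    model_metrics(y, predict(fa, m))[["r2"]]
  }, numeric(1))
  structure(list(r2 = mets[["r2"]], q2 = 1 - press / tss,
                 rmse = mets[["rmse"]], n_components = n_components,
                 partial_r2 = diff(c(0, partial)),
                 loadings = fit$P, model = fit,
                 fold_assignment = fold_id, seed = seed),
            class = "plsr_report")
}

#' @export
print.plsr_report <- function(x, ...) {
  cat(sprintf(
    "<plsr_report: %d components, R2 = %.4f, Q2 = %.4f, RMSE = %.4f>\n",
    x$n_components, x$r2, x$q2, x$rmse))
  invisible(x)
}

#' Descriptor importance from a PLS fit
#'
#' Components are not equally informative, so each component's weight
#' vector is scaled by that component's contribution to the response (the
#' response loading times the score SD) before ranking; a descriptor's
#' importance is then the largest absolute scaled weight it attains on any
#' component, keeping its sign. This mirrors how multi-component loading
#' tables are conventionally read (dominant-component coordinates shrink
#' with component relevance).
#'
#' @param report a `plsr_report` or `plsr_model`.
#' @return named numeric vector of signed importances.
#' @export
plsr_importance <- function(report) {
  model <- if (inherits(report, "plsr_report")) report$model else report
  stopifnot(inherits(model, "plsr_model"))
  scale_a <- abs(model$q) * sqrt(model$eigenvalues)
  L <- sweep(model$W, 2, scale_a, "*")
  apply(L, 1, function(row) row[which.max(abs(row))])
}
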
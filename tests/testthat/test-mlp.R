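# the 17-3-1 backprop network, fold plan, and contribution analysis

test_that("fold plans partition 137 ids into 5 x 27 + 2 shared extras", {
  ids <- sprintf("S%03d", 1:137)
  plan <- make_fold_plan(ids, seed = 3)
  expect_length(plan$folds, 5)
  expect_true(all(lengths(plan$folds) == 27))
  expect_length(plan$extras, 2)
  all_ids <- c(unlist(plan$folds), plan$extras)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0)
  # each test set has 29 items
  expect_true(all(vapply(plan$folds, function(f)
    length(c(f, plan$extras)), numeric(1)) == 29))
  expect_identical(plan, make_fold_plan(ids, seed = 3))
  expect_error(make_fold_plan(sprintf("S%03d", 1:100)), "5k")
})

test_that("forward pass matches hand arithmetic and edge cases", {
  model <- structure(list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
                          W2 = c(0, 0), b2 = 0), class = "mlp_model")
  expect_equal(unname(predict(model, matrix(rnorm(6), 3, 2))),
               rep(0.5, 3))
  # hand-computed 2-input / 1-hidden example
  m2 <- structure(list(W1 = matrix(c(1, -1), 2, 1), b1 = 0.5,
                       W2 = 2, b2 = -1), class = "mlp_model")
  x <- matrix(c(0.3, 0.7), 1, 2)
  h <- 1 / (1 + exp(-(0.3 - 0.7 + 0.5)))
  expect_equal(unname(predict(m2, x)), 1 / (1 + exp(-(2 * h - 1))),
               tolerance = 1e-12)
  # saturation under a large positive path
  m3 <- structure(list(W1 = matrix(c(50, 0), 2, 1), b1 = 0,
                       W2 = 50, b2 = -25), class = "mlp_model")
  expect_gt(predict(m3, matrix(c(1, 0), 1, 2)), 0.999)
  expect_error(predict(m2, matrix(0, 1, 3)), "expects")
})

test_that("training contracts: null update, bias-only fit, divergence", {
  with_seed_local(21, {
    X <- matrix(runif(40 * 5), 40, 5)
    y <- runif(40)
    cfg0 <- mlp_config(n_inputs = 5, learning_rate = 0, epochs = 50,
                       seed = 1)
    m0 <- mlp_train(X, y, cfg0)
    m_init <- mlp_train(X, y, mlp_config(n_inputs = 5, learning_rate = 0,
                                         epochs = 0, seed = 1))
    expect_identical(m0$W1, m_init$W1)
    expect_identical(m0$W2, m_init$W2)
    # constant target 0.5: bias alone solves it quickly
    m1 <- mlp_train(X, rep(0.5, 40),
                    mlp_config(n_inputs = 5, epochs = 700, seed = 2))
    expect_lt(m1$final_mse, 1e-3)
    # oversized learning rate raises the divergence guard: start near the
    # solution (targets ~0.5, so initial MSE is tiny) and blow it up
    y_mid <- runif(40, 0.48, 0.52)
    expect_error(
      mlp_train(X, y_mid, mlp_config(n_inputs = 5, learning_rate = 500,
                                     epochs = 200, seed = 3)),
      "learning rate")
  })
})

test_that("training is deterministic and order-invariant within an epoch", {
  with_seed_local(22, {
    X <- matrix(runif(30 * 4), 30, 4)
    y <- runif(30)
    cfg <- mlp_config(n_inputs = 4, epochs = 100, seed = 9)
    a <- mlp_train(X, y, cfg)
    b <- mlp_train(X, y, cfg)
    expect_identical(a$W1, b$W1)
    expect_identical(a$trace, b$trace)
    # permuting pattern order leaves the summed batch update unchanged
    perm <- sample(30)
    c_ <- mlp_train(X[perm, ], y[perm], cfg)
    expect_equal(unname(a$W1), unname(c_$W1), tolerance = 1e-12)
    expect_equal(a$final_mse, c_$final_mse, tolerance = 1e-12)
  })
})

test_that("a noiseless planted mapping converges below the MSE target", {
  with_seed_local(23, {
    X <- matrix(runif(108 * 17), 108, 17,
                dimnames = list(NULL, paste0("d", 1:17)))
    y <- 0.2 + 0.25 * X[, 3] + 0.2 * X[, 7] + 0.15 * X[, 12]
    m <- mlp_train(X, y, mlp_config(epochs = 1000, seed = 4))
    expect_lt(m$final_mse, 0.008)
    expect_true(all(is.finite(m$trace)))
  })
})

test_that("cross-validation reports five fold RMSEs and their mean", {
  with_seed_local(24, {
    n <- 52  # 5 folds of 10 + 2 extras
    X <- matrix(runif(n * 6), n, 6,
                dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:6)))
    y <- stats::setNames(0.3 + 0.4 * X[, 2], rownames(X))
    plan <- make_fold_plan(rownames(X), seed = 5)
    cv <- crossvalidate_mlp(X, y, plan,
                            mlp_config(n_inputs = 6, epochs = 700,
                                       seed = 6))
    expect_length(cv$fold_rmse, 5)
    expect_equal(cv$mean_rmse, mean(cv$fold_rmse))
    expect_lt(cv$mean_rmse, 0.05)  # learnable noiseless mapping
    met <- mlp_cv_metrics(cv, X, y)
    expect_true(all(is.finite(met)))
    expect_lt(met[["q2"]], 1)
  })
})

test_that("Milne contributions match a brute-force path enumeration", {
  # single active path
  m <- structure(list(W1 = matrix(c(2, 0, 0, 0, 0, 0), 3, 2),
                      W2 = c(1, 0)), class = "mlp_model")
  rownames(m$W1) <- c("a", "b", "c")
  contrib <- milne_contributions(m)
  expect_equal(unname(contrib), c(100, 0, 0))
  # sign symmetry: negating the output weights flips all signs
  with_seed_local(25, {
    W1 <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
    W2 <- rnorm(2)
    m1 <- structure(list(W1 = W1, W2 = W2), class = "mlp_model")
    m2 <- structure(list(W1 = W1, W2 = -W2), class = "mlp_model")
    expect_equal(milne_contributions(m1), -milne_contributions(m2))
    # brute-force per-path summation oracle
    raw <- numeric(3)
    for (i in 1:3) {
      for (j in 1:2) {
        raw[i] <- raw[i] + W1[i, j] / sum(abs(W1[, j])) * W2[j]
      }
    }
    oracle <- 100 * raw / sum(abs(raw))
    expect_equal(unname(milne_contributions(m1)), oracle,
                 tolerance = 1e-12)
    # absolute contributions sum to 100
    expect_equal(sum(abs(milne_contributions(m1))), 100,
                 tolerance = 1e-12)
  })
})

test_that("more hidden units do not wreck held-out error", {
  with_seed_local(26, {
    n <- 52
    X <- matrix(runif(n * 6), n, 6,
                dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:6)))
    y <- stats::setNames(0.25 + 0.3 * X[, 1] + 0.2 * X[, 4], rownames(X))
    plan <- make_fold_plan(rownames(X), seed = 7)
    cv3 <- crossvalidate_mlp(X, y, plan,
                             mlp_config(n_inputs = 6, n_hidden = 3,
                                        epochs = 300, seed = 8))
    cv7 <- crossvalidate_mlp(X, y, plan,
                             mlp_config(n_inputs = 6, n_hidden = 7,
                                        epochs = 300, seed = 8))
    expect_lt(cv7$mean_rmse - cv3$mean_rmse, 0.02)
  })
})
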
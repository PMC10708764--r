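test_that("hidden-size heuristics evaluate as defined", {
  cand <- hidden_size_candidates(21, 1, k_samples = 113)
  expect_equal(cand$log2, 5)                      # ceiling(log2(21))
  expect_equal(cand$sqrt_range, ceiling(sqrt(22)) + 0:10)
  expect_equal(cand$trial, 5:20)
  # coverage heuristic against a direct enumeration
  brute <- function(n, k) {
    for (M in 1:64) {
      s <- 0
      for (i in 0:n) s <- s + if (i > M) 0 else choose(M, i)
      if (s > k) return(M)
    }
  }
  for (case in list(c(3, 10), c(5, 100), c(21, 113)))
    expect_equal(hidden_size_candidates(case[1], 1, case[2])$cover,
                 brute(case[1], case[2]))
  # literal un-rooted variant
  expect_equal(hidden_size_candidates(21, 1, 10, literal_sum = TRUE)$sqrt_range,
               22 + 0:10)
})

test_that("the 70/15/15 split is exhaustive, disjoint and sized by floor", {
  sp <- split_dataset(100, seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$validation, 15)
  expect_length(sp$test, 15)

  sp162 <- split_dataset(162, seed = 2)
  expect_length(sp162$train, 113)
  expect_length(sp162$validation, 24)
  expect_length(sp162$test, 25)
  all_idx <- c(sp162$train, sp162$validation, sp162$test)
  expect_setequal(all_idx, 1:162)
  expect_equal(length(all_idx), length(unique(all_idx)))

  expect_identical(split_dataset(50, seed = 3), split_dataset(50, seed = 3))
  expect_error(split_dataset(5), "at least 10")
})

test_that("backprop Jacobian matches central finite differences", {
  set.seed(13)
  p <- 3; h <- 4; N <- 7
  X <- matrix(rnorm(N * p), N, p)
  theta <- rnorm(forestagb:::mlp_n_params(p, h), sd = 0.6)
  J <- forestagb:::mlp_jacobian(theta, X, p, h)
  eps <- 1e-6
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    fd <- (forestagb:::mlp_forward(tp, X, p, h)$yhat -
             forestagb:::mlp_forward(tm, X, p, h)$yhat) / (2 * eps)
    expect_equal(J[, k], fd, tolerance = 1e-5)
  }
})

test_that("accepted training steps strictly decrease the training MSE", {
  set.seed(14)
  n <- 80
  X <- matrix(runif(n * 3, -1, 1), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- sin(2 * X[, 1]) + 0.5 * X[, 2] + rnorm(n, 0, 0.05)
  fit <- train_mlp_lm(X, y, mlp_config(hidden_size = 6, seed = 3))
  expect_gt(nrow(fit$history), 3)
  expect_true(all(diff(fit$history$mse_train) < 0))
})

test_that("degenerate and easy targets are fitted to specification", {
  set.seed(15)
  n <- 40
  X <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  # constant target: training MSE collapses to ~0
  fitc <- train_mlp_lm(X, rep(3, n), mlp_config(hidden_size = 3, seed = 1))
  expect_lt(mean((predict(fitc, X) - 3)^2), 1e-10)

  # linear low-noise target: near-perfect held-out fit
  n2 <- 150
  X2 <- matrix(runif(n2 * 3, -1, 1), n2, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  y2 <- 2 * X2[, 1] - X2[, 3] + 5 + rnorm(n2, 0, 0.01)
  sp <- split_dataset(n2, seed = 4)
  fit2 <- train_mlp_lm(X2, y2, mlp_config(hidden_size = 10, seed = 5), sp)
  r2 <- r_squared(predict(fit2, X2[sp$test, ]), y2[sp$test], "cod")
  expect_gte(r2, 0.99)

  # XOR: the classic nonlinear fixture
  Xx <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  fx <- train_mlp_lm(Xx, c(0, 1, 1, 0),
                     mlp_config(hidden_size = 3, max_epochs = 500, seed = 2))
  expect_lt(mean((predict(fx, Xx) - c(0, 1, 1, 0))^2), 1e-3)
})

test_that("prediction is deterministic and matches a hand-coded forward pass", {
  # pinned 2-2-1 network with identity normalisation
  w <- list(W1 = matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2),
            b1 = c(0.1, -0.2), w2 = c(1.2, -0.7), b2 = 0.05)
  obj <- structure(list(
    weights = w, theta = forestagb:::mlp_flatten(w),
    norm = list(x_lo = c(a = -1, b = -1), x_hi = c(a = 1, b = 1),
                y_lo = -1, y_hi = 1),
    config = mlp_config(hidden_size = 2),
    feature_names = c("a", "b"),
    history = NULL, best_epoch = 0L, stop_reason = "pinned"),
    class = "agb_mlp")
  x <- c(a = 0.3, b = -0.6)
  hd <- tanh(w$W1 %*% x + w$b1)
  expected <- sum(w$w2 * hd) + w$b2
  got <- predict(obj, as.data.frame(as.list(x)))
  expect_equal(got, expected, tolerance = 1e-14)
  expect_identical(got, predict(obj, as.data.frame(as.list(x))))

  # zero weights: constant output at the (denormalised) output bias
  wz <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0), w2 = c(0, 0), b2 = 0.4)
  objz <- obj; objz$weights <- wz; objz$theta <- forestagb:::mlp_flatten(wz)
  X <- data.frame(a = rnorm(5), b = rnorm(5))
  expect_equal(predict(objz, X), rep(0.4, 5))

  expect_error(predict(obj, data.frame(a = 1)), "feature")
})

test_that("training is reproducible for a fixed configuration", {
  set.seed(16)
  X <- matrix(runif(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + X[, 2]^2
  sp <- split_dataset(60, seed = 6)
  f1 <- train_mlp_lm(X, y, mlp_config(hidden_size = 5, seed = 9), sp)
  f2 <- train_mlp_lm(X, y, mlp_config(hidden_size = 5, seed = 9), sp)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$history, f2$history)
})

test_that("hidden-size search covers the range and selects the validation optimum", {
  set.seed(17)
  n <- 90
  X <- matrix(runif(n * 2, -1, 1), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1.5 * X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.02)
  sp <- split_dataset(n, seed = 7)
  hs <- hidden_size_search(X, y, sizes = 5:8, sp,
                           mlp_config(max_epochs = 60, seed = 8))
  expect_equal(hs$table$hidden_size, 5:8)
  expect_true(all(is.finite(hs$table$val_mse)))
  expect_equal(hs$best_size,
               hs$table$hidden_size[which.min(hs$table$val_mse)])
  hs2 <- hidden_size_search(X, y, sizes = 5:8, sp,
                            mlp_config(max_epochs = 60, seed = 8))
  expect_identical(hs$table, hs2$table)
})
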
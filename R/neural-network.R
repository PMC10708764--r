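#' Configuration of the single-hidden-layer network
#'
#' One hidden layer of `hidden_size` tanh units and a linear output unit,
#' trained by damped Gauss-Newton (Levenberg-Marquardt) least squares on
#' min-max normalised inputs and targets.
#'
#' @param hidden_size Number of hidden units (>= 1).
#' @param max_epochs Maximum accepted update steps.
#' @param lm_lambda_init Initial damping factor (default 1e-3).
#' @param lm_lambda_factor Multiplicative damping adjustment (default 10):
#'   divided out after an accepted step, multiplied in after a rejection.
#' @param lm_lambda_max Damping overflow bound; training stops when
#'   exceeded.
#' @param validation_patience Consecutive epochs without validation-MSE
#'   improvement tolerated before early stopping (default 6).
#' @param seed Seed for weight initialisation.
#' @return Object of class `agb_mlp_config`.
#' @export
mlp_config <- function(hidden_size = 10L, max_epochs = 200L,
                       lm_lambda_init = 1e-3, lm_lambda_factor = 10,
                       lm_lambda_max = 1e10, validation_patience = 6L,
                       seed = 1L) {
  stopifnot(hidden_size >= 1L, max_epochs >= 0L, lm_lambda_init > 0,
            lm_lambda_factor > 1, validation_patience >= 1L)
  structure(list(hidden_size = as.integer(hidden_size),
                 max_epochs = as.integer(max_epochs),
                 lm_lambda_init = lm_lambda_init,
                 lm_lambda_factor = lm_lambda_factor,
                 lm_lambda_max = lm_lambda_max,
                 validation_patience = as.integer(validation_patience),
                 seed = as.integer(seed)),
            class = "agb_mlp_config")
}

#' Hidden-layer size candidates
#'
#' The three common sizing heuristics plus the trial-and-error range
#' 5..20:
#' \enumerate{
#'   \item the smallest `M` such that `sum_{i=0}^{n} C(M, i) > k` (with
#'     `C(M, i) := 0` when `i > M`), where `k` is the training-sample count
#'     and `n` the input count;
#'   \item `ceiling(sqrt(n + m)) + a` for `a` in `0..10` (`m` = output
#'     count); the literal un-rooted form `n + m + a` is available via
#'     `literal_sum = TRUE`;
#'   \item `ceiling(log2(n))`.
#' }
#'
#' @param n_inputs Number of input nodes.
#' @param n_outputs Number of output nodes (default 1).
#' @param k_samples Number of training samples (heuristic 1).
#' @param a_range Constant range for heuristic 2 (default `0:10`).
#' @param literal_sum Use `n + m + a` instead of `sqrt(n + m) + a`.
#' @return List with elements `cover`, `sqrt_range`, `log2`, `trial`.
#' @export
hidden_size_candidates <- function(n_inputs, n_outputs = 1L, k_samples,
                                   a_range = 0:10, literal_sum = FALSE) {
  stopifnot(n_inputs >= 1, n_outputs >= 1, k_samples >= 1)
  cover <- NA_integer_
  for (M in 1:64) {
    s <- sum(vapply(0:n_inputs,
                    function(i) if (i > M) 0 else choose(M, i), numeric(1)))
    if (s > k_samples) { cover <- M; break }
  }
  base <- if (literal_sum) n_inputs + n_outputs else
    ceiling(sqrt(n_inputs + n_outputs))
  list(cover = cover,
       sqrt_range = base + a_range,
       log2 = as.integer(ceiling(log2(n_inputs))),
       trial = 5:20)
}

#' Random train/validation/test split
#'
#' Shuffles `1..n` under the seed and cuts it into
#' `floor(r1 n)` / `floor(r2 n)` / remainder pieces (default ratios
#' 0.70/0.15/0.15, so the test set absorbs the rounding remainder).
#'
#' @param n Number of observations (>= 10).
#' @param ratios Length-3 ratios summing to 1.
#' @param seed Integer seed.
#' @return List of class `agb_split` with integer index vectors `train`,
#'   `validation`, `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  if (n < 10L) stop("need at least 10 observations to split")
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  structure(list(train = sort(idx[seq_len(n_train)]),
                 validation = sort(idx[n_train + seq_len(n_val)]),
                 test = sort(idx[(n_train + n_val + 1):n]),
                 ratios = ratios, seed = seed),
            class = "agb_split")
}

# ---- internal parameter plumbing ------------------------------------------

mlp_n_params <- function(p, h) h * p + h + h + 1L

mlp_unflatten <- function(theta, p, h) {
  stopifnot(length(theta) == mlp_n_params(p, h))
  i <- 0L
  W1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- theta[i + seq_len(h)]; i <- i + h
  w2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_flatten <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)

mlp_forward <- function(theta, Xn, p, h) {
  w <- mlp_unflatten(theta, p, h)
  Z <- Xn %*% t(w$W1) + matrix(w$b1, nrow(Xn), h, byrow = TRUE)
  Tn <- tanh(Z)
  list(yhat = as.numeric(Tn %*% w$w2 + w$b2), Tn = Tn, w = w)
}

# per-sample Jacobian d yhat_i / d theta (N x P) by backprop
mlp_jacobian <- function(theta, Xn, p, h) {
  fw <- mlp_forward(theta, Xn, p, h)
  Tn <- fw$Tn
  dtanh <- 1 - Tn^2
  N <- nrow(Xn)
  JW1 <- matrix(0, N, h * p)
  for (k in seq_len(p))
    JW1[, (k - 1L) * h + seq_len(h)] <-
      dtanh * matrix(fw$w$w2, N, h, byrow = TRUE) * Xn[, k]
  Jb1 <- dtanh * matrix(fw$w$w2, N, h, byrow = TRUE)
  Jw2 <- Tn
  Jb2 <- matrix(1, N, 1)
  # column order must match mlp_flatten: W1 is stored column-major (h x p)
  cbind(JW1, Jb1, Jw2, Jb2)
}

minmax_norm <- function(x, lo, hi) {
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(x, 2, lo), 2, span, "/") * 2 - 1
}

mlp_init_theta <- function(p, h, seed) {
  set.seed(seed)
  W1 <- matrix(stats::runif(h * p, -0.5, 0.5) / sqrt(p), h, p)
  b1 <- stats::runif(h, -0.5, 0.5)
  w2 <- stats::runif(h, -0.5, 0.5) / sqrt(h)
  b2 <- stats::runif(1, -0.5, 0.5)
  mlp_flatten(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2))
}

#' Train the network by Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the training subset: at each epoch the update
#' `delta` solves `(J'J + lambda I) delta = J'e` with the per-sample
#' backpropagated Jacobian `J`; a step is accepted only if it strictly
#' reduces the training SSE (then `lambda` shrinks), otherwise `lambda`
#' grows and the step is retried.  Training stops at `max_epochs`, on
#' damping overflow, or when the validation MSE has not improved for
#' `validation_patience` consecutive epochs (the returned weights are those
#' of the best validation epoch).
#'
#' Inputs and targets are min-max normalised to `[-1, 1]` using the
#' training subset; the normalisation is stored with the weights and
#' applied transparently by [predict.agb_mlp()].
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param y Numeric response.
#' @param config An [mlp_config()].
#' @param split Optional [split_dataset()] result; without it all rows are
#'   training data and early stopping is disabled.
#' @param init_theta Optional initial flattened weight vector (used by the
#'   swarm-optimised trainer); default random initialisation under
#'   `config$seed`.
#' @return Object of class `agb_mlp`: weights, normalisation, history
#'   (accepted epochs: `epoch`, `lambda`, `mse_train`, `mse_val`),
#'   `feature_names`, `stop_reason`, `best_epoch`.
#' @export
train_mlp_lm <- function(X, y, config = mlp_config(), split = NULL,
                         init_theta = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  p <- ncol(X); h <- config$hidden_size
  tr <- if (is.null(split)) seq_len(nrow(X)) else split$train
  va <- if (is.null(split)) integer(0) else split$validation
  x_lo <- apply(X[tr, , drop = FALSE], 2, min)
  x_hi <- apply(X[tr, , drop = FALSE], 2, max)
  y_lo <- min(y[tr]); y_hi <- max(y[tr])
  y_span <- if (y_hi > y_lo) y_hi - y_lo else 1
  Xn <- minmax_norm(X, x_lo, x_hi)
  yn <- (y - y_lo) / y_span * 2 - 1
  Xtr <- Xn[tr, , drop = FALSE]; ytr <- yn[tr]
  Xva <- Xn[va, , drop = FALSE]; yva <- yn[va]

  theta <- if (is.null(init_theta)) mlp_init_theta(p, h, config$seed) else {
    stopifnot(length(init_theta) == mlp_n_params(p, h))
    init_theta
  }
  sse <- function(th, Xs, ys) {
    e <- ys - mlp_forward(th, Xs, p, h)$yhat
    sum(e^2)
  }
  lambda <- config$lm_lambda_init
  cur_sse <- sse(theta, Xtr, ytr)
  val_mse <- function(th) if (length(va)) sse(th, Xva, yva) / length(va)
    else NA_real_
  best_val <- val_mse(theta); best_theta <- theta; best_epoch <- 0L
  bad_epochs <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < config$max_epochs) {
    J <- mlp_jacobian(theta, Xtr, p, h)
    e <- ytr - mlp_forward(theta, Xtr, p, h)$yhat
    g <- crossprod(J, e)
    H <- crossprod(J)
    accepted <- FALSE
    while (lambda <= config$lm_lambda_max) {
      delta <- tryCatch(
        solve(H + lambda * diag(ncol(H)), g),
        error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        cand_sse <- sse(cand, Xtr, ytr)
        if (is.finite(cand_sse) && cand_sse < cur_sse) {
          theta <- cand; cur_sse <- cand_sse
          lambda <- max(lambda / config$lm_lambda_factor, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$lm_lambda_factor
    }
    if (!accepted) {
      stop_reason <- if (lambda > config$lm_lambda_max) "lambda_overflow"
        else "no_improvement"
      break
    }
    epoch <- epoch + 1L
    vm <- val_mse(theta)
    hist[[epoch]] <- data.frame(epoch = epoch, lambda = lambda,
                                mse_train = cur_sse / length(ytr),
                                mse_val = vm)
    if (length(va)) {
      if (!is.na(vm) && (is.na(best_val) || vm < best_val)) {
        best_val <- vm; best_theta <- theta; best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$validation_patience) {
          stop_reason <- "early_stopping"
          break
        }
      }
    } else {
      best_theta <- theta; best_epoch <- epoch
    }
  }
  final_theta <- if (length(va)) best_theta else theta
  structure(list(
    weights = mlp_unflatten(final_theta, p, h),
    theta = final_theta,
    norm = list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
    config = config,
    feature_names = colnames(X),
    history = if (length(hist)) do.call(rbind, hist) else
      data.frame(epoch = integer(0), lambda = numeric(0),
                 mse_train = numeric(0), mse_val = numeric(0)),
    best_epoch = best_epoch,
    stop_reason = stop_reason),
    class = "agb_mlp")
}

#' Predict from a trained network
#'
#' Applies the stored min-max normalisation, the tanh hidden layer and
#' linear output, then maps back to the target scale.
#'
#' @param object An `agb_mlp` from [train_mlp_lm()] or [pso_train_mlp()].
#' @param newdata Matrix or data frame with the training feature columns.
#' @param ... Unused.
#' @return Numeric predictions on the original target scale.
#' @export
predict.agb_mlp <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (ncol(X) != length(object$norm$x_lo))
    stop("feature count mismatch")
  Xn <- minmax_norm(X, object$norm$x_lo, object$norm$x_hi)
  p <- ncol(X); h <- object$config$hidden_size
  yn <- mlp_forward(object$theta, Xn, p, h)$yhat
  (yn + 1) / 2 * (object$norm$y_hi - object$norm$y_lo) + object$norm$y_lo
}

#' @export
print.agb_mlp <- function(x, ...) {
  cat(sprintf(
    "agb_mlp: %d-%d-1 tanh network, %d accepted epoch(s), stop: %s\n",
    length(x$norm$x_lo), x$config$hidden_size, nrow(x$history),
    x$stop_reason))
  invisible(x)
}

#' Trial-and-error hidden-size search
#'
#' Trains one network per candidate size and selects the size with the
#' smallest validation MSE (ties break toward the smaller network).
#'
#' @param X,y Training data.
#' @param sizes Candidate hidden sizes (default 5..20).
#' @param split An [split_dataset()] result (validation set required).
#' @param config Base [mlp_config()]; its `hidden_size` is overridden.
#' @return List: `best_size`, `table` (data frame `hidden_size`,
#'   `val_mse`, `epochs`), `models` (fitted networks, named by size).
#' @export
hidden_size_search <- function(X, y, sizes = 5:20, split,
                               config = mlp_config()) {
  stopifnot(length(split$validation) > 0)
  res <- lapply(sizes, function(h) {
    cfg <- config; cfg$hidden_size <- as.integer(h)
    fit <- train_mlp_lm(X, y, cfg, split)
    vm <- mean((y[split$validation] -
                  predict(fit, X[split$validation, , drop = FALSE]))^2)
    list(fit = fit, vm = vm)
  })
  tab <- data.frame(hidden_size = sizes,
                    val_mse = vapply(res, function(r) r$vm, numeric(1)),
                    epochs = vapply(res, function(r) nrow(r$fit$history),
                                    numeric(1)))
  best <- sizes[which.min(tab$val_mse)]  # first minimum = smallest size
  list(best_size = best, table = tab,
       models = stats::setNames(lapply(res, `[[`, "fit"), sizes))
}
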
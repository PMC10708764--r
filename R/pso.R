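#' Particle swarm optimiser configuration
#'
#' Canonical global-best PSO: velocity update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, position update
#' `x <- x + v`, with componentwise velocity clamping and positions kept
#' inside the search bounds.  The inertia weight decreases linearly from
#' `inertia[1]` to `inertia[2]` over the run.
#'
#' @param swarm_size Number of particles N (>= 2, default 30).
#' @param max_iterations Iteration budget (default 200).
#' @param inertia Length-2 inertia schedule (default `c(0.9, 0.4)`).
#' @param c1,c2 Cognitive and social acceleration (default 1.49445).
#' @param position_bounds Length-2 search box applied to every dimension
#'   (default `c(-1, 1)`).
#' @param velocity_clamp Componentwise speed limit; default a quarter of
#'   the box width.
#' @param fitness_tolerance Stop early once the global best fitness is
#'   `<=` this value (default `-Inf`: disabled).
#' @param seed Integer seed.
#' @return Object of class `agb_pso_config`.
#' @export
pso_config <- function(swarm_size = 30L, max_iterations = 200L,
                       inertia = c(0.9, 0.4), c1 = 1.49445, c2 = 1.49445,
                       position_bounds = c(-1, 1),
                       velocity_clamp = 0.25 * diff(position_bounds),
                       fitness_tolerance = -Inf, seed = 1L) {
  stopifnot(swarm_size >= 2L, max_iterations >= 0L, c1 >= 0, c2 >= 0,
            length(inertia) == 2L, length(position_bounds) == 2L,
            position_bounds[2] > position_bounds[1], velocity_clamp > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, c1 = c1, c2 = c2,
                 position_bounds = position_bounds,
                 velocity_clamp = velocity_clamp,
                 fitness_tolerance = fitness_tolerance,
                 seed = as.integer(seed)),
            class = "agb_pso_config")
}

#' Minimise a function by particle swarm
#'
#' Implements the standard flow: (1) random initialisation of positions and
#' velocities; (2) fitness evaluation; (3) per-particle best (pbest)
#' update; (4) global best (gbest) update; (5) velocity and position
#' update; (6) repeat until the iteration budget is spent or the fitness
#' tolerance is reached.  With `max_iterations = 0` the result is exactly
#' the best of the `N` random initial positions.
#'
#' @param fitness Function mapping a numeric vector of length `dim` to a
#'   finite scalar (minimised).
#' @param dim Problem dimension.
#' @param config An [pso_config()].
#' @return List of class `agb_pso`: `par` (gbest position), `value` (gbest
#'   fitness), `history` (gbest fitness after initialisation and after
#'   each iteration; non-increasing), `iterations`, `swarm` (final
#'   positions/velocities/pbests).
#' @export
pso_minimize <- function(fitness, dim, config = pso_config()) {
  stopifnot(is.function(fitness), dim >= 1L)
  set.seed(config$seed)
  N <- config$swarm_size
  lo <- config$position_bounds[1]; hi <- config$position_bounds[2]
  vc <- config$velocity_clamp
  X <- matrix(stats::runif(N * dim, lo, hi), N, dim)
  V <- matrix(stats::runif(N * dim, -vc, vc), N, dim)
  fit <- apply(X, 1, fitness)
  if (any(!is.finite(fit)))
    stop("non-finite fitness at initialisation")
  P <- X                       # pbest positions
  pfit <- fit                  # pbest fitnesses
  g <- which.min(pfit)
  gbest <- P[g, ]; gfit <- pfit[g]
  history <- gfit
  iters_done <- 0L
  if (config$max_iterations > 0L && gfit > config$fitness_tolerance) {
    for (it in seq_len(config$max_iterations)) {
      w <- config$inertia[1] +
        (config$inertia[2] - config$inertia[1]) *
        (it - 1) / max(config$max_iterations - 1, 1)
      r1 <- matrix(stats::runif(N * dim), N, dim)
      r2 <- matrix(stats::runif(N * dim), N, dim)
      V <- w * V + config$c1 * r1 * (P - X) +
        config$c2 * r2 * (matrix(gbest, N, dim, byrow = TRUE) - X)
      V <- pmin(pmax(V, -vc), vc)
      X <- pmin(pmax(X + V, lo), hi)
      fit <- apply(X, 1, fitness)
      better <- is.finite(fit) & fit < pfit
      P[better, ] <- X[better, , drop = FALSE]
      pfit[better] <- fit[better]
      g <- which.min(pfit)
      if (pfit[g] < gfit) { gfit <- pfit[g]; gbest <- P[g, ] }
      history <- c(history, gfit)
      iters_done <- it
      if (gfit <= config$fitness_tolerance) break
    }
  }
  structure(list(par = gbest, value = gfit, history = history,
                 iterations = iters_done,
                 swarm = list(positions = X, velocities = V,
                              pbest = P, pbest_fitness = pfit)),
            class = "agb_pso")
}

#' Train the network by particle swarm optimisation
#'
#' Each particle encodes the flattened network weight vector; the fitness
#' is the training-set MSE on the normalised scale.  After the swarm
#' search, the global best is (by default) fine-tuned by the
#' Levenberg-Marquardt trainer, which also provides validation-based early
#' stopping; with `fine_tune = FALSE` the gbest weights are returned
#' directly.
#'
#' @param X,y Training data (all rows, indexed by `split`).
#' @param mlp_cfg An [mlp_config()] (hidden size, LM settings for the
#'   fine-tune stage).
#' @param pso_cfg An [pso_config()]; `position_bounds` bound the weights.
#' @param split Optional [split_dataset()] result.
#' @param fine_tune Run LM fine-tuning from the swarm optimum (default
#'   `TRUE`).
#' @return An `agb_mlp` (see [train_mlp_lm()]) whose `pso` element holds
#'   the swarm history.
#' @export
pso_train_mlp <- function(X, y, mlp_cfg = mlp_config(),
                          pso_cfg = pso_config(), split = NULL,
                          fine_tune = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X); h <- mlp_cfg$hidden_size
  tr <- if (is.null(split)) seq_len(nrow(X)) else split$train
  x_lo <- apply(X[tr, , drop = FALSE], 2, min)
  x_hi <- apply(X[tr, , drop = FALSE], 2, max)
  y_lo <- min(y[tr]); y_hi <- max(y[tr])
  y_span <- if (y_hi > y_lo) y_hi - y_lo else 1
  Xtr <- minmax_norm(X[tr, , drop = FALSE], x_lo, x_hi)
  ytr <- (y[tr] - y_lo) / y_span * 2 - 1
  fitness <- function(theta)
    mean((ytr - mlp_forward(theta, Xtr, p, h)$yhat)^2)
  sw <- pso_minimize(fitness, dim = mlp_n_params(p, h), config = pso_cfg)
  if (fine_tune) {
    cfg <- mlp_cfg
    fit <- train_mlp_lm(X, y, cfg, split, init_theta = sw$par)
  } else {
    fit <- structure(list(
      weights = mlp_unflatten(sw$par, p, h),
      theta = sw$par,
      norm = list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
      config = mlp_cfg,
      feature_names = colnames(X),
      history = data.frame(epoch = integer(0), lambda = numeric(0),
                           mse_train = numeric(0), mse_val = numeric(0)),
      best_epoch = 0L,
      stop_reason = "pso_only"), class = "agb_mlp")
  }
  fit$pso <- list(history = sw$history, value = sw$value,
                  iterations = sw$iterations)
  fit
}
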
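#' Linear biomass model specification
#'
#' A frozen linear predictor: intercept plus named coefficients over the
#' feature catalogue (plus terrain names).  Optional per-term statistics
#' (standard error, standardised coefficient, t, p) are carried as metadata.
#'
#' @param intercept Intercept.
#' @param coefficients Named numeric vector of slopes.
#' @param stats Optional data frame of per-term statistics.
#' @param label Optional model label.
#' @return Object of class `agb_linear_model`.
#' @export
linear_model_spec <- function(intercept, coefficients, stats = NULL,
                              label = "linear") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 stats = stats, label = label),
            class = "agb_linear_model")
}

#' @export
print.agb_linear_model <- function(x, ...) {
  cat(sprintf("Linear AGB model '%s': intercept %.4g + %d term(s)\n",
              x$label, x$intercept, length(x$coefficients)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' The published stepwise-regression biomass model
#'
#' The eight-term linear inversion model reported for the 162-plot study
#' data, frozen exactly as printed (the source data are confidential and the
#' model cannot be refit):
#' `Biomass = -243.422 + 0.090 Altitude + 125.943 CanopyClosure
#'  - 156.917 ARVI + 73.454 EVI + 148.340 RVI + 34.447 VVEntropy
#'  + 24.306 B6Mean - 245.049 B6`.
#' Per-term standard errors, standardised coefficients, t and p values are
#' attached as metadata.
#'
#' @return An [linear_model_spec()] of class `agb_linear_model`.
#' @export
published_model <- function() {
  coefs <- c(Altitude = 0.090, CanopyClosure = 125.943, ARVI = -156.917,
             EVI = 73.454, RVI = 148.340, VVEntropy = 34.447,
             B6Mean = 24.306, B6 = -245.049)
  stats <- data.frame(
    term = c("(Intercept)", names(coefs)),
    estimate = c(-243.422, unname(coefs)),
    std_error = c(126.015, 0.025, 33.185, 64.266, 35.773, 43.052, 18.391,
                  13.932, 93.419),
    std_coef = c(NA, 0.276, 0.267, -0.472, 0.236, 0.676, 0.127, 0.417,
                 -0.656),
    t = c(-1.932, 3.533, 3.795, -2.442, 2.053, 3.446, 1.873, 1.745, -2.623),
    p = c(0.055, 0.001, 0.000, 0.016, 0.042, 0.001, 0.063, 0.083, 0.010))
  linear_model_spec(-243.422, coefs, stats = stats, label = "published")
}

#' Evaluate a linear model specification
#'
#' `intercept + sum coef_i * x_i` per row.  Every coefficient's feature must
#' be present; a missing feature is an error naming it.
#'
#' @param spec An `agb_linear_model`.
#' @param features Data frame (or named vector for a single observation).
#' @return Numeric vector of predictions.
#' @export
predict_linear <- function(spec, features) {
  stopifnot(inherits(spec, "agb_linear_model"))
  if (!is.data.frame(features))
    features <- as.data.frame(as.list(features))
  miss <- setdiff(names(spec$coefficients), names(features))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(features[, names(spec$coefficients), drop = FALSE])
  as.numeric(spec$intercept + x %*% spec$coefficients)
}

#' @export
predict.agb_linear_model <- function(object, newdata, ...) {
  predict_linear(object, newdata)
}

#' Stepwise linear regression (p-value entry/removal)
#'
#' Iterative forward entry of the candidate with the smallest F-test
#' p-value below `entry_p`, followed by backward removal of any term whose
#' p-value exceeds `removal_p`, until the model is stable.  This is the
#' classic bidirectional stepwise procedure with the usual 0.05/0.10
#' defaults.  The ordinary-least-squares sub-fits use [stats::lm()].
#'
#' @param X Data frame or matrix of candidate predictors (no constant
#'   columns).
#' @param y Response vector.
#' @param entry_p Entry threshold (default 0.05).
#' @param removal_p Removal threshold (default 0.10), must be `>= entry_p`
#'   to guarantee termination.
#' @param max_steps Safety cap on entry/removal cycles.
#' @return List of class `agb_stepwise_fit`: `spec` (an
#'   `agb_linear_model`), `fit` (the final `lm`), `report` (R-squared,
#'   adjusted R-squared, overall F-test p, per-term table) and `trace`
#'   (entry/removal log).
#' @export
stepwise_fit <- function(X, y, entry_p = 0.05, removal_p = 0.10,
                         max_steps = 100L) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), entry_p <= removal_p)
  const <- vapply(X, function(c) stats::sd(c) == 0, logical(1))
  if (any(const))
    stop("constant column(s): ", paste(names(X)[const], collapse = ", "))
  dat <- data.frame(.y = y, X, check.names = FALSE)
  current <- character(0)
  trace <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    candidates <- setdiff(names(X), current)
    if (length(candidates)) {
      fit0 <- stats::lm(make_formula(current), data = dat)
      add <- stats::add1(fit0,
                         scope = make_formula(c(current, candidates),
                                              rhs_only = TRUE),
                         test = "F")
      pv <- add[["Pr(>F)"]][-1]
      names(pv) <- strip_bt(rownames(add)[-1])
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) < entry_p) {
        enter <- names(pv)[which.min(pv)]
        current <- c(current, enter)
        trace <- c(trace, paste0("+", enter, " (p=", signif(min(pv), 3), ")"))
        changed <- TRUE
      }
    }
    if (length(current)) {
      fit1 <- stats::lm(make_formula(current), data = dat)
      dr <- stats::drop1(fit1, test = "F")
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- strip_bt(rownames(dr)[-1])
      pv <- pv[!is.na(pv)]
      if (length(pv) && max(pv) > removal_p) {
        leave <- names(pv)[which.max(pv)]
        current <- setdiff(current, leave)
        trace <- c(trace, paste0("-", leave, " (p=", signif(max(pv), 3), ")"))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (step == max_steps)
      stop("stepwise selection did not stabilise; trace:\n",
           paste(trace, collapse = "\n"))
  }
  fit <- stats::lm(make_formula(current), data = dat)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  spec <- linear_model_spec(
    intercept = unname(cf[1]),
    coefficients = if (length(cf) > 1)
      stats::setNames(unname(cf[-1]), strip_bt(names(cf)[-1])) else
      stats::setNames(numeric(0), character(0))[0],
    label = "stepwise")
  fp <- if (length(current)) {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_
  report <- list(r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_p = unname(fp),
                 terms = data.frame(term = strip_bt(rownames(sm$coefficients)),
                                    sm$coefficients, check.names = FALSE))
  structure(list(spec = spec, fit = fit, report = report, trace = trace),
            class = "agb_stepwise_fit")
}

make_formula <- function(terms, rhs_only = FALSE, env = parent.frame()) {
  rhs <- if (length(terms))
    paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  stats::as.formula(paste(if (rhs_only) "~" else ".y ~", rhs), env = env)
}

strip_bt <- function(x) gsub("`", "", x)

#' Serialize / restore a linear model specification as JSON
#'
#' @param spec An `agb_linear_model`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_model_spec()` returns the restored spec.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "agb_linear_model"))
  jsonlite::write_json(
    list(label = spec$label, intercept = spec$intercept,
         coefficients = as.list(spec$coefficients)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model_spec(j$intercept, unlist(j$coefficients), label = j$label)
}
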
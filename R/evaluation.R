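#' R-squared of predictions against observations
#'
#' Two variants are computed because the two are often conflated in
#' inversion studies: `"corr"` is the squared Pearson correlation of
#' predictions and observations (invariant to any affine transform of the
#' predictions), while `"cod"` is the coefficient of determination
#' `1 - SS_res / SS_tot` (penalising bias and scale error).
#'
#' @param pred,obs Numeric vectors, length >= 3; `obs` needs non-zero
#'   variance.
#' @param variant `"both"` (default, named vector), `"corr"` or `"cod"`.
#' @return Named numeric vector (`corr`, `cod`) or a single value.
#' @export
r_squared <- function(pred, obs, variant = c("both", "corr", "cod")) {
  variant <- match.arg(variant)
  stopifnot(length(pred) == length(obs), length(obs) >= 3L)
  if (stats::sd(obs) == 0) {
    warning("zero variance in observations: R-squared undefined")
    return(if (variant == "both") c(corr = NA_real_, cod = NA_real_)
           else NA_real_)
  }
  corr <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, obs)^2
  cod <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  switch(variant,
         both = c(corr = corr, cod = cod),
         corr = corr,
         cod = cod)
}

#' Signed relative errors in percent
#'
#' `100 * (pred - obs) / obs` per element.  Zero observations give `NA`;
#' their positions are recorded in the `"flagged"` attribute.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Numeric vector of percentages with attribute `"flagged"`.
#' @export
relative_errors <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  bad <- obs == 0
  out <- 100 * (pred - obs) / obs
  out[bad] <- NA_real_
  attr(out, "flagged") <- which(bad)
  out
}

#' Mean absolute relative error after discarding gross outliers
#'
#' Entries with `|relative error| > threshold` (percent) are treated as
#' outliers and discarded; the mean of the absolute values of the
#' remainder is returned.
#'
#' @param rel_errors Vector of signed relative errors in percent
#'   (`NA` entries are dropped first).
#' @param threshold Discard threshold in percent (default 100;
#'   `Inf` disables discarding).
#' @return List: `mean_deviation` (percent, `NA` with a warning if nothing
#'   survives), `n_discarded`.
#' @export
mean_deviation_after_discard <- function(rel_errors, threshold = 100) {
  rel <- rel_errors[!is.na(rel_errors)]
  if (!length(rel)) stop("no usable relative errors")
  keep <- abs(rel) <= threshold
  n_disc <- sum(!keep)
  if (!any(keep)) {
    warning("every entry exceeded the discard threshold")
    return(list(mean_deviation = NA_real_, n_discarded = n_disc))
  }
  list(mean_deviation = mean(abs(rel[keep])), n_discarded = n_disc)
}

#' Compare fitted models on a common test set
#'
#' Evaluates every model on identical held-out data and tabulates both
#' R-squared variants, the extreme signed relative errors, the number of
#' predictions discarded by the `|relative error| > threshold` rule and
#' the mean absolute deviation of the remainder.
#'
#' @param models Named list; each element is either an object with a
#'   `predict` method (`agb_linear_model`, `agb_mlp`, `lm`, ...) or a
#'   function `X -> predictions`.
#' @param X_test Test predictors (data frame or matrix).
#' @param y_test Observed test response.
#' @param threshold Relative-error discard threshold in percent.
#' @return Data frame with one row per model: `model`, `r2_corr`,
#'   `r2_cod`, `max_rel_err`, `min_rel_err`, `n_discarded`,
#'   `mean_deviation`.  Attribute `"scatter"` holds per-model
#'   predicted/observed pairs for plotting.
#' @export
compare_models <- function(models, X_test, y_test, threshold = 100) {
  stopifnot(is.list(models), length(models) >= 1L,
            !is.null(names(models)), all(nzchar(names(models))))
  scatter <- list()
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    pred <- if (is.function(m)) m(X_test) else predict(m, X_test)
    pred <- as.numeric(pred)
    if (length(pred) != length(y_test))
      stop("model '", nm, "' returned ", length(pred),
           " predictions for ", length(y_test), " test observations")
    scatter[[nm]] <<- data.frame(model = nm, observed = y_test,
                                 predicted = pred)
    r2 <- r_squared(pred, y_test)
    rel <- relative_errors(pred, y_test)
    md <- mean_deviation_after_discard(rel, threshold)
    data.frame(model = nm, r2_corr = r2[["corr"]], r2_cod = r2[["cod"]],
               max_rel_err = max(rel, na.rm = TRUE),
               min_rel_err = min(rel, na.rm = TRUE),
               n_discarded = md$n_discarded,
               mean_deviation = md$mean_deviation)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scatter") <- do.call(rbind, scatter)
  out
}
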
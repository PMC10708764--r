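#' Remove biomass outliers from a plot table
#'
#' Flags plots whose biomass falls outside `mean +/- k * SD`.  Because a
#' single pass of a 3-SD rule can never remove more than about a ninth of
#' the data (the outliers themselves inflate the standard deviation), the
#' rule is iterated by default: mean and SD are recomputed on the retained
#' set until no further plot is removed.  Every removal is logged with the
#' iteration number and the bounds that triggered it.
#'
#' @param plots Data frame with the biomass column; at least 3 rows.
#' @param value Name of the biomass column (default `"agb"`).
#' @param k SD multiplier (default 3).
#' @param iterate Recompute the rule on the retained set until stable
#'   (default `TRUE`); `FALSE` gives the single-pass rule.
#' @param max_iter Safety cap on iterations.
#' @return List of class `agb_outlier_filter`: `retained` (filtered data
#'   frame), `removed` (data frame of removed rows with `iteration`,
#'   `lower`, `upper`), `rule` (description).
#' @export
remove_outliers <- function(plots, value = "agb", k = 3, iterate = TRUE,
                            max_iter = 100L) {
  stopifnot(is.data.frame(plots), value %in% names(plots))
  if (nrow(plots) < 3L) stop("need at least 3 plots")
  keep <- rep(TRUE, nrow(plots))
  removed <- list()
  for (it in seq_len(if (iterate) max_iter else 1L)) {
    x <- plots[[value]][keep]
    mu <- mean(x); sdv <- stats::sd(x)
    lo <- mu - k * sdv; hi <- mu + k * sdv
    out <- keep & (plots[[value]] < lo | plots[[value]] > hi)
    if (!any(out)) break
    rm_df <- plots[out, , drop = FALSE]
    rm_df$iteration <- it; rm_df$lower <- lo; rm_df$upper <- hi
    removed[[it]] <- rm_df
    keep <- keep & !out
    if (sum(keep) < 3L) break
  }
  if (!any(keep)) stop("outlier rule removed every plot")
  structure(list(
    retained = plots[keep, , drop = FALSE],
    removed = if (length(removed)) do.call(rbind, removed) else
      plots[0, , drop = FALSE],
    rule = sprintf("%smean +/- %g*SD on '%s'",
                   if (iterate) "iterated " else "", k, value)),
    class = "agb_outlier_filter")
}

#' @export
print.agb_outlier_filter <- function(x, ...) {
  cat(sprintf("Outlier filter (%s): retained %d, removed %d\n",
              x$rule, nrow(x$retained), nrow(x$removed)))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / (sqrt(sum((x - mean(x))^2)) *
#' sqrt(sum((y - mean(y))^2)))`.  Undefined (zero-variance) input yields
#' `NA` with a warning rather than an arbitrary value.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined, reported as NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t-transform `t = r sqrt((n - 2) / (1 - r^2))` against the
#' t distribution with `n - 2` degrees of freedom.  `|r| = 1` returns 0 by
#' convention.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value in `[0, 1]`.
#' @export
pearson_p <- function(r, n) {
  stopifnot(n >= 3L)
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Correlate every catalogue feature with plot biomass
#'
#' @param features Data frame of predictor columns (a `plot_id` column is
#'   ignored if present).
#' @param biomass Numeric vector, one value per feature row.
#' @return Data frame of class `agb_cor_table` with columns `feature`, `r`,
#'   `p`, `n`, `tier` (`"none"`, `"p<0.05"` or `"p<0.01"`); attribute
#'   `"n_tests"` records the number of correlations computed (no
#'   multiple-testing correction is applied).
#' @export
correlation_screen <- function(features, biomass) {
  stopifnot(is.data.frame(features), nrow(features) == length(biomass))
  feats <- features[, setdiff(names(features), "plot_id"), drop = FALSE]
  n <- length(biomass)
  res <- lapply(names(feats), function(nm) {
    x <- feats[[nm]]
    r <- if (stats::sd(x) == 0 || stats::sd(biomass) == 0) NA_real_ else
      stats::cor(x, biomass)
    p <- pearson_p(r, n)
    data.frame(feature = nm, r = r, p = p, n = n,
               tier = if (is.na(p)) "none" else if (p < 0.01) "p<0.01"
                      else if (p < 0.05) "p<0.05" else "none")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_tests") <- ncol(feats)
  class(out) <- c("agb_cor_table", "data.frame")
  out
}

#' Select significant predictors from a correlation table
#'
#' Features with `p < alpha`, ordered by decreasing `|r|`.
#'
#' @param table An [correlation_screen()] result.
#' @param alpha Significance threshold (default 0.01, the strong tier).
#' @return Character vector of feature names (possibly empty, with a
#'   warning).
#' @export
select_predictors <- function(table, alpha = 0.01) {
  stopifnot(inherits(table, "agb_cor_table"))
  sel <- table[!is.na(table$p) & table$p < alpha, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no feature passes p < ", alpha)
    return(character(0))
  }
  sel$feature[order(-abs(sel$r))]
}
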
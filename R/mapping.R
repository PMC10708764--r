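#' Apply a fitted biomass model pixelwise to a raster stack
#'
#' Computes, for every raster cell, the catalogue features the model needs
#' (texture measures use the same window size and grey-level count as at
#' training time) and evaluates the model's point predictor; the result is
#' a single-band biomass surface carrying the input georeferencing.
#' Cells whose texture window runs off the edge, or with missing band
#' values, propagate to nodata (`NA`).  Negative predictions are written
#' as-is; their count is reported in the `"n_negative"` attribute.
#'
#' @param model An `agb_linear_model`, `agb_mlp`, or any object with a
#'   `predict(object, newdata)` method over named features.
#' @param stack An [raster_stack()] with bands `b2..b7`, `vv`, `vh`,
#'   `altitude`, `slope`, `canopy_closure`.
#' @param window_size,levels Texture parameters; must match training.
#' @param features Features to compute; defaults to the model's own
#'   requirement (coefficient names or stored training features).
#' @param batch_rows Rows of the raster processed per batch; batching is
#'   an implementation detail and the output is identical for any value.
#' @return An [raster_stack()] with a single band `agb`.
#' @export
invert_raster <- function(model, stack, window_size = 7L, levels = 64L,
                          features = NULL, batch_rows = 8L) {
  stopifnot(inherits(stack, "agb_raster"))
  if (is.null(features)) {
    features <- if (inherits(model, "agb_linear_model"))
      names(model$coefficients)
    else if (inherits(model, "agb_mlp")) model$feature_names
    else catalogue_names()
  }
  unknown <- setdiff(features, catalogue_names())
  if (length(unknown))
    stop("model requires non-catalogue feature(s): ",
         paste(unknown, collapse = ", "))
  d <- dim(stack$values)
  out <- matrix(NA_real_, d[1], d[2])
  row_starts <- seq(1L, d[1], by = batch_rows)
  for (r0 in row_starts) {
    r1 <- min(r0 + batch_rows - 1L, d[1])
    cells <- expand.grid(row = r0:r1, col = seq_len(d[2]))
    pc <- pixel_catalogue(stack, window_size = window_size, levels = levels,
                          features = features, cells = cells)
    ok <- stats::complete.cases(pc$features)
    if (any(ok)) {
      newdata <- as.data.frame(pc$features[ok, , drop = FALSE])
      pred <- as.numeric(predict(model, newdata))
      out[cbind(cells$row[ok], cells$col[ok])] <- pred
    }
  }
  res <- raster_stack(out, bands = "agb", xmin = stack$xmin,
                      ymax = stack$ymax, res = stack$res, crs = stack$crs)
  n_neg <- sum(res$values < 0, na.rm = TRUE)
  if (n_neg > 0)
    warning(n_neg, " cell(s) received negative biomass predictions")
  attr(res, "n_negative") <- n_neg
  res
}
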
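#' Canonical names of the 86-variable predictor catalogue
#'
#' Six optical bands, seven vegetation indices, 48 optical texture measures
#' (8 per band), two SAR backscatter channels, 20 SAR texture measures
#' (10 per polarisation) and three terrain/canopy variables:
#' `6 + 7 + 48 + 2 + 20 + 3 = 86`.
#'
#' @return Character vector of 86 unique feature names, in catalogue order.
#' @export
catalogue_names <- function() {
  opt_bands <- paste0("B", 2:7)
  idx <- c("ARVI", "DVI", "EVI", "NDPI", "NDVI", "RVI", "SAVI")
  opt_tex <- as.vector(t(outer(opt_bands, optical_measure_names(), paste0)))
  sar <- c("VH", "VV")
  sar_tex <- as.vector(t(outer(sar, sar_measure_names(), paste0)))
  c(opt_bands, idx, opt_tex, sar, sar_tex,
    "Altitude", "Slope", "CanopyClosure")
}

# map raster band name -> catalogue base name
.band_alias <- c(b2 = "B2", b3 = "B3", b4 = "B4", b5 = "B5", b6 = "B6",
                 b7 = "B7", vh = "VH", vv = "VV")

# Extract the full 86-entry feature vector for one cell of a pre-quantized
# band list.  Returns NULL when the texture window does not fit.
cell_features <- function(stack, qbands, row, col, half, levels,
                          soil_L = 0.5, evi_standard = FALSE,
                          arvi_standard = FALSE) {
  d <- dim(stack$values)
  if (row - half < 1 || row + half > d[1] || col - half < 1 ||
      col + half > d[2])
    return(NULL)
  v <- stack$values[row, col, ]
  if (anyNA(v)) return(NULL)
  out <- numeric(0)
  opt <- paste0("b", 2:7)
  out <- c(out, stats::setNames(v[opt], paste0("B", 2:7)))
  vi <- vegetation_indices(as.list(v[opt]), soil_L = soil_L,
                           evi_standard = evi_standard,
                           arvi_standard = arvi_standard)
  out <- c(out, stats::setNames(
    as.numeric(vi[1, c("arvi", "dvi", "evi", "ndpi", "ndvi", "rvi", "savi")]),
    c("ARVI", "DVI", "EVI", "NDPI", "NDVI", "RVI", "SAVI")))
  rr <- (row - half):(row + half)
  cc <- (col - half):(col + half)
  for (bn in opt) {
    g <- glcm_from_window(qbands[[bn]][rr, cc, drop = FALSE], levels = levels)
    tm <- texture_measures(g)
    out <- c(out, stats::setNames(
      tm[measure_key[optical_measure_names()]],
      paste0(.band_alias[bn], optical_measure_names())))
  }
  out <- c(out, c(VH = unname(v["vh"]), VV = unname(v["vv"])))
  for (bn in c("vh", "vv")) {
    g <- glcm_from_window(qbands[[bn]][rr, cc, drop = FALSE], levels = levels)
    tm <- texture_measures(g)
    out <- c(out, stats::setNames(
      tm[measure_key[sar_measure_names()]],
      paste0(.band_alias[bn], sar_measure_names())))
  }
  out <- c(out, c(Altitude = unname(v["altitude"]),
                  Slope = unname(v["slope"]),
                  CanopyClosure = unname(v["canopy_closure"])))
  out[catalogue_names()]
}

quantize_bands <- function(stack, levels) {
  qb <- list()
  for (bn in c(paste0("b", 2:7), "vh", "vv"))
    qb[[bn]] <- quantize_image(get_band(stack, bn), levels = levels)
  qb
}

#' Assemble the 86-variable feature catalogue for plots
#'
#' For every plot cell, extracts band reflectance, vegetation indices,
#' grey-level co-occurrence texture measures (optical bands on quantized
#' reflectance, SAR channels on quantized dB backscatter, all quantized
#' over the raster-wide range), backscatter and terrain variables.  Plots
#' whose texture window runs off the raster edge are excluded and listed in
#' the `"excluded"` attribute.
#'
#' @param plots Plot table (needs `plot_id`); only used for ids.
#' @param stack An [raster_stack()] with bands
#'   `b2..b7`, `vv`, `vh`, `altitude`, `slope`, `canopy_closure`.
#' @param plot_pixels Data frame `plot_id`, `row`, `col` mapping plots to
#'   raster cells.
#' @param window_size Odd texture window size (default 7).
#' @param levels Grey levels for texture quantisation (default 64).
#' @param soil_L,evi_standard,arvi_standard Passed to
#'   [vegetation_indices()].
#' @return Data frame with `plot_id` plus the 86 [catalogue_names()]
#'   columns; attribute `"excluded"` holds ids of skipped plots.
#' @export
assemble_catalogue <- function(plots, stack, plot_pixels, window_size = 7L,
                               levels = 64L, soil_L = 0.5,
                               evi_standard = FALSE, arvi_standard = FALSE) {
  stopifnot(inherits(stack, "agb_raster"), window_size %% 2L == 1L)
  half <- window_size %/% 2L
  qb <- quantize_bands(stack, levels)
  n <- nrow(plot_pixels)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    fv <- cell_features(stack, qb, plot_pixels$row[i], plot_pixels$col[i],
                        half, levels, soil_L, evi_standard, arvi_standard)
    if (is.null(fv)) {
      excluded <- c(excluded, plot_pixels$plot_id[i])
      next
    }
    rows[[i]] <- fv
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  out <- data.frame(plot_id = plot_pixels$plot_id[keep], mat,
                    check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-cell feature catalogue of a whole raster
#'
#' Computes the same 86-variable catalogue as [assemble_catalogue()] for
#' every raster cell with a complete texture window and no missing band
#' values; used by pixelwise model application.
#'
#' @inheritParams assemble_catalogue
#' @param features Optional character subset of [catalogue_names()] to
#'   return (all 86 by default).
#' @param cells Optional data frame `row`, `col` restricting computation.
#' @return List with `cells` (data frame `row`, `col`) and `features`
#'   (numeric matrix, one row per cell, `NA` rows for cells that could not
#'   be evaluated).
#' @export
pixel_catalogue <- function(stack, window_size = 7L, levels = 64L,
                            features = catalogue_names(), cells = NULL,
                            soil_L = 0.5, evi_standard = FALSE,
                            arvi_standard = FALSE) {
  stopifnot(inherits(stack, "agb_raster"), window_size %% 2L == 1L)
  half <- window_size %/% 2L
  d <- dim(stack$values)
  if (is.null(cells))
    cells <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  qb <- quantize_bands(stack, levels)
  mat <- matrix(NA_real_, nrow(cells), length(features),
                dimnames = list(NULL, features))
  for (i in seq_len(nrow(cells))) {
    fv <- cell_features(stack, qb, cells$row[i], cells$col[i], half, levels,
                        soil_L, evi_standard, arvi_standard)
    if (!is.null(fv)) mat[i, ] <- fv[features]
  }
  list(cells = cells, features = mat)
}
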
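#' In-memory multi-band raster stack
#'
#' A light-weight georeferenced raster container used throughout the
#' package: a `rows x cols x bands` numeric array plus band names, an affine
#' geotransform (`xmin`, `ymax`, cell size) and a free-form CRS identifier.
#' `NA` encodes nodata.
#'
#' @param values Numeric array with `dim = c(rows, cols, n_bands)`, or a
#'   matrix for a single band.
#' @param bands Character vector of band names, one per layer.
#' @param xmin,ymax Coordinates of the outer corner of the top-left cell.
#' @param res Cell size (square cells) in CRS units.
#' @param crs Coordinate reference identifier (free-form string).
#' @return An object of class `agb_raster`.
#' @export
raster_stack <- function(values, bands, xmin = 0, ymax = 0, res = 30,
                         crs = "local") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (missing(bands)) bands <- paste0("band", seq_len(dim(values)[3]))
  stopifnot(length(bands) == dim(values)[3], !anyDuplicated(bands))
  dimnames(values) <- list(NULL, NULL, bands)
  structure(list(values = values, bands = bands,
                 xmin = xmin, ymax = ymax, res = res, crs = crs),
            class = "agb_raster")
}

#' @export
print.agb_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("agb_raster: %d x %d cells, %d band(s) [%s]\n", d[1], d[2], d[3],
              paste(x$bands, collapse = ", ")))
  cat(sprintf("  origin (%g, %g), res %g, crs '%s', %d NA cell-values\n",
              x$xmin, x$ymax, x$res, x$crs, sum(is.na(x$values))))
  invisible(x)
}

#' Extract one band of a raster stack as a matrix
#'
#' @param stack An [raster_stack()] object.
#' @param band Band name.
#' @return Numeric matrix.
#' @export
get_band <- function(stack, band) {
  stopifnot(inherits(stack, "agb_raster"))
  if (!band %in% stack$bands) stop("no such band: ", band)
  stack$values[, , band]
}

#' Write a raster stack to disk
#'
#' Rasters are stored as multi-page 32-bit TIFF plus a JSON sidecar
#' (`<path>.json`).  The TIFF holds, per band, a value page rescaled to
#' `[0, 1]` followed by a validity-mask page; the sidecar records the band
#' names, per-band scale/offset, geotransform and CRS so that
#' [read_raster_stack()] restores the original values (to 32-bit float
#' precision) and `NA` cells exactly.
#'
#' @param stack An [raster_stack()] object.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_raster_stack <- function(stack, path) {
  stopifnot(inherits(stack, "agb_raster"))
  nb <- length(stack$bands)
  pages <- vector("list", 2L * nb)
  scales <- numeric(nb); offsets <- numeric(nb)
  for (k in seq_len(nb)) {
    v <- stack$values[, , k]
    finite <- v[is.finite(v)]
    lo <- if (length(finite)) min(finite) else 0
    hi <- if (length(finite)) max(finite) else 0
    sc <- hi - lo
    if (sc == 0) sc <- 1
    offsets[k] <- lo; scales[k] <- sc
    scaled <- (v - lo) / sc
    mask <- ifelse(is.finite(v), 1, 0)
    scaled[!is.finite(scaled)] <- 0
    pages[[2L * k - 1L]] <- scaled
    pages[[2L * k]] <- mask
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(bands = stack$bands, scale = scales, offset = offsets,
               xmin = stack$xmin, ymax = stack$ymax, res = stack$res,
               crs = stack$crs, rows = dim(stack$values)[1],
               cols = dim(stack$values)[2])
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster stack written by [write_raster_stack()]
#'
#' @param path Path to the TIFF file (the `<path>.json` sidecar must exist).
#' @return An [raster_stack()] object.
#' @export
read_raster_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("raster sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- length(meta$bands)
  stopifnot(length(pages) == 2L * nb)
  vals <- array(NA_real_, dim = c(meta$rows, meta$cols, nb))
  for (k in seq_len(nb)) {
    v <- pages[[2L * k - 1L]] * meta$scale[k] + meta$offset[k]
    v[pages[[2L * k]] < 0.5] <- NA_real_
    vals[, , k] <- v
  }
  raster_stack(vals, bands = meta$bands, xmin = meta$xmin, ymax = meta$ymax,
               res = meta$res, crs = meta$crs)
}
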
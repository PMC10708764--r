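#' Vegetation indices from band reflectance
#'
#' Computes the seven candidate indices (NDVI, SAVI, DVI, RVI, ARVI, EVI,
#' NDPI) from a table of band reflectances.  Band roles follow the
#' Landsat 8 OLI convention: BLUE = b2, RED = b4, NIR = b5, SWIR1 = b6.
#'
#' Two indices are implemented, by default, exactly as printed in the source
#' regression workflow rather than in their textbook form:
#' \itemize{
#'   \item `EVI = 2.5 (NIR - RED) / (NIR + 6 RED - 7 BLUE + 1)` — coefficient
#'     7 on BLUE; set `evi_standard = TRUE` for the conventional 7.5.
#'   \item `ARVI = (NIR - 2 RED - BLUE) / (NIR + 2 RED - BLUE)` — BLUE enters
#'     the numerator with a minus sign; set `arvi_standard = TRUE` for the
#'     conventional `NIR - (2 RED - BLUE)` numerator.
#' }
#' `NDPI = (NIR - (0.74 RED + 0.26 SWIR)) / (NIR + (0.74 RED + 0.26 SWIR))`.
#'
#' Zero denominators yield `NA` for the affected index; the offending rows
#' and index names are recorded in the `"flagged"` attribute rather than
#' silently coerced to zero.
#'
#' @param sample Data frame (or named list) with numeric columns
#'   `b2`, `b4`, `b5`, `b6` at least; extra columns are ignored.
#' @param soil_L Soil-adjustment coefficient for SAVI (default 0.5).
#' @param evi_standard,arvi_standard Use the conventional instead of the
#'   printed coefficient form (see Details).
#' @return Data frame with columns `ndvi`, `savi`, `dvi`, `rvi`, `arvi`,
#'   `evi`, `ndpi`; a `"flagged"` attribute lists rows with undefined
#'   denominators.
#' @export
vegetation_indices <- function(sample, soil_L = 0.5,
                               evi_standard = FALSE, arvi_standard = FALSE) {
  sample <- as.data.frame(sample)
  need <- c("b2", "b4", "b5", "b6")
  miss <- setdiff(need, names(sample))
  if (length(miss)) stop("missing band column(s): ", paste(miss, collapse = ", "))
  blue <- sample$b2; red <- sample$b4; nir <- sample$b5; swir <- sample$b6

  safe_div <- function(num, den, idx_name, flags) {
    bad <- is.finite(den) & den == 0
    out <- num / den
    out[bad] <- NA_real_
    if (any(bad))
      flags[[idx_name]] <- which(bad)
    list(value = out, flags = flags)
  }
  flags <- list()

  r <- safe_div(nir - red, nir + red, "ndvi", flags)
  ndvi <- r$value; flags <- r$flags
  r <- safe_div((1 + soil_L) * (nir - red), nir + red + soil_L, "savi", flags)
  savi <- r$value; flags <- r$flags
  dvi <- nir - red
  r <- safe_div(nir, red, "rvi", flags)
  rvi <- r$value; flags <- r$flags
  arvi_num <- if (arvi_standard) nir - (2 * red - blue) else nir - 2 * red - blue
  r <- safe_div(arvi_num, nir + 2 * red - blue, "arvi", flags)
  arvi <- r$value; flags <- r$flags
  blue_coef <- if (evi_standard) 7.5 else 7
  r <- safe_div(2.5 * (nir - red), nir + 6 * red - blue_coef * blue + 1,
                "evi", flags)
  evi <- r$value; flags <- r$flags
  mix <- 0.74 * red + 0.26 * swir
  r <- safe_div(nir - mix, nir + mix, "ndpi", flags)
  ndpi <- r$value; flags <- r$flags

  out <- data.frame(ndvi = ndvi, savi = savi, dvi = dvi, rvi = rvi,
                    arvi = arvi, evi = evi, ndpi = ndpi)
  attr(out, "flagged") <- flags
  out
}
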
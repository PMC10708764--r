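#' Allometric model parameters
#'
#' Parameters of the power-law allometric model `W = a * D^b * H^c` relating
#' per-tree above-ground biomass `W` to diameter at breast height `D` (cm)
#' and tree height `H` (m).  The defaults are the published parameter set for
#' mixed temperate forest (a = 0.0470, b = 2.1181, c = 0.7088).
#'
#' The output unit of `W` is carried as an opaque label (default `"kg"`,
#' the convention of the source allometry); it is metadata only and is never
#' converted.
#'
#' @param a Scale coefficient, must be positive.
#' @param b DBH exponent.
#' @param c Height exponent.
#' @param unit Character label for the biomass unit.
#' @return An object of class `agb_allometry` (a named list).
#' @examples
#' p <- allometry_params()
#' tree_agb(20, 15, p)
#' @export
allometry_params <- function(a = 0.0470, b = 2.1181, c = 0.7088, unit = "kg") {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (a < 0) stop("allometric scale coefficient 'a' must be >= 0")
  structure(list(a = a, b = b, c = c, unit = unit), class = "agb_allometry")
}

#' @export
print.agb_allometry <- function(x, ...) {
  cat(sprintf("Allometric AGB model: W = %.4g * D^%.4g * H^%.4g  [%s]\n",
              x$a, x$b, x$c, x$unit))
  invisible(x)
}

#' Per-tree above-ground biomass
#'
#' Evaluates `W = a * D^b * H^c`.  Vectorised over `dbh` and `height`
#' (recycled to a common length).
#'
#' @param dbh Diameter at breast height in cm; strictly positive.
#' @param height Tree height in m; strictly positive.
#' @param params An [allometry_params()] object.
#' @return Numeric vector of biomass values in `params$unit`.
#' @export
tree_agb <- function(dbh, height, params = allometry_params()) {
  stopifnot(inherits(params, "agb_allometry"))
  if (length(dbh) == 0L || length(height) == 0L)
    return(numeric(0))
  if (any(!is.finite(dbh)) || any(!is.finite(height)))
    stop("dbh and height must be finite")
  if (any(dbh <= 0)) stop("dbh must be strictly positive")
  if (any(height <= 0)) stop("height must be strictly positive")
  params$a * dbh^params$b * height^params$c
}

#' Aggregate tree biomass to plot level
#'
#' Sums per-tree allometric biomass within each plot.  Optionally normalises
#' to per-hectare values when the plot area is known; by default no
#' normalisation is applied (plot area is rarely recorded in inventory
#' extracts).
#'
#' @param trees Data frame with columns `plot_id`, `dbh`, `height` (and
#'   optionally `species`).
#' @param params An [allometry_params()] object.
#' @param area_ha Optional plot area in hectares; when supplied, `agb` is
#'   divided by it (per-hectare biomass).
#' @return Data frame with columns `plot_id`, `agb`, `n_trees`, ordered by
#'   `plot_id`.
#' @export
plot_biomass <- function(trees, params = allometry_params(), area_ha = NULL) {
  check_tree_table(trees)
  if (nrow(trees) == 0L)
    return(data.frame(plot_id = character(0), agb = numeric(0),
                      n_trees = integer(0)))
  w <- tree_agb(trees$dbh, trees$height, params)
  agg <- stats::aggregate(w, by = list(plot_id = trees$plot_id), FUN = sum)
  cnt <- stats::aggregate(w, by = list(plot_id = trees$plot_id), FUN = length)
  out <- data.frame(plot_id = agg$plot_id, agb = agg$x,
                    n_trees = as.integer(cnt$x))
  if (!is.null(area_ha)) {
    stopifnot(is.numeric(area_ha), area_ha > 0)
    out$agb <- out$agb / area_ha
  }
  out[order(out$plot_id), , drop = FALSE]
}

#' Biomass share by species
#'
#' Total allometric biomass per species and its fraction of the overall
#' biomass, sorted in decreasing order of share.
#'
#' @inheritParams plot_biomass
#' @return Data frame with columns `species`, `agb`, `fraction` (fractions
#'   sum to 1), sorted descending by `fraction`.  Empty input gives an empty
#'   table.
#' @export
species_share <- function(trees, params = allometry_params()) {
  check_tree_table(trees, need_species = TRUE)
  if (nrow(trees) == 0L)
    return(data.frame(species = character(0), agb = numeric(0),
                      fraction = numeric(0)))
  w <- tree_agb(trees$dbh, trees$height, params)
  agg <- stats::aggregate(w, by = list(species = trees$species), FUN = sum)
  out <- data.frame(species = agg$species, agb = agg$x,
                    fraction = agg$x / sum(agg$x))
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_tree_table <- function(trees, need_species = FALSE) {
  stopifnot(is.data.frame(trees))
  need <- c("plot_id", "dbh", "height", if (need_species) "species")
  missing <- setdiff(need, names(trees))
  if (length(missing))
    stop("tree table lacks column(s): ", paste(missing, collapse = ", "))
  invisible(trees)
}

#' Read a tree table from CSV
#'
#' Thin wrapper over [utils::read.csv()] that validates the inventory
#' columns (`plot_id`, `species`, `dbh`, `height`).
#'
#' @param path Path to a CSV file.
#' @return Data frame of tree records.
#' @export
read_tree_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_tree_table(df, need_species = TRUE)
  df
}
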
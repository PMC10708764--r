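#' Configuration of the synthetic inventory/raster generator
#'
#' Defines the simulated study conditions: a fixed-plot forest inventory
#' (default 354 plots, emulating a provincial continuous inventory) whose
#' plot biomass is tied to optical reflectance, SAR backscatter and
#' canopy/terrain variables through a known, exported link function, with a
#' configurable fraction of plots carrying corrupted (outlying) biomass.
#'
#' Each plot has a latent site-quality score `s ~ U(-1, 1)`.  Clean plot
#' biomass is `base + span * g(s)` with
#' `g(s) = (s + gamma * tanh(2 s)) / (1 + gamma)` and
#' `gamma = nonlinearity_strength`, so biomass is affine in the generated
#' features when `gamma = 0` and saturating-nonlinear otherwise.  Outlier
#' plots have their biomass inflated multiplicatively by log-uniformly
#' spaced factors `10^seq(lo, hi)` (default decades 1.5 to 5, randomly
#' assigned to the outlier plots), which keeps the corrupted values
#' separated both from the compact support of the clean biomass
#' distribution and from one another, so the iterated outlier screen
#' removes exactly the planted set.
#'
#' @param n_plots Number of plots (default 354).
#' @param trees_per_plot Integer range `c(min, max)` of trees per plot.
#' @param species_mix Data frame with columns `species`, `proportion`
#'   (proportions must sum to 1).
#' @param dbh_range_cm Range of generated diameters at breast height (cm).
#' @param height_link List `alpha`, `beta`, `sdlog`: tree height is
#'   `alpha * DBH^beta * exp(N(0, sdlog))` metres.
#' @param terrain_ranges List of ranges `altitude` (m), `slope` (degrees),
#'   `canopy_closure` (fraction in `[0, 1]`).
#' @param spectral_link List controlling the biomass-feature link: `biomass_base`,
#'   `biomass_span`, per-band `band_base`/`band_slope` (reflectance, bands
#'   b2..b7), `band_noise_sd`, `sar_base`/`sar_slope`/`sar_noise_sd`
#'   (VV/VH backscatter, dB), and `outlier_factor_log10 = c(lo, hi)`.
#' @param outlier_fraction Fraction of plots given corrupted biomass; default
#'   `(354 - 162) / 354` so that outlier screening retains 162 of 354 plots.
#' @param nonlinearity_strength Non-negative scalar `gamma` above.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration.
#' @return An object of class `agb_sim_config`.
#' @export
simulation_config <- function(n_plots = 354L,
                              trees_per_plot = c(8L, 30L),
                              species_mix = default_species_mix(),
                              dbh_range_cm = c(5, 45),
                              height_link = list(alpha = 1.1, beta = 0.7,
                                                 sdlog = 0.08),
                              terrain_ranges = list(
                                altitude = c(50, 1200),
                                slope = c(0, 35),
                                canopy_closure = c(0.2, 0.95)),
                              spectral_link = default_spectral_link(),
                              outlier_fraction = (354 - 162) / 354,
                              nonlinearity_strength = 1,
                              seed = 1L) {
  stopifnot(n_plots >= 3, length(trees_per_plot) == 2L,
            trees_per_plot[1] >= 1, trees_per_plot[2] >= trees_per_plot[1],
            is.data.frame(species_mix),
            all(c("species", "proportion") %in% names(species_mix)),
            length(dbh_range_cm) == 2L, dbh_range_cm[1] > 0,
            nonlinearity_strength >= 0, length(seed) == 1L)
  if (abs(sum(species_mix$proportion) - 1) > 1e-8)
    stop("species proportions must sum to 1")
  if (outlier_fraction < 0 || outlier_fraction >= 0.6)
    stop("outlier_fraction must lie in [0, 0.6)")
  if (dbh_range_cm[2] <= dbh_range_cm[1])
    stop("degenerate dbh range")
  for (nm in c("altitude", "slope", "canopy_closure")) {
    r <- terrain_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[2] <= r[1])
      stop("degenerate terrain range for ", nm)
  }
  if (any(terrain_ranges$canopy_closure < 0) ||
      any(terrain_ranges$canopy_closure > 1))
    stop("canopy_closure range must lie within [0, 1]")
  structure(list(n_plots = as.integer(n_plots),
                 trees_per_plot = as.integer(trees_per_plot),
                 species_mix = species_mix,
                 dbh_range_cm = dbh_range_cm,
                 height_link = height_link,
                 terrain_ranges = terrain_ranges,
                 spectral_link = spectral_link,
                 outlier_fraction = outlier_fraction,
                 nonlinearity_strength = nonlinearity_strength,
                 seed = as.integer(seed)),
            class = "agb_sim_config")
}

#' Default species mixture of the simulated inventory
#'
#' A mixed temperate broadleaf/conifer composition in which the dominant oak
#' contributes about a quarter of the biomass and a long tail of minor
#' species the rest.
#'
#' @return Data frame with columns `species`, `proportion` (summing to 1).
#' @export
default_species_mix <- function() {
  data.frame(
    species = c("Quercus mongolica", "Populus davidiana", "Quercus aliena",
                "Betula platyphylla", "Larix gmelinii",
                "Pinus sylvestris var. mongolica", "Other"),
    proportion = c(0.24, 0.07, 0.05, 0.12, 0.14, 0.13, 0.25))
}

#' Default biomass-feature link parameters
#'
#' Visible and shortwave-infrared reflectance decreases with biomass (denser
#' canopies absorb more), near-infrared reflectance and VV/VH backscatter
#' increase with it; noise is additive Gaussian per band.
#'
#' @return Named list of link parameters (see [simulation_config()]).
#' @export
default_spectral_link <- function() {
  list(biomass_base = 2500, biomass_span = 2000,
       band_base  = c(b2 = 0.10, b3 = 0.12, b4 = 0.09,
                      b5 = 0.35, b6 = 0.18, b7 = 0.12),
       band_slope = c(b2 = -0.040, b3 = -0.030, b4 = -0.035,
                      b5 = 0.100, b6 = -0.050, b7 = -0.040),
       band_noise_sd = 0.008,
       sar_base = c(vv = -11, vh = -17),
       sar_slope = c(vv = 1.5, vh = 2.0),
       sar_noise_sd = 0.6,
       outlier_factor_log10 = c(1.5, 5))
}

#' Latent biomass link function
#'
#' Maps the latent site-quality score `s in [-1, 1]` to clean plot biomass
#' under a configuration.  Exported so parameter-recovery tests can compare
#' fitted models against the generating truth.
#'
#' @param s Numeric vector of site-quality scores.
#' @param config An [simulation_config()] object.
#' @return Numeric vector of latent (clean) plot biomass.
#' @export
biomass_link <- function(s, config) {
  stopifnot(inherits(config, "agb_sim_config"))
  g <- config$nonlinearity_strength
  shape <- (s + g * tanh(2 * s)) / (1 + g)
  config$spectral_link$biomass_base + config$spectral_link$biomass_span * shape
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Band/backscatter values for a vector of site scores (no plot noise when
# noise_sd overrides are zero); returns a data.frame b2..b7, vv, vh.
spectral_from_score <- function(s, link) {
  n <- length(s)
  out <- list()
  for (bn in names(link$band_base)) {
    v <- link$band_base[[bn]] + link$band_slope[[bn]] * s +
      stats::rnorm(n, 0, link$band_noise_sd)
    out[[bn]] <- clamp(v, 0.001, 0.999)
  }
  for (pn in names(link$sar_base)) {
    v <- link$sar_base[[pn]] + link$sar_slope[[pn]] * s +
      stats::rnorm(n, 0, link$sar_noise_sd)
    out[[pn]] <- clamp(v, -30, 0)
  }
  as.data.frame(out)
}

#' Generate a synthetic plot inventory
#'
#' Draws per-plot site-quality scores, plants outliers, generates trees whose
#' allometric biomass sums exactly to each plot's target biomass (tree
#' diameters are rescaled under the power-law height link, which preserves
#' the allometric form), and attaches terrain and per-plot spectral samples.
#'
#' @param config An [simulation_config()] object.
#' @param params Allometric parameters used to make tree and plot tables
#'   consistent (default [allometry_params()]).
#' @return A list of class `agb_inventory` with elements
#'   \describe{
#'     \item{trees}{data frame `plot_id`, `species`, `dbh`, `height`}
#'     \item{plots}{data frame `plot_id`, `longitude`, `latitude`,
#'       `altitude`, `slope`, `canopy_closure`, `b2..b7`, `vv`, `vh`,
#'       `agb`, `n_trees`}
#'     \item{truth}{list: `s` (site scores), `latent_biomass` (clean),
#'       `observed_biomass`, `outlier` (logical flags), `link`
#'       (the score-to-biomass function), `config`}
#'   }
#' @export
generate_inventory <- function(config = simulation_config(),
                               params = allometry_params()) {
  stopifnot(inherits(config, "agb_sim_config"))
  set.seed(config$seed)
  n <- config$n_plots
  lk <- config$spectral_link

  s <- stats::runif(n, -1, 1)
  latent <- biomass_link(s, config)
  n_out <- round(config$outlier_fraction * n)
  outlier <- rep(FALSE, n)
  if (n_out > 0) outlier[sample.int(n, n_out)] <- TRUE
  # corruption factors are log-uniformly *spaced* (stratified) rather than
  # drawn iid, so outlier magnitudes never cluster and the iterated
  # mean +/- 3 SD screen peels every planted outlier
  observed <- latent
  if (n_out > 0) {
    f_log <- seq(lk$outlier_factor_log10[1], lk$outlier_factor_log10[2],
                 length.out = n_out)
    observed[outlier] <- latent[outlier] * 10^f_log[sample.int(n_out)]
  }

  plot_id <- sprintf("P%03d", seq_len(n))
  tr <- config$terrain_ranges
  u_alt <- stats::runif(n); u_cc <- stats::runif(n)
  altitude <- tr$altitude[1] + diff(tr$altitude) *
    clamp(0.5 + 0.25 * s + 0.25 * (2 * u_alt - 1), 0, 1)
  slope <- stats::runif(n, tr$slope[1], tr$slope[2])
  canopy_closure <- tr$canopy_closure[1] + diff(tr$canopy_closure) *
    clamp(0.5 + 0.35 * s + 0.15 * (2 * u_cc - 1), 0, 1)
  spectral <- spectral_from_score(s, lk)

  hl <- config$height_link
  p_exp <- params$b + hl$beta * params$c  # biomass scales as D^p_exp
  trees <- vector("list", n)
  n_trees <- integer(n)
  for (i in seq_len(n)) {
    nt <- sample(seq(config$trees_per_plot[1], config$trees_per_plot[2]), 1L)
    n_trees[i] <- nt
    d0 <- stats::runif(nt, config$dbh_range_cm[1], config$dbh_range_cm[2])
    hn <- exp(stats::rnorm(nt, 0, hl$sdlog))
    w0 <- params$a * d0^params$b * (hl$alpha * d0^hl$beta * hn)^params$c
    k <- (observed[i] / sum(w0))^(1 / p_exp)
    d <- k * d0
    h <- hl$alpha * d^hl$beta * hn
    trees[[i]] <- data.frame(
      plot_id = plot_id[i],
      species = sample(config$species_mix$species, nt, replace = TRUE,
                       prob = config$species_mix$proportion),
      dbh = d, height = h)
  }
  tree_df <- do.call(rbind, trees)
  rownames(tree_df) <- NULL

  plots <- data.frame(plot_id = plot_id,
                      longitude = stats::runif(n, 120, 125),
                      latitude = stats::runif(n, 38.7, 43.3),
                      altitude = altitude, slope = slope,
                      canopy_closure = canopy_closure,
                      spectral,
                      agb = observed, n_trees = n_trees)
  truth <- list(s = s, latent_biomass = latent, observed_biomass = observed,
                outlier = outlier,
                link = function(score) biomass_link(score, config),
                config = config)
  structure(list(trees = tree_df, plots = plots, truth = truth),
            class = "agb_inventory")
}

#' @export
print.agb_inventory <- function(x, ...) {
  cat(sprintf("agb_inventory: %d plots, %d trees, %d planted outliers\n",
              nrow(x$plots), nrow(x$trees), sum(x$truth$outlier)))
  invisible(x)
}

#' Generate a synthetic feature raster stack
#'
#' Builds an analysis-ready raster with bands `b2..b7`, `vv`, `vh`,
#' `altitude`, `slope` and `canopy_closure`.  Background cells follow a
#' smooth site-quality field through the same biomass-feature link as the
#' plots; each plot is assigned a distinct cell (away from the raster edge
#' by `margin` cells so texture windows fit) whose values equal the plot
#' table's values exactly.
#'
#' @param config An [simulation_config()] object.
#' @param grid_shape `c(rows, cols)`; the interior must hold all plots.
#' @param inventory Optional [generate_inventory()] result; generated from
#'   `config` if missing.
#' @param margin Edge margin (cells) kept free of plots; default 3 matches
#'   the default 7x7 texture window.
#' @return List with elements `stack` (an [raster_stack()]), `plot_pixels`
#'   (data frame `plot_id`, `row`, `col`) and `truth_field` (matrix of
#'   background site scores).
#' @export
generate_raster_stack <- function(config = simulation_config(),
                                  grid_shape = c(26L, 26L),
                                  inventory = NULL, margin = 3L) {
  stopifnot(inherits(config, "agb_sim_config"), length(grid_shape) == 2L)
  if (is.null(inventory)) inventory <- generate_inventory(config)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  rows_ok <- seq(margin + 1L, nr - margin)
  cols_ok <- seq(margin + 1L, nc - margin)
  n <- nrow(inventory$plots)
  if (length(rows_ok) < 1L || length(cols_ok) < 1L ||
      length(rows_ok) * length(cols_ok) < n)
    stop(sprintf("grid %dx%d too small for %d plots with margin %d",
                 nr, nc, n, margin))
  set.seed(config$seed + 104729L)  # fixed offset: raster sub-stream

  # smooth background site-quality field
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  field <- 0.7 * sin(2 * pi * rr / nr) * cos(2 * pi * cc / nc) +
    0.3 * matrix(stats::rnorm(nr * nc, 0, 0.5), nr, nc)
  field <- clamp(field, -1, 1)

  lk <- config$spectral_link
  sp <- spectral_from_score(as.vector(field), lk)
  tr <- config$terrain_ranges
  npix <- nr * nc
  alt <- tr$altitude[1] + diff(tr$altitude) *
    clamp(0.5 + 0.25 * as.vector(field) + stats::rnorm(npix, 0, 0.1), 0, 1)
  slp <- stats::runif(npix, tr$slope[1], tr$slope[2])
  ccl <- tr$canopy_closure[1] + diff(tr$canopy_closure) *
    clamp(0.5 + 0.35 * as.vector(field) + stats::rnorm(npix, 0, 0.08), 0, 1)

  bands <- c(names(lk$band_base), names(lk$sar_base),
             "altitude", "slope", "canopy_closure")
  vals <- array(NA_real_, dim = c(nr, nc, length(bands)))
  for (k in seq_along(c(names(lk$band_base), names(lk$sar_base))))
    vals[, , k] <- matrix(sp[[k]], nr, nc)
  vals[, , length(bands) - 2L] <- matrix(alt, nr, nc)
  vals[, , length(bands) - 1L] <- matrix(slp, nr, nc)
  vals[, , length(bands)] <- matrix(ccl, nr, nc)

  # place plots at distinct interior cells; plot cells take plot values
  cells <- expand.grid(row = rows_ok, col = cols_ok)
  pick <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  plot_pixels <- data.frame(plot_id = inventory$plots$plot_id,
                            row = pick$row, col = pick$col)
  plot_cols <- c(names(lk$band_base), names(lk$sar_base),
                 "altitude", "slope", "canopy_closure")
  for (k in seq_along(plot_cols)) {
    m <- vals[, , k]
    m[cbind(pick$row, pick$col)] <- inventory$plots[[plot_cols[k]]]
    vals[, , k] <- m
  }
  stack <- raster_stack(vals, bands = bands, xmin = 0, ymax = nr * 30,
                        res = 30, crs = "local-utm-like")
  list(stack = stack, plot_pixels = plot_pixels, truth_field = field)
}

#' Write inventory tables and truth sidecar to a directory
#'
#' @param inventory An [generate_inventory()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inventory <- function(inventory, dir) {
  stopifnot(inherits(inventory, "agb_inventory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(inventory$trees, file.path(dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(inventory$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  truth <- inventory$truth
  jsonlite::write_json(
    list(s = truth$s, latent_biomass = truth$latent_biomass,
         observed_biomass = truth$observed_biomass, outlier = truth$outlier,
         nonlinearity_strength = truth$config$nonlinearity_strength,
         seed = truth$config$seed),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
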
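#' End-to-end pipeline configuration
#'
#' Bundles per-stage settings under one global seed.  The global seed fans
#' out deterministically to per-stage seeds (simulation: `seed`; split:
#' `seed + 1`; network init: `seed + 2`; swarm: `seed + 3`) so each stage
#' is independently reproducible.
#'
#' @param seed Global integer seed.
#' @param sim An [simulation_config()]; its seed is overridden by `seed`.
#' @param grid_shape Raster dimensions for the synthetic stack.
#' @param window_size,levels Texture parameters used throughout.
#' @param alpha Predictor-selection significance level (default 0.01).
#' @param max_predictors Cap on the number of screened predictors passed to
#'   the models (strongest first; default 8).
#' @param hidden_size Hidden units for both networks.
#' @param swarm_size,pso_iterations Swarm settings.
#' @param mlp_epochs Levenberg-Marquardt epoch budget.
#' @return Object of class `agb_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = simulation_config(seed = seed),
                            grid_shape = c(26L, 26L), window_size = 7L,
                            levels = 64L, alpha = 0.01, max_predictors = 8L,
                            hidden_size = 10L, swarm_size = 30L,
                            pso_iterations = 200L, mlp_epochs = 200L) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim,
                 grid_shape = grid_shape, window_size = window_size,
                 levels = levels, alpha = alpha,
                 max_predictors = as.integer(max_predictors),
                 hidden_size = as.integer(hidden_size),
                 swarm_size = as.integer(swarm_size),
                 pso_iterations = as.integer(pso_iterations),
                 mlp_epochs = as.integer(mlp_epochs)),
            class = "agb_pipeline_config")
}

#' Run the full synthetic-data inversion pipeline
#'
#' Simulate an inventory and feature raster, assemble the 86-variable
#' catalogue, filter biomass outliers, screen predictors by Pearson
#' correlation, fit the three competing models (stepwise linear regression,
#' Levenberg-Marquardt network, swarm-optimised network) on a 70/15/15
#' split, evaluate them on the held-out test plots, and map biomass with
#' the best model.  All tables, model specifications, the comparison
#' report and the biomass raster are written to `out_dir` together with
#' the effective configuration (and its hash) for provenance.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param verbose Print stage progress (default `TRUE`).
#' @return List of class `agb_pipeline_result`: `inventory`, `raster`,
#'   `catalogue`, `filter`, `correlation`, `selected`, `split`, `models`,
#'   `report`, `best_model`, `map`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "agb_pipeline_config"))
  say <- function(...) if (verbose) message("[forestagb] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inv <- stage("simulate inventory", generate_inventory(config$sim))
  ras <- stage("simulate raster stack",
               generate_raster_stack(config$sim, config$grid_shape,
                                     inventory = inv,
                                     margin = config$window_size %/% 2L))
  cat86 <- stage("assemble feature catalogue",
                 assemble_catalogue(inv$plots, ras$stack, ras$plot_pixels,
                                    window_size = config$window_size,
                                    levels = config$levels))
  plots <- merge(inv$plots[, c("plot_id", "agb")], cat86, by = "plot_id")
  filt <- stage("remove biomass outliers", remove_outliers(plots))
  kept <- filt$retained
  cors <- stage("correlation screening",
                correlation_screen(
                  kept[, catalogue_names(), drop = FALSE], kept$agb))
  selected <- stage("select predictors", {
    s <- select_predictors(cors, alpha = config$alpha)
    utils::head(s, config$max_predictors)
  })
  if (length(selected) == 0L)
    stop("no predictors passed screening; cannot fit models")

  Xs <- kept[, selected, drop = FALSE]
  y <- kept$agb
  split <- split_dataset(nrow(Xs), seed = config$seed + 1L)
  mcfg <- mlp_config(hidden_size = config$hidden_size,
                     max_epochs = config$mlp_epochs,
                     seed = config$seed + 2L)
  pcfg <- pso_config(swarm_size = config$swarm_size,
                     max_iterations = config$pso_iterations,
                     seed = config$seed + 3L)
  lin <- stage("fit stepwise linear model",
               stepwise_fit(Xs[split$train, , drop = FALSE],
                            y[split$train]))
  bp <- stage("fit LM-trained network",
              train_mlp_lm(Xs, y, mcfg, split))
  psobp <- stage("fit swarm-optimised network",
                 pso_train_mlp(Xs, y, mcfg, pcfg, split))

  models <- list(stepwise_linear = lin$spec, bp_network = bp,
                 pso_network = psobp)
  report <- stage("evaluate on test set",
                  compare_models(models,
                                 Xs[split$test, , drop = FALSE],
                                 y[split$test]))
  best_name <- report$model[which.max(report$r2_cod)]
  say("best model by coefficient of determination: ", best_name)
  map <- stage("map biomass",
               invert_raster(models[[best_name]], ras$stack,
                             window_size = config$window_size,
                             levels = config$levels))

  res <- structure(list(inventory = inv, raster = ras, catalogue = cat86,
                        filter = filt, correlation = cors,
                        selected = selected, split = split, models = models,
                        report = report, best_model = best_name, map = map,
                        config = config),
                   class = "agb_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir, say)
  res
}

write_pipeline_artifacts <- function(res, out_dir, say = message) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("writing artifacts to ", out_dir)
  write_inventory(res$inventory, out_dir)
  utils::write.csv(species_share(res$inventory$trees),
                   file.path(out_dir, "species_share.csv"),
                   row.names = FALSE)
  utils::write.csv(res$catalogue,
                   file.path(out_dir, "feature_catalogue.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$correlation),
                   file.path(out_dir, "correlation_table.csv"),
                   row.names = FALSE)
  writeLines(res$selected, file.path(out_dir, "selected_features.txt"))
  write_model_spec(res$models$stepwise_linear,
                   file.path(out_dir, "linear_model.json"))
  utils::write.csv(res$report, file.path(out_dir, "comparison_report.csv"),
                   row.names = FALSE)
  write_raster_stack(res$map, file.path(out_dir, "agb_map.tif"))
  cfg_json <- jsonlite::toJSON(unclass_deep(res$config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(out_dir, "run_config.json")
  writeLines(cfg_json, cfg_path)
  hash <- as.character(tools::md5sum(cfg_path))
  jsonlite::write_json(list(config_hash = unname(hash),
                            best_model = res$best_model),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.function(x)) NULL
  else x
}

#' @export
print.agb_pipeline_result <- function(x, ...) {
  cat("agb_pipeline_result\n")
  cat(sprintf("  plots: %d simulated, %d after outlier filter\n",
              nrow(x$inventory$plots), nrow(x$filter$retained)))
  cat(sprintf("  predictors selected (p < %g): %s\n", x$config$alpha,
              paste(x$selected, collapse = ", ")))
  cat("  test-set comparison:\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("  best model: %s\n", x$best_model))
  invisible(x)
}
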
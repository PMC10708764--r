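test_that("generator is a pure function of the configuration", {
  cfg <- simulation_config(n_plots = 40, seed = 9)
  a <- generate_inventory(cfg)
  b <- generate_inventory(cfg)
  expect_identical(a$trees, b$trees)
  expect_identical(a$plots, b$plots)
  expect_identical(a$truth$outlier, b$truth$outlier)
})

test_that("default configuration emits 354 plots with planted outliers", {
  inv <- generate_inventory(simulation_config(seed = 2))
  expect_equal(nrow(inv$plots), 354)
  expect_equal(sum(inv$truth$outlier),
               round((354 - 162) / 354 * 354))
  expect_true(all(inv$trees$dbh > 0))
  expect_true(all(inv$trees$height > 0))
  expect_true(all(inv$plots$canopy_closure >= 0 &
                    inv$plots$canopy_closure <= 1))
})

test_that("plot biomass recomputed from trees equals the recorded biomass", {
  inv <- generate_inventory(simulation_config(n_plots = 30, seed = 4))
  pb <- plot_biomass(inv$trees)
  m <- merge(pb, inv$plots[, c("plot_id", "agb")], by = "plot_id")
  expect_equal(m$agb.x, m$agb.y, tolerance = 1e-12)
  # clean plots carry the latent biomass of the exported link
  clean <- !inv$truth$outlier
  expect_equal(inv$plots$agb[clean],
               inv$truth$link(inv$truth$s)[clean], tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(dbh_range_cm = c(10, 10)), "degenerate")
  expect_error(simulation_config(outlier_fraction = 0.7), "outlier_fraction")
  bad_mix <- data.frame(species = c("a", "b"), proportion = c(0.5, 0.6))
  expect_error(simulation_config(species_mix = bad_mix), "sum to 1")
})

test_that("raster stack embeds plot samples exactly and round-trips", {
  cfg <- simulation_config(n_plots = 25, seed = 7)
  inv <- generate_inventory(cfg)
  ras <- generate_raster_stack(cfg, grid_shape = c(26, 26), inventory = inv)
  # reading the raster at plot pixels reproduces the plot table
  for (bn in c("b2", "b5", "vv", "altitude", "canopy_closure")) {
    m <- get_band(ras$stack, bn)
    expect_identical(m[cbind(ras$plot_pixels$row, ras$plot_pixels$col)],
                     inv$plots[[bn]])
  }
  b <- get_band(ras$stack, "b5")
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(get_band(ras$stack, "vv") >= -30 &
                    get_band(ras$stack, "vv") <= 0))
  expect_error(generate_raster_stack(cfg, grid_shape = c(8, 8),
                                     inventory = inv), "too small")
})

test_that("zero nonlinearity makes biomass affine in the features", {
  lk <- default_spectral_link()
  lk$band_noise_sd <- 0; lk$sar_noise_sd <- 0
  cfg <- simulation_config(n_plots = 60, seed = 3, outlier_fraction = 0,
                           nonlinearity_strength = 0, spectral_link = lk)
  inv <- generate_inventory(cfg)
  fit <- lm(agb ~ b5, data = inv$plots)
  # summary.lm warns on an essentially perfect fit, which is the point here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  expect_gt(r2, 0.999999)
})

test_that("positive nonlinearity puts a linear fit strictly below a flexible one", {
  lk <- default_spectral_link()
  lk$band_noise_sd <- 0; lk$sar_noise_sd <- 0
  cfg <- simulation_config(n_plots = 80, seed = 3, outlier_fraction = 0,
                           nonlinearity_strength = 3, spectral_link = lk)
  inv <- generate_inventory(cfg)
  r2_lin <- summary(lm(agb ~ b5, data = inv$plots))$r.squared
  r2_flex <- summary(lm(agb ~ poly(b5, 5), data = inv$plots))$r.squared
  expect_lt(r2_lin, r2_flex)
  expect_gt(r2_flex - r2_lin, 0.001)
})

test_that("inventory tables and truth sidecar are written as plain text", {
  dir <- withr::local_tempdir()
  inv <- generate_inventory(simulation_config(n_plots = 10, seed = 1,
                                              outlier_fraction = 0))
  write_inventory(inv, dir)
  expect_true(file.exists(file.path(dir, "trees.csv")))
  tr <- read_tree_table(file.path(dir, "trees.csv"))
  expect_equal(nrow(tr), nrow(inv$trees))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$latent_biomass, inv$truth$latent_biomass,
               tolerance = 1e-12)
})
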
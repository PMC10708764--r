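test_that("vegetation indices match direct evaluation of their formulas", {
  # equal NIR and RED: differences vanish, ratio is one
  s <- list(b2 = 0.05, b4 = 0.3, b5 = 0.3, b6 = 0.2)
  vi <- vegetation_indices(s)
  expect_equal(vi$ndvi, 0)
  expect_equal(vi$dvi, 0)
  expect_equal(vi$rvi, 1)

  s2 <- list(b2 = 0.04, b4 = 0.1, b5 = 0.5, b6 = 0.2)
  vi2 <- vegetation_indices(s2)
  expect_equal(vi2$ndvi, 0.4 / 0.6)
  # frozen: (0.5 - (0.74*0.1 + 0.26*0.2)) / (0.5 + (0.74*0.1 + 0.26*0.2))
  expect_equal(vi2$ndpi, 0.59744408945686901, tolerance = 1e-14)
  expect_equal(vi2$savi, 1.5 * 0.4 / (0.6 + 0.5))
  # printed coefficient forms
  expect_equal(vi2$evi, 2.5 * 0.4 / (0.5 + 0.6 - 7 * 0.04 + 1))
  expect_equal(vi2$arvi, (0.5 - 0.2 - 0.04) / (0.5 + 0.2 - 0.04))
  # conventional variants differ as expected
  vi2s <- vegetation_indices(s2, evi_standard = TRUE, arvi_standard = TRUE)
  expect_equal(vi2s$evi, 2.5 * 0.4 / (0.5 + 0.6 - 7.5 * 0.04 + 1))
  expect_equal(vi2s$arvi, (0.5 - (0.2 - 0.04)) / (0.5 + 0.2 - 0.04))
})

test_that("zero denominators are flagged as missing, not coerced to zero", {
  s <- list(b2 = 0.1, b4 = 0, b5 = 0, b6 = 0.2)   # NIR + RED = 0, RVI 0/0
  vi <- vegetation_indices(s)
  expect_true(is.na(vi$ndvi))
  expect_true(is.na(vi$rvi))
  flags <- attr(vi, "flagged")
  expect_true("ndvi" %in% names(flags))
  expect_equal(flags$ndvi, 1L)
})

test_that("index ranges hold over random non-degenerate band values", {
  set.seed(22)
  s <- data.frame(b2 = runif(200, 0.01, 0.3), b4 = runif(200, 0.01, 0.4),
                  b5 = runif(200, 0.05, 0.6), b6 = runif(200, 0.01, 0.4))
  vi <- vegetation_indices(s)
  expect_true(all(abs(vi$ndvi) <= 1))
  expect_true(all(abs(vi$ndpi) <= 1))
  expect_true(all(vi$rvi >= 0))
  expect_true(all(is.finite(as.matrix(vi))))
})

test_that("GLCM matches exhaustive pair enumeration", {
  offs <- list(c(0L, 1L))
  chk <- matrix(c(0L, 1L, 1L, 0L), 2, 2)  # 2x2 checkerboard
  g <- glcm_from_window(chk, levels = 2L, offsets = offs)
  expect_equal(unclass(as.matrix(g)), glcm_oracle(chk, 2L, offs),
               ignore_attr = TRUE)

  set.seed(33)
  offs4 <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (i in 1:12) {
    w <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    g <- glcm_from_window(w, levels = 4L, offsets = offs4)
    expect_equal(unclass(as.matrix(g)), glcm_oracle(w, 4L, offs4),
                 ignore_attr = TRUE, tolerance = 1e-14)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_true(all(g >= 0))
    # symmetric by construction, and invariant to transposition under
    # the symmetric offset set
    expect_equal(unclass(as.matrix(g)), t(unclass(as.matrix(g))),
                 tolerance = 1e-14)
    gt <- glcm_from_window(t(w), levels = 4L, offsets = offs4)
    expect_equal(unclass(as.matrix(gt)), unclass(as.matrix(g)),
                 tolerance = 1e-14)
  }
})

test_that("degenerate GLCM inputs behave as specified", {
  const <- matrix(2L, 5, 5)
  g <- glcm_from_window(const, levels = 4L)
  expect_equal(sum(g), 1)
  expect_equal(g[3, 3], 1)  # single nonzero cell at (level, level)
  expect_error(glcm_from_window(matrix(0L, 1, 1), levels = 2L), "offset")
  expect_error(glcm_from_window(matrix(5L, 3, 3), levels = 4L), "levels")
})

test_that("texture measures match the hand-summed Haralick oracle", {
  # delta distribution: constant window
  g <- glcm_from_window(matrix(1L, 4, 4), levels = 4L)
  tm <- texture_measures(g)
  expect_equal(tm[["contrast"]], 0)
  expect_equal(tm[["dissimilarity"]], 0)
  expect_equal(tm[["entropy"]], 0)
  expect_equal(tm[["asm"]], 1)
  expect_equal(tm[["energy"]], 1)
  expect_equal(tm[["max_probability"]], 1)

  # uniform GLCM over L^2 cells: closed forms
  L <- 4L
  unif <- matrix(1 / L^2, L, L)
  tmu <- texture_measures(unif)
  expect_equal(tmu[["entropy"]], 2 * log(L))
  expect_equal(tmu[["asm"]], 1 / L^2)

  set.seed(44)
  for (i in 1:10) {
    w <- matrix(sample(0:3, 12, replace = TRUE), 3, 4)
    g <- glcm_from_window(w, levels = 4L)
    expect_equal(texture_measures(g), haralick_oracle(unclass(as.matrix(g))),
                 tolerance = 1e-12)
  }
})

test_that("the assembled catalogue has exactly the 86 canonical variables", {
  nm <- catalogue_names()
  expect_length(nm, 86)
  expect_false(anyDuplicated(nm) > 0)
  # decomposition 6 + 7 + 48 + 2 + 20 + 3
  expect_length(grep("^B[2-7]$", nm), 6)
  expect_true(all(c("ARVI", "DVI", "EVI", "NDPI", "NDVI", "RVI", "SAVI")
                  %in% nm))
  expect_length(grep("^B[2-7](Mean|Variance|Homogeneity|Contrast|Dissimilarity|Entropy|SecondMoment|Correlation)$", nm), 48)
  expect_true(all(c("VH", "VV") %in% nm))
  expect_length(grep("^V[HV](Mean|Variance|Homogeneity|Contrast|Dissimilarity|Entropy|Correlation|ASM|MAX|Energy)$", nm), 20)
  expect_true(all(c("Altitude", "Slope", "CanopyClosure") %in% nm))

  sc <- small_scene()
  cat86 <- assemble_catalogue(sc$inv$plots, sc$ras$stack, sc$ras$plot_pixels)
  expect_equal(names(cat86), c("plot_id", nm))
  expect_equal(nrow(cat86), nrow(sc$inv$plots))
  expect_false(anyNA(cat86))
  # band and terrain entries equal the plot table directly
  expect_equal(cat86$B5, sc$inv$plots$b5)
  expect_equal(cat86$Altitude, sc$inv$plots$altitude)
  expect_equal(cat86$CanopyClosure, sc$inv$plots$canopy_closure)
})

test_that("catalogue assembly is deterministic and constant on constant rasters", {
  sc <- small_scene()
  a <- assemble_catalogue(sc$inv$plots, sc$ras$stack, sc$ras$plot_pixels)
  b <- assemble_catalogue(sc$inv$plots, sc$ras$stack, sc$ras$plot_pixels)
  expect_identical(a, b)

  const <- make_test_stack(12, 12, bands = list(
    b2 = matrix(0.1, 12, 12), b3 = matrix(0.1, 12, 12),
    b4 = matrix(0.1, 12, 12), b5 = matrix(0.4, 12, 12),
    b6 = matrix(0.2, 12, 12), b7 = matrix(0.1, 12, 12),
    vv = matrix(-12, 12, 12), vh = matrix(-18, 12, 12),
    altitude = matrix(500, 12, 12), slope = matrix(10, 12, 12),
    canopy_closure = matrix(0.6, 12, 12)))
  px <- data.frame(plot_id = c("A", "B", "C"), row = c(5, 6, 7),
                   col = c(5, 7, 6))
  cc <- assemble_catalogue(NULL, const, px)
  expect_equal(nrow(unique(cc[, -1])), 1)
})

test_that("edge plots without a full texture window are excluded and logged", {
  sc <- small_scene()
  px <- rbind(sc$ras$plot_pixels,
              data.frame(plot_id = "EDGE", row = 1L, col = 5L))
  cat86 <- assemble_catalogue(NULL, sc$ras$stack, px)
  expect_false("EDGE" %in% cat86$plot_id)
  expect_equal(attr(cat86, "excluded"), "EDGE")
})
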
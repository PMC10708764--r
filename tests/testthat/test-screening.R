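test_that("pearson_r matches the two-pass summation oracle", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-14)
  set.seed(55)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-12)
    # symmetry and invariance to positive affine rescaling
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2.5 * a + 3, b), pearson_r(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(r0 <- pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r0))
})

test_that("correlation p-values agree with a permutation oracle", {
  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(1, 10), 0)
  # monotone in |r|
  ps <- sapply(seq(0.1, 0.9, by = 0.1), pearson_p, n = 25)
  expect_true(all(diff(ps) < 0))
  # t-transform matches stats::cor.test exactly
  set.seed(66)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- pearson_r(x, y)
  expect_equal(pearson_p(r, 20), cor.test(x, y)$p.value, tolerance = 1e-12)
  # permutation estimate within Monte-Carlo error
  nperm <- 1e5
  set.seed(67)
  perm_r <- sapply(seq_len(nperm), function(i) cor(x, sample(y)))
  p_perm <- mean(abs(perm_r) >= abs(r))
  expect_equal(pearson_p(r, 20), p_perm, tolerance = 0.012)
})

test_that("outlier removal is the identity on clean data and catches planted extremes", {
  clean <- data.frame(plot_id = letters[1:10],
                      agb = c(100, 105, 98, 110, 102, 97, 104, 99, 106, 101))
  f <- remove_outliers(clean)
  expect_equal(nrow(f$retained), 10)
  expect_equal(nrow(f$removed), 0)

  dirty <- rbind(clean, data.frame(plot_id = "z", agb = 1e6))
  f2 <- remove_outliers(dirty)
  expect_equal(f2$removed$plot_id, "z")
  expect_equal(nrow(f2$retained), 10)

  expect_error(remove_outliers(clean[1:2, ]), "at least 3")
})

test_that("the default run retains 162 of 354 plots, exactly the clean ones", {
  inv <- generate_inventory(simulation_config(seed = 20))
  f <- remove_outliers(inv$plots)
  expect_equal(nrow(f$retained), 162)
  expect_setequal(f$retained$plot_id,
                  inv$plots$plot_id[!inv$truth$outlier])
})

test_that("correlation screening reports consistent significance tiers", {
  set.seed(77)
  n <- 60
  bio <- rnorm(n, 100, 20)
  feats <- data.frame(strong = bio + rnorm(n, 0, 5),
                      weak = bio + rnorm(n, 0, 80),
                      noise1 = rnorm(n), noise2 = rnorm(n))
  tab <- correlation_screen(feats, bio)
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  # every strong-tier feature is also significant at 0.05
  in01 <- tab$feature[tab$tier == "p<0.01"]
  in05 <- tab$feature[tab$tier %in% c("p<0.01", "p<0.05")]
  expect_true(all(in01 %in% in05))
  expect_true("strong" %in% in01)
  expect_equal(attr(tab, "n_tests"), 4)
})

test_that("predictor selection orders by |r| and honours alpha", {
  set.seed(88)
  n <- 80
  bio <- rnorm(n, 100, 20)
  feats <- data.frame(perfect = bio,
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- correlation_screen(feats, bio)
  sel <- select_predictors(tab, alpha = 0.01)
  expect_equal(sel[1], "perfect")

  # planted strong predictors rank first
  feats2 <- data.frame(s1 = bio + rnorm(n, 0, 2), s2 = -bio + rnorm(n, 0, 4),
                       n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                       n4 = rnorm(n))
  sel2 <- select_predictors(correlation_screen(feats2, bio), alpha = 0.01)
  expect_setequal(sel2[1:2], c("s1", "s2"))
})

test_that("all-noise screening has the nominal type-I error rate", {
  set.seed(99)
  n <- 30
  bio <- rnorm(n)
  feats <- as.data.frame(matrix(rnorm(n * 1000), n, 1000))
  tab <- correlation_screen(feats, bio)
  frac <- mean(tab$p < 0.05)
  # binomial SE at p=0.05 with 1000 draws is ~0.007
  expect_lt(abs(frac - 0.05), 0.025)
})
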
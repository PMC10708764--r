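# Independent brute-force oracles, deliberately written with explicit loops
# and naive summation so they share no code path with the package.

# two-pass Pearson correlation, straight from the defining sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / (sqrt(dx2) * sqrt(dy2))
}

# exhaustive pair-enumeration GLCM: count co-occurring level pairs in both
# directions for each offset, normalise per offset, average
glcm_oracle <- function(window, levels, offsets) {
  nr <- nrow(window); nc <- ncol(window)
  acc <- matrix(0, levels, levels)
  n_used <- 0
  for (off in offsets) {
    counts <- matrix(0, levels, levels)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- window[r, c]; b <- window[r2, c2]
        if (!is.na(a) && !is.na(b)) {
          counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
          counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
        }
      }
    }
    if (sum(counts) > 0) {
      acc <- acc + counts / sum(counts)
      n_used <- n_used + 1
    }
  }
  acc / n_used
}

# Haralick measures by explicit double loops over the co-occurrence matrix
haralick_oracle <- function(p) {
  L <- nrow(p)
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0; hom <- 0; con <- 0; dis <- 0; ent <- 0
  asm <- 0; mx <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    var_i <- var_i + (i - 1 - mu_i)^2 * pij
    var_j <- var_j + (j - 1 - mu_j)^2 * pij
    hom <- hom + pij / (1 + ((i - 1) - (j - 1))^2)
    con <- con + ((i - 1) - (j - 1))^2 * pij
    dis <- dis + abs((i - 1) - (j - 1)) * pij
    if (pij > 0) ent <- ent - pij * log(pij)
    asm <- asm + pij^2
    if (pij > mx) mx <- pij
    cov <- cov + (i - 1 - mu_i) * (j - 1 - mu_j) * pij
  }
  corr <- if (var_i > 0 && var_j > 0) cov / sqrt(var_i * var_j) else 0
  c(mean = mu_i, variance = var_i, homogeneity = hom, contrast = con,
    dissimilarity = dis, entropy = ent, second_moment = asm,
    correlation = corr, asm = asm, max_probability = mx,
    energy = sqrt(asm))
}

# ordinary least squares by the closed-form normal equations
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# small raster stack with all 11 bands filled from supplied matrices or a
# default gradient; used by feature/mapping tests
make_test_stack <- function(nr = 8, nc = 8, bands = NULL) {
  all_bands <- c(paste0("b", 2:7), "vv", "vh",
                 "altitude", "slope", "canopy_closure")
  vals <- array(NA_real_, dim = c(nr, nc, length(all_bands)))
  grad <- outer(seq_len(nr), seq_len(nc), function(r, c) (r + c) / (nr + nc))
  defaults <- list(b2 = 0.05 + 0.1 * grad, b3 = 0.06 + 0.1 * grad,
                   b4 = 0.05 + 0.12 * grad, b5 = 0.25 + 0.2 * grad,
                   b6 = 0.1 + 0.15 * grad, b7 = 0.08 + 0.1 * grad,
                   vv = -15 + 6 * grad, vh = -20 + 5 * grad,
                   altitude = 100 + 900 * grad, slope = 2 + 20 * grad,
                   canopy_closure = 0.3 + 0.5 * grad)
  for (k in seq_along(all_bands)) {
    bn <- all_bands[k]
    m <- if (!is.null(bands) && !is.null(bands[[bn]])) bands[[bn]]
      else defaults[[bn]]
    vals[, , k] <- m
  }
  raster_stack(vals, bands = all_bands, xmin = 0, ymax = nr * 30, res = 30)
}

# small simulated scene shared by catalogue tests
small_scene <- function(seed = 11, n_plots = 12) {
  cfg <- simulation_config(n_plots = n_plots, seed = seed,
                           outlier_fraction = 0)
  inv <- generate_inventory(cfg)
  ras <- generate_raster_stack(cfg, grid_shape = c(26L, 26L),
                               inventory = inv)
  list(cfg = cfg, inv = inv, ras = ras)
}
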
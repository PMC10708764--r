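#' Quantize a numeric image to integer grey levels
#'
#' Equal-width binning of a numeric matrix into levels `0 .. levels - 1`
#' over a fixed value range (by default the range of the data).  Using a
#' raster-wide range for every window keeps texture comparable across
#' windows.
#'
#' @param x Numeric matrix; `NA` allowed (propagated).
#' @param levels Number of grey levels (default 64).
#' @param range Length-2 numeric range mapped onto the levels; values
#'   outside are clamped.
#' @return Integer matrix with values in `0 .. levels - 1` (`NA` preserved).
#' @export
quantize_image <- function(x, levels = 64L, range = NULL) {
  stopifnot(is.matrix(x), levels >= 2L)
  if (is.null(range)) range <- base::range(x, na.rm = TRUE)
  lo <- range[1]; hi <- range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    q <- matrix(0L, nrow(x), ncol(x))
    q[is.na(x)] <- NA_integer_
    return(q)
  }
  q <- floor((pmin(pmax(x, lo), hi) - lo) / (hi - lo) * levels)
  q[q == levels] <- levels - 1L
  mode(q) <- "integer"
  matrix(q, nrow(x), ncol(x))
}

#' Grey-level co-occurrence matrix of an image window
#'
#' Counts co-occurring grey-level pairs at the given pixel offsets,
#' symmetrises (each pair is counted in both directions), averages over
#' offsets and normalises to sum 1.
#'
#' @param window Integer matrix with values in `0 .. levels - 1` (`NA`
#'   allowed; pairs touching `NA` are skipped).
#' @param levels Number of grey levels.
#' @param offsets List of integer `c(dr, dc)` offsets; the default
#'   `{(0,1), (1,0), (1,1), (1,-1)}` covers the four principal directions.
#' @return A `levels x levels` matrix of class `agb_glcm` whose entries are
#'   non-negative and sum to 1; attributes record `levels` and `offsets`.
#' @export
glcm_from_window <- function(window, levels = 64L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.matrix(window), levels >= 2L)
  w <- window
  if (any(w < 0 | w >= levels, na.rm = TRUE))
    stop("window values must lie in [0, levels)")
  nr <- nrow(w); nc <- ncol(w)
  acc <- matrix(0, levels, levels)
  n_used <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (abs(dr) >= nr || abs(dc) >= nc)
      stop(sprintf("window %dx%d smaller than offset reach (%d,%d)",
                   nr, nc, dr, dc))
    r1 <- seq(max(1, 1 - dr), min(nr, nr - dr))
    c1 <- seq(max(1, 1 - dc), min(nc, nc - dc))
    a <- w[r1, c1, drop = FALSE]
    b <- w[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- matrix(0, levels, levels)
    tab <- table(factor(a[ok], levels = 0:(levels - 1)),
                 factor(b[ok], levels = 0:(levels - 1)))
    counts <- counts + tab + t(tab)   # symmetric counting
    if (sum(counts) > 0) {
      acc <- acc + counts / sum(counts)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no valid pixel pairs in window")
  g <- acc / n_used
  structure(unclass(as.matrix(g)), class = "agb_glcm",
            levels = as.integer(levels), offsets = offsets)
}

#' Haralick-style texture measures of a GLCM
#'
#' Standard measures of a normalised, symmetric co-occurrence matrix
#' `p(i, j)` with 0-based levels `i, j`:
#' mean `sum i p(i,j)`, variance `sum (i - mu)^2 p(i,j)`,
#' homogeneity `sum p / (1 + (i-j)^2)`, contrast `sum (i-j)^2 p`,
#' dissimilarity `sum |i-j| p`, entropy `-sum p ln p` (with `0 ln 0 := 0`),
#' angular second moment `ASM = sum p^2` (also reported as
#' `second_moment`), `energy = sqrt(ASM)`, `max_probability = max p`, and
#' correlation `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)`.
#' For a degenerate (zero-variance) GLCM the correlation is reported as 0.
#'
#' @param g An [glcm_from_window()] result (any normalised matrix works).
#' @return Named numeric vector with elements `mean`, `variance`,
#'   `homogeneity`, `contrast`, `dissimilarity`, `entropy`, `second_moment`,
#'   `correlation`, `asm`, `max_probability`, `energy`.
#' @export
texture_measures <- function(g) {
  p <- unclass(as.matrix(g))
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM must be normalised to sum 1")
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  plog <- ifelse(p > 0, p * log(p), 0)
  asm <- sum(p^2)
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j) else 0
  c(mean = mu_i,
    variance = var_i,
    homogeneity = sum(p / (1 + (i - j)^2)),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    entropy = -sum(plog),
    second_moment = asm,
    correlation = corr,
    asm = asm,
    max_probability = max(p),
    energy = sqrt(asm))
}

# measure sets used by the catalogue: 8 per optical band, 10 per SAR channel
optical_measure_names <- function()
  c("Mean", "Variance", "Homogeneity", "Contrast", "Dissimilarity",
    "Entropy", "SecondMoment", "Correlation")

sar_measure_names <- function()
  c("Mean", "Variance", "Homogeneity", "Contrast", "Dissimilarity",
    "Entropy", "Correlation", "ASM", "MAX", "Energy")

measure_key <- c(Mean = "mean", Variance = "variance",
                 Homogeneity = "homogeneity", Contrast = "contrast",
                 Dissimilarity = "dissimilarity", Entropy = "entropy",
                 SecondMoment = "second_moment", Correlation = "correlation",
                 ASM = "asm", MAX = "max_probability", Energy = "energy")
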
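#' Min-max gray-level normalization to 0..255
#'
#' Maps in-mask intensities affinely onto integer levels 0..255 (floor after
#' scaling); a constant in-mask volume maps to level 0. Out-of-mask voxels are
#' set to `NA` and ignored by every texture operator.
#'
#' @param volume 3D numeric array.
#' @param mask logical 3D array.
#' @return a `norm_volume`: list with `levels` (integer array, `NA` outside
#'   the mask) and `mask`.
#' @export
normalize_gray_levels <- function(volume, mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask: nothing to normalize")
  v <- volume[mask]
  rng <- range(v)
  lev <- array(NA_integer_, dim(volume))
  if (rng[1] == rng[2]) {
    lev[mask] <- 0L
  } else {
    lev[mask] <- pmin(255L, as.integer(floor(
      (v - rng[1]) / (rng[2] - rng[1]) * 255)))
  }
  structure(list(levels = lev, mask = mask), class = "norm_volume")
}

#' First-order texture features (36)
#'
#' Histogram statistics of the in-mask gray levels: mean, median, population
#' variance and SD, excess kurtosis, skewness, Shannon entropy of the
#' 256-level histogram (7); the empirical CDF at 10 equally spaced thresholds
#' over 0..255 (10); percentiles 10..100 in steps of 10 (10); observation
#' count, bin count, bin width and lower limit of a 4-bin histogram (4); the
#' four bin counts (4); and a duplicated descriptive mean (1).
#' Skewness and kurtosis are defined as 0 for a constant volume.
#'
#' @param normvol a `norm_volume` from [normalize_gray_levels()].
#' @return named numeric vector of length 36.
#' @export
first_order_features <- function(normvol) {
  x <- as.numeric(normvol$levels[normvol$mask])
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  p <- tabulate(x + 1L, 256L) / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  cdf_t <- seq(0, 255, length.out = 10)
  cdf <- vapply(cdf_t, function(t) mean(x <= t), 0)
  names(cdf) <- sprintf("fo_cdf_%03d", round(cdf_t))
  pct <- stats::quantile(x, probs = seq(0.1, 1, by = 0.1), names = FALSE)
  names(pct) <- sprintf("fo_p%02d", seq(10, 100, by = 10))
  n_bins <- 4L
  bw <- 256 / n_bins
  bins <- tabulate(pmin(n_bins, x %/% bw + 1L), n_bins)
  names(bins) <- sprintf("fo_bin%d_count", seq_len(n_bins))
  c(fo_mean = mu, fo_median = stats::median(x), fo_variance = m2,
    fo_sd = sqrt(m2), fo_kurtosis = kurt, fo_skewness = skew,
    fo_entropy = entropy,
    cdf, pct,
    fo_n_obs = n, fo_n_bins = n_bins, fo_bin_width = bw, fo_lower_limit = 0,
    bins,
    fo_descriptive_mean = mu)
}

# The 13 canonical offsets whose +/- pairs enumerate all 26 neighbours of a
# voxel: 4 in-plane directions (angles 0, pi/4, pi/2, 3pi/4) and 9 towards the
# upper layer.
glcm_offsets <- function() {
  inplane <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(-1, 1, 0))
  upper <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 1))
  rbind(inplane, unname(upper))
}

#' 3D gray-level co-occurrence matrix over the 26-neighbourhood
#'
#' Accumulates level co-occurrence counts over all 26 unit-distance neighbour
#' offsets (8 in-plane at angles 0, pi/4, pi/2, 3pi/4 and their opposites,
#' plus the 9 upper-layer and 9 lower-layer offsets). Only pairs with both
#' voxels in-mask are counted. The 256 x 256 matrix is then normalized to sum
#' to one; it is symmetric because every offset's opposite is included.
#'
#' @param normvol a `norm_volume`.
#' @param normalize divide by the total count (default `TRUE`).
#' @return a `glcm`: 256 x 256 matrix with attributes `n_pairs`, `normalized`.
#' @export
build_glcm <- function(normvol, normalize = TRUE) {
  lev <- normvol$levels
  d <- dim(lev)
  counts <- matrix(0, 256, 256)
  for (r in seq_len(nrow(glcm_offsets()))) {
    off <- glcm_offsets()[r, ]
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    kx <- xs + off[1] >= 1 & xs + off[1] <= d[1]
    ky <- ys + off[2] >= 1 & ys + off[2] <= d[2]
    kz <- zs + off[3] >= 1 & zs + off[3] <= d[3]
    a <- lev[xs[kx], ys[ky], zs[kz], drop = FALSE]
    b <- lev[xs[kx] + off[1], ys[ky] + off[2], zs[kz] + off[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] * 256L + b[ok] + 1L, 65536L)
    counts <- counts + matrix(tab, 256, 256, byrow = TRUE)
  }
  counts <- counts + t(counts)                  # opposite offsets
  total <- sum(counts)
  if (total < 1) stop("fewer than one valid voxel pair for the GLCM")
  out <- if (normalize) counts / total else counts
  structure(out, n_pairs = total, normalized = normalize, class = "glcm")
}

#' GLCM summary features (6)
#'
#' Contrast, correlation, angular second moment (ASM), dissimilarity,
#' homogeneity and energy of a normalized GLCM, with gray levels 0..255 as
#' the row/column values. When a marginal variance is zero the correlation is
#' reported as 1 (a constant image is perfectly predictable).
#'
#' @param glcm a normalized `glcm`.
#' @return named numeric vector of length 6.
#' @export
glcm_features <- function(glcm) {
  stopifnot(isTRUE(attr(glcm, "normalized")))
  p <- unclass(glcm)
  i <- matrix(0:255, 256, 256)
  j <- t(i)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  var_i <- sum(p * (i - mu_i)^2); var_j <- sum(p * (j - mu_j)^2)
  asm <- sum(p^2)
  corr <- if (var_i > 0 && var_j > 0)
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j) else 1
  c(glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_asm = asm,
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_energy = sqrt(asm))
}

#' 3D gray-level run-length matrix
#'
#' Accumulates maximal runs of equal gray level along the X axis within each
#' (y, z) line ("XY-horizontal") and along the Z axis within each (x, y)
#' column ("Z-vertical"). Out-of-mask voxels break runs. Entry `p[i, j]` is
#' the number of runs of level `i - 1` and length `j`.
#'
#' @param normvol a `norm_volume`.
#' @param orientations subset of `c("x", "z")` (default both).
#' @return a `glrlm`: 256 x L_max matrix with attributes `n_voxels`,
#'   `n_orientations`.
#' @export
build_glrlm <- function(normvol, orientations = c("x", "z")) {
  lev <- normvol$levels
  runs_g <- integer(0); runs_l <- integer(0)
  for (or in orientations) {
    a <- if (or == "x") lev else aperm(lev, c(3, 1, 2))
    d <- dim(a)
    m <- matrix(as.integer(a), d[1], d[2] * d[3])
    v <- as.vector(rbind(m, -1L))                # sentinel breaks lines
    v[is.na(v)] <- -1L                           # mask gaps break runs
    r <- rle(v)
    keep <- r$values >= 0L
    runs_g <- c(runs_g, r$values[keep])
    runs_l <- c(runs_l, r$lengths[keep])
  }
  if (!length(runs_g)) stop("empty mask: no runs")
  lmax <- max(runs_l)
  p <- matrix(0, 256, lmax)
  tab <- table(factor(runs_g, levels = 0:255), factor(runs_l, levels = 1:lmax))
  p[] <- as.numeric(tab)
  structure(p, n_voxels = sum(!is.na(lev)),
            n_orientations = length(orientations), class = "glrlm")
}

#' GLRLM summary features (16)
#'
#' The standard run-length statistics: SRE, LRE, GLN, GLNN, RLN, RLNN, RP,
#' GLV, RV, RE, LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE. Gray-level
#' weights use levels shifted to 1..256 so low-gray-level emphases stay
#' finite at level 0; run percentage divides the run count by
#' `n_voxels x n_orientations`.
#'
#' @param glrlm a `glrlm` from [build_glrlm()].
#' @param n_voxels in-mask voxel count (default: taken from the matrix).
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(glrlm, n_voxels = attr(glrlm, "n_voxels")) {
  p <- unclass(glrlm)
  nr <- sum(p)
  stopifnot(nr >= 1)
  gl <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))         # levels 1..256
  rl <- matrix(seq_len(ncol(p)), nrow(p), ncol(p), byrow = TRUE)
  pg <- rowSums(p); pr <- colSums(p)
  pn <- p / nr
  mu_g <- sum(pn * gl); mu_r <- sum(pn * rl)
  pe <- pn[pn > 0]
  c(glrlm_sre = sum(p / rl^2) / nr,
    glrlm_lre = sum(p * rl^2) / nr,
    glrlm_gln = sum(pg^2) / nr,
    glrlm_glnn = sum(pg^2) / nr^2,
    glrlm_rln = sum(pr^2) / nr,
    glrlm_rlnn = sum(pr^2) / nr^2,
    glrlm_rp = nr / (n_voxels * attr(glrlm, "n_orientations")),
    glrlm_glv = sum(pn * (gl - mu_g)^2),
    glrlm_rv = sum(pn * (rl - mu_r)^2),
    glrlm_re = -sum(pe * log2(pe)),
    glrlm_lglre = sum(p / gl^2) / nr,
    glrlm_hglre = sum(p * gl^2) / nr,
    glrlm_srlgle = sum(p / (gl^2 * rl^2)) / nr,
    glrlm_srhgle = sum(p * gl^2 / rl^2) / nr,
    glrlm_lrlgle = sum(p * rl^2 / gl^2) / nr,
    glrlm_lrhgle = sum(p * gl^2 * rl^2) / nr)
}

#' Whole-prostate T2W texture feature vector (58)
#'
#' First-order (36), GLCM (6) and GLRLM (16) features of the min-max
#' normalized T2W volume inside the prostate mask.
#'
#' @param case a `prostate_case`.
#' @return named numeric vector of length 58.
#' @export
texture_feature_vector <- function(case) {
  nv <- normalize_gray_levels(case$t2w_volume, case$prostate_mask)
  c(first_order_features(nv),
    glcm_features(build_glcm(nv)),
    glrlm_features(build_glrlm(nv)))
}
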
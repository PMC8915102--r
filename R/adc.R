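#' Voxel-wise apparent diffusion coefficient map
#'
#' Computes `ADC(x,y,z) = ln(s0 / s_n) / (b_n - b0)` from the baseline (b = 0)
#' and a higher-b-value DW acquisition. Voxels where either signal is
#' non-positive cannot feed the logarithm and are dropped from the valid mask
#' rather than clipped.
#'
#' @param s0_volume 3D baseline signal volume.
#' @param sn_volume 3D signal volume at b-value `b_n`.
#' @param b_n the higher b-value, s/mm^2 (> `b0`).
#' @param mask logical 3D array delimiting the tissue of interest.
#' @param b0 baseline b-value, s/mm^2 (default 0).
#' @return an `adc_map`: list with `values` (mm^2/s, `NA` outside
#'   `valid_mask`), `valid_mask`, `b_value`, `b0`.
#' @export
compute_adc_map <- function(s0_volume, sn_volume, b_n, mask, b0 = 0) {
  if (b_n == b0) stop("b_n equals b0: ADC denominator is zero")
  stopifnot(b_n > b0)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask: no voxels to compute ADC on")
  if (!identical(dim(s0_volume), dim(mask)) ||
      !identical(dim(sn_volume), dim(mask)))
    stop("volumes and mask must share one grid shape")
  valid <- mask & s0_volume > 0 & sn_volume > 0
  values <- array(NA_real_, dim(mask))
  values[valid] <- log(s0_volume[valid] / sn_volume[valid]) / (b_n - b0)
  structure(list(values = values, valid_mask = valid,
                 b_value = b_n, b0 = b0),
            class = "adc_map")
}

#' Dataset-wide ADC range for the CDF grid
#'
#' Scans every case and every configured nonzero b-value and records the
#' smallest and largest valid ADC, so that all cases' CDF features live on one
#' shared grid. A degenerate range (single value) is widened symmetrically by
#' `eps`. The returned object serialises to JSON ([write_adc_range()]) so a
#' range estimated on training data can be reused on new cases.
#'
#' @param cohort list of `prostate_case` objects.
#' @param b_values nonzero b-values to scan; default: all nonzero b-values of
#'   the first case.
#' @param n_steps number of CDF grid steps (default 100).
#' @param eps widening applied to a degenerate range, mm^2/s.
#' @return an `adc_range`: list with `adc_min`, `adc_max`, `n_steps`.
#' @export
estimate_global_range <- function(cohort, b_values = NULL, n_steps = 100L,
                                  eps = 1e-6) {
  stopifnot(length(cohort) >= 1, n_steps >= 2)
  if (is.null(b_values)) {
    bs <- as.numeric(names(cohort[[1]]$dw_volumes))
    b_values <- bs[bs > 0]
  }
  lo <- Inf; hi <- -Inf
  for (cs in cohort) {
    s0 <- cs$dw_volumes[["0"]]
    for (b in b_values) {
      m <- compute_adc_map(s0, cs$dw_volumes[[as.character(b)]], b,
                           cs$prostate_mask)
      v <- m$values[m$valid_mask]
      if (length(v)) {
        lo <- min(lo, min(v)); hi <- max(hi, max(v))
      }
    }
  }
  if (!is.finite(lo)) stop("no valid ADC voxels anywhere in the cohort")
  if (hi - lo < eps) { lo <- lo - eps; hi <- hi + eps }   # degenerate range
  structure(list(adc_min = lo, adc_max = hi, n_steps = as.integer(n_steps)),
            class = "adc_range")
}

#' @rdname estimate_global_range
#' @param range an `adc_range`.
#' @param path JSON file path.
#' @export
write_adc_range <- function(range, path) {
  jsonlite::write_json(unclass(range), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname estimate_global_range
#' @export
read_adc_range <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(adc_min = x$adc_min, adc_max = x$adc_max,
                 n_steps = as.integer(x$n_steps)), class = "adc_range")
}

#' Empirical CDF of an ADC map on a fixed grid
#'
#' Entry `k` is the fraction of valid voxels with ADC at or below the k-th of
#' `n_steps` equally spaced grid values spanning `[adc_min, adc_max]`. Values
#' above `adc_max` clamp into the top step, so the final entry is always 1.
#'
#' @param adc_map an `adc_map` from [compute_adc_map()].
#' @param range an `adc_range` from [estimate_global_range()].
#' @return numeric vector of length `range$n_steps`, non-decreasing in
#'   `[0, 1]`.
#' @export
adc_cdf <- function(adc_map, range) {
  stopifnot(inherits(range, "adc_range"), range$adc_min < range$adc_max)
  v <- adc_map$values[adc_map$valid_mask]
  if (!length(v)) stop("empty valid mask: no ADC values for the CDF")
  grid <- seq(range$adc_min, range$adc_max, length.out = range$n_steps)
  cdf <- vapply(grid, function(g) mean(v <= g), 0)
  cdf[range$n_steps] <- 1          # values above adc_max clamp into top step
  cdf
}

#' Layout of the functional feature vector
#'
#' The whole-prostate functional feature set summarises the eight per-b-value
#' ADC CDFs. The default layout samples each 100-step CDF at `n_points = 15`
#' equally spaced grid indices (8 x 15 = 120) and appends the case-level
#' in-mask ADC minimum and maximum, for 122 features in total.
#'
#' @param n_points CDF grid indices sampled per b-value.
#' @param include_extrema append case-level ADC min and max.
#' @return a `functional_layout` object.
#' @export
functional_layout <- function(n_points = 15L, include_extrema = TRUE) {
  structure(list(n_points = as.integer(n_points),
                 include_extrema = include_extrema),
            class = "functional_layout")
}

#' Functional (ADC-CDF) feature vector for one case
#'
#' @param case a `prostate_case`.
#' @param range shared `adc_range`.
#' @param layout a [functional_layout()].
#' @param b_values the nonzero b-values the case must provide (default: the
#'   acquisition protocol's eight); a missing one is an error naming it.
#' @return named numeric vector (length 122 under the defaults).
#' @export
functional_feature_vector <- function(case, range,
                                      layout = functional_layout(),
                                      b_values = c(100, 200, 300, 400, 500,
                                                   600, 700, 1400)) {
  stopifnot(all(b_values > 0))
  s0 <- case$dw_volumes[["0"]]
  if (is.null(s0)) stop("missing b-value: 0 (baseline)")
  idx <- unique(round(seq(1, range$n_steps, length.out = layout$n_points)))
  out <- c(); adc_all <- c()
  for (b in b_values) {
    sn <- case$dw_volumes[[as.character(b)]]
    if (is.null(sn)) stop("missing b-value: ", b)
    m <- compute_adc_map(s0, sn, b, case$prostate_mask)
    cdf <- adc_cdf(m, range)[idx]
    names(cdf) <- sprintf("fn_b%04d_cdf%03d", b, idx)
    out <- c(out, cdf)
    adc_all <- c(adc_all, range(m$values[m$valid_mask]))
  }
  if (layout$include_extrema)
    out <- c(out, fn_adc_min = min(adc_all), fn_adc_max = max(adc_all))
  out
}
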
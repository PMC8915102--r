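make_vols <- function(d = c(4, 4, 4), s0 = 500, sn = 500) {
  list(s0 = array(s0, d), sn = array(sn, d), mask = array(TRUE, d))
}

test_that("compute_adc_map inverts the mono-exponential analytically", {
  v <- make_vols()
  m <- compute_adc_map(v$s0, v$sn, 700, v$mask)
  expect_equal(unique(as.vector(m$values)), 0)       # ln(1) = 0

  v <- make_vols(s0 = 1000, sn = 1000 * exp(-1))
  m <- compute_adc_map(v$s0, v$sn, 1000, v$mask)
  expect_equal(as.vector(m$values), rep(1.0e-3, 64), tolerance = 1e-12)
})

test_that("non-positive signals are excluded from the valid mask, not clipped", {
  v <- make_vols()
  v$sn[2, 3, 1] <- 0
  v$s0[1, 1, 2] <- -5
  m <- compute_adc_map(v$s0, v$sn, 500, v$mask)
  expect_false(m$valid_mask[2, 3, 1])
  expect_false(m$valid_mask[1, 1, 2])
  expect_equal(sum(m$valid_mask), 62)
  expect_true(all(is.finite(m$values[m$valid_mask])))
})

test_that("compute_adc_map agrees with a scalar per-voxel loop", {
  set.seed(42)
  for (rep in 1:5) {
    d <- c(4, 4, 4)
    s0 <- array(runif(64, 0, 1000), d)
    sn <- array(runif(64, -10, 800), d)
    mask <- array(runif(64) > 0.3, d)
    m <- compute_adc_map(s0, sn, 700, mask)
    oracle <- brute_adc(s0, sn, 700, mask)
    expect_equal(which(!is.na(oracle)), which(m$valid_mask))
    expect_equal(m$values[m$valid_mask], oracle[!is.na(oracle)],
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs error as specified", {
  v <- make_vols()
  expect_error(compute_adc_map(v$s0, v$sn, 0, v$mask), "denominator")
  expect_error(compute_adc_map(v$s0, v$sn, 700, array(FALSE, c(4, 4, 4))),
               "empty mask")
})

test_that("estimate_global_range brackets all valid voxels", {
  # two noiseless phantoms with distinct constant ADCs
  c1 <- generate_cohort(noiseless_config(adc = 0.7e-3, seed = 1))[[1]]
  c2 <- generate_cohort(noiseless_config(adc = 1.6e-3, seed = 2))[[1]]
  rng <- estimate_global_range(list(c1, c2))
  expect_equal(rng$adc_min, 0.7e-3, tolerance = 1e-9)
  expect_equal(rng$adc_max, 1.6e-3, tolerance = 1e-9)
  # monotonicity: adding a case can only widen the range
  c3 <- generate_cohort(noiseless_config(adc = 1.0e-3, seed = 3))[[1]]
  rng3 <- estimate_global_range(list(c1, c2, c3))
  expect_lte(rng3$adc_min, rng$adc_min)
  expect_gte(rng3$adc_max, rng$adc_max)
})

test_that("a degenerate range is widened symmetrically", {
  c1 <- generate_cohort(noiseless_config(adc = 1.0e-3, seed = 1))[[1]]
  rng <- estimate_global_range(list(c1))
  expect_equal(rng$adc_min, 1.0e-3 - 1e-6, tolerance = 1e-12)
  expect_equal(rng$adc_max, 1.0e-3 + 1e-6, tolerance = 1e-12)
})

test_that("adc_range serializes and restores through JSON", {
  rng <- estimate_global_range(cohort_small()[1:2])
  path <- withr::local_tempfile(fileext = ".json")
  write_adc_range(rng, path)
  back <- read_adc_range(path)
  expect_equal(back$adc_min, rng$adc_min)
  expect_equal(back$adc_max, rng$adc_max)
  expect_identical(back$n_steps, rng$n_steps)
})

test_that("adc_cdf is a step function for a point mass and a ramp for uniform", {
  d <- c(5, 5, 4)
  rng <- structure(list(adc_min = 0, adc_max = 2e-3, n_steps = 100L),
                   class = "adc_range")
  mk_map <- function(vals) {
    structure(list(values = array(vals, d), valid_mask = array(TRUE, d),
                   b_value = 700, b0 = 0), class = "adc_map")
  }
  cdf <- adc_cdf(mk_map(1e-3), rng)           # point mass at the midpoint
  grid <- seq(0, 2e-3, length.out = 100)
  expect_equal(cdf, as.numeric(grid >= 1e-3))
  set.seed(1)
  vals <- runif(prod(d), 0, 2e-3)
  cdf <- adc_cdf(mk_map(vals), rng)
  ecdf_direct <- vapply(grid, function(g) mean(sort(vals) <= g), 0)
  expect_equal(cdf, ecdf_direct)              # identical to sorting-based ECDF
  expect_true(all(diff(cdf) >= 0))
  expect_equal(cdf[100], 1)
})

test_that("adc_cdf handles boundary configurations", {
  d <- c(3, 3, 3)
  rng2 <- structure(list(adc_min = 0, adc_max = 1e-3, n_steps = 2L),
                    class = "adc_range")
  vals <- array(c(rep(0, 10), rep(5e-4, 17)), d)
  m <- structure(list(values = vals, valid_mask = array(TRUE, d)),
                 class = "adc_map")
  expect_equal(adc_cdf(m, rng2), c(10 / 27, 1))
  # values above adc_max clamp into the top step
  m$values[] <- 2e-3
  expect_equal(adc_cdf(m, rng2), c(0, 1))
})

test_that("functional feature vector has the default 122-feature layout", {
  cs <- cohort_small()[[1]]
  rng <- estimate_global_range(cohort_small())
  fv <- functional_feature_vector(cs, rng)
  expect_length(fv, 122)
  expect_false(anyDuplicated(names(fv)) > 0)
  # deterministic: identical input, identical output
  expect_identical(fv, functional_feature_vector(cs, rng))
  # CDF entries in [0, 1] and non-decreasing within each b-value block
  cdf_part <- fv[grep("cdf", names(fv))]
  expect_true(all(cdf_part >= 0 & cdf_part <= 1))
  for (b in c(100, 200, 1400)) {
    blk <- fv[grep(sprintf("b%04d", b), names(fv))]
    expect_true(all(diff(blk) >= 0))
  }
})

test_that("a missing b-value is reported by name", {
  cs <- cohort_small()[[1]]
  rng <- estimate_global_range(cohort_small())
  cs$dw_volumes[["400"]] <- NULL
  expect_error(functional_feature_vector(cs, rng), "400")
})

test_that("the malignant CDF dominates the benign CDF pointwise", {
  # constant-ADC noiseless phantoms at the two class means
  ben <- generate_cohort(noiseless_config(adc = 1.8e-3, seed = 1))[[1]]
  mal <- generate_cohort(noiseless_config(adc = 0.9e-3, seed = 1))[[1]]
  rng <- estimate_global_range(list(ben, mal))
  fb <- functional_feature_vector(ben, rng)
  fm <- functional_feature_vector(mal, rng)
  cdf_idx <- grep("cdf", names(fb))
  expect_true(all(fm[cdf_idx] >= fb[cdf_idx]))  # lower ADC reaches 1 earlier
  expect_gt(sum(fm[cdf_idx] > fb[cdf_idx]), 0)
})

test_that("noiseless phantoms recover the generator's diffusivity at every b-value", {
  D <- 1.3e-3
  cs <- generate_cohort(noiseless_config(adc = D, seed = 5))[[1]]
  for (b in c(100, 200, 300, 400, 500, 600, 700, 1400)) {
    m <- compute_adc_map(cs$dw_volumes[["0"]], cs$dw_volumes[[as.character(b)]],
                         b, cs$prostate_mask)
    expect_equal(median(m$values[m$valid_mask]), D, tolerance = 1e-9)
  }
})
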
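norm_from_levels <- function(lev, mask = NULL) {
  # build a norm_volume directly from integer levels (bypassing scaling)
  if (is.null(mask)) mask <- array(TRUE, dim(lev))
  l <- array(NA_integer_, dim(lev))
  l[mask] <- as.integer(lev[mask])
  structure(list(levels = l, mask = mask), class = "norm_volume")
}

test_that("gray-level normalization maps the in-mask range onto 0..255", {
  d <- c(3, 3, 2)
  vol <- array(10, d); vol[1, 1, 1] <- 20
  nv <- normalize_gray_levels(vol, array(TRUE, d))
  expect_equal(nv$levels[1, 1, 1], 255L)
  expect_equal(nv$levels[2, 2, 2], 0L)

  vol <- array(0, d); vol[1, 1, 1] <- 510; vol[1, 2, 1] <- 255
  nv <- normalize_gray_levels(vol, array(TRUE, d))
  expect_equal(nv$levels[1, 2, 1], 127L)      # floor(255 * 255 / 510)

  nv <- normalize_gray_levels(array(7, d), array(TRUE, d))
  expect_true(all(nv$levels == 0L))           # constant volume convention
  expect_error(normalize_gray_levels(vol, array(FALSE, d)), "empty mask")
})

test_that("first-order roster has 36 stable features with correct moments", {
  lev <- array(c(0, 0, 255, 255), c(4, 1, 1))
  fo <- first_order_features(norm_from_levels(lev))
  expect_length(fo, 36)
  expect_equal(unname(fo["fo_mean"]), 127.5)
  expect_equal(unname(fo["fo_median"]), 127.5)
  expect_equal(unname(fo["fo_variance"]), 16256.25)   # population variance
  expect_equal(unname(fo["fo_descriptive_mean"]), 127.5)
  expect_equal(unname(fo["fo_n_obs"]), 4)

  const <- first_order_features(norm_from_levels(array(0L, c(3, 3, 3))))
  expect_equal(unname(const["fo_variance"]), 0)
  expect_equal(unname(const["fo_sd"]), 0)
  expect_equal(unname(const["fo_entropy"]), 0)
  expect_equal(unname(const[grep("fo_p", names(const))]),
               rep(0, 10))                    # all percentiles equal
  expect_true(all(is.finite(const)))
})

test_that("GLCM matches the brute-force 26-offset scanner exactly", {
  set.seed(7)
  # random small volumes with few levels
  for (rep in 1:6) {
    d <- sample(2:4, 3, replace = TRUE)
    lev <- array(sample(0:3, prod(d), replace = TRUE), d)
    mask <- array(runif(prod(d)) > 0.2, d)
    if (sum(mask) < 2) next
    got <- build_glcm(norm_from_levels(lev, mask), normalize = FALSE)
    expect_equal(unclass(got), brute_glcm(norm_from_levels(lev, mask)$levels),
                 ignore_attr = TRUE)
  }
  # exhaustive sweep of all 2x2x2 binary volumes
  for (code in 0:255) {
    lev <- array(as.integer(intToBits(code)[1:8]), c(2, 2, 2))
    got <- build_glcm(norm_from_levels(lev), normalize = FALSE)
    expect_equal(unclass(got), brute_glcm(norm_from_levels(lev)$levels),
                 ignore_attr = TRUE)
  }
})

test_that("GLCM is 256x256, normalized to one, and symmetric", {
  nv <- normalize_gray_levels(cohort_small()[[1]]$t2w_volume,
                              cohort_small()[[1]]$prostate_mask)
  g <- build_glcm(nv)
  expect_equal(dim(g), c(256L, 256L))
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_equal(unclass(g), t(unclass(g)))
})

test_that("GLCM features match hand-computed values on degenerate matrices", {
  const <- build_glcm(norm_from_levels(array(5L, c(3, 3, 3))))
  f <- glcm_features(const)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_asm"]), 1)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 1)  # zero-variance convention

  # mass 1/2 at (0,255) and 1/2 at (255,0)
  p <- matrix(0, 256, 256); p[1, 256] <- 0.5; p[256, 1] <- 0.5
  g <- structure(p, normalized = TRUE, class = "glcm")
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_contrast"]), 255^2)
  expect_equal(unname(f["glcm_dissimilarity"]), 255)
  expect_length(f, 6)
})

test_that("GLRLM matches hand enumeration and the brute-force scanner", {
  # single X-run of 5 voxels at level 7
  lev <- array(7L, c(5, 1, 1))
  p <- build_glrlm(norm_from_levels(lev), orientations = "x")
  expect_equal(unclass(p)[8, 5], 1)
  expect_equal(sum(p), 1)

  # row [3, 3, 9, 3]: runs (3,2), (9,1), (3,1)
  lev <- array(c(3L, 3L, 9L, 3L), c(4, 1, 1))
  p <- build_glrlm(norm_from_levels(lev), orientations = "x")
  expect_equal(unclass(p)[4, 2], 1)
  expect_equal(unclass(p)[10, 1], 1)
  expect_equal(unclass(p)[4, 1], 1)
  expect_equal(sum(p), 3)

  set.seed(3)
  for (rep in 1:5) {
    d <- c(4, 4, 4)
    lev <- array(sample(0:3, prod(d), replace = TRUE), d)
    mask <- array(runif(prod(d)) > 0.15, d)
    got <- unclass(build_glrlm(norm_from_levels(lev, mask)))
    want <- brute_glrlm(norm_from_levels(lev, mask)$levels)
    expect_equal(got[, seq_len(ncol(want)), drop = FALSE], want,
                 ignore_attr = TRUE)
  }
})

test_that("total run length mass equals in-mask voxels per orientation", {
  nv <- normalize_gray_levels(cohort_small()[[2]]$t2w_volume,
                              cohort_small()[[2]]$prostate_mask)
  n_vox <- sum(nv$mask)
  for (or in c("x", "z")) {
    p <- unclass(build_glrlm(nv, orientations = or))
    rl <- matrix(seq_len(ncol(p)), nrow(p), ncol(p), byrow = TRUE)
    expect_equal(sum(p * rl), n_vox)
  }
})

test_that("GLRLM features match two-term hand computations", {
  # runs p(1,1) = 1 and p(1,4) = 1
  p <- matrix(0, 256, 4); p[2, 1] <- 1; p[2, 4] <- 1
  g <- structure(p, n_voxels = 5, n_orientations = 1, class = "glrlm")
  f <- glrlm_features(g)
  expect_length(f, 16)
  expect_equal(unname(f["glrlm_sre"]), (1 + 1 / 16) / 2)    # 0.53125
  expect_equal(unname(f["glrlm_lre"]), (1 + 16) / 2)        # 8.5
  expect_equal(unname(f["glrlm_rp"]), 2 / 5)

  # single run of length 1, one voxel, one orientation: RP = 1
  p1 <- matrix(0, 256, 1); p1[3, 1] <- 1
  g1 <- structure(p1, n_voxels = 1, n_orientations = 1, class = "glrlm")
  f1 <- glrlm_features(g1)
  expect_equal(unname(f1["glrlm_rp"]), 1)
  expect_equal(unname(f1["glrlm_sre"]), 1)
  expect_equal(unname(f1["glrlm_lre"]), 1)
})

test_that("texture vector is 58 long, deterministic and finite", {
  cs <- cohort_small()[[1]]
  tv <- texture_feature_vector(cs)
  expect_length(tv, 58)
  expect_length(grep("^fo_", names(tv)), 36)
  expect_length(grep("^glcm_", names(tv)), 6)
  expect_length(grep("^glrlm_", names(tv)), 16)
  expect_true(all(is.finite(tv)))
  expect_identical(tv, texture_feature_vector(cs))
})

test_that("malignant phantoms show higher GLCM contrast than benign", {
  coh <- generate_cohort(phantom_config(n_cases = 14, seed = 21))
  contrast <- vapply(coh, function(cs)
    texture_feature_vector(cs)[["glcm_contrast"]], 0)
  lab <- vapply(coh, `[[`, "", "label")
  expect_gt(mean(contrast[lab == "malignant"]),
            mean(contrast[lab == "benign"]))
})
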
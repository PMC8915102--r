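test_that("the real SH basis is orthonormal on the sphere", {
  # product-Gauss quadrature: uniform phi grid x Gauss-Legendre in cos(theta)
  ngl <- 24
  gl <- gauss_legendre(ngl)
  nphi <- 48
  phis <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  th <- rep(acos(gl$x), each = nphi)
  ph <- rep(phis, times = ngl)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  B <- do.call(cbind, lapply(0:5, function(l) sh_basis_block(l, th, ph)))
  G <- crossprod(B * w, B)
  expect_equal(unname(G), diag(ncol(B)), tolerance = 1e-10)
})

test_that("low-degree SH blocks match their closed forms", {
  th <- c(0.3, 1.1, 2.2); ph <- c(0.5, 2.5, 4.4)
  b0 <- sh_basis_block(0, th, ph)
  expect_equal(as.vector(b0), rep(1 / sqrt(4 * pi), 3))
  b1 <- sh_basis_block(1, th, ph)
  expect_equal(b1[, "Y1_0"], sqrt(3 / (4 * pi)) * cos(th))
  expect_equal(b1[, "Y1_+1"], sqrt(3 / (4 * pi)) * sin(th) * cos(ph))
  expect_equal(b1[, "Y1_-1"], sqrt(3 / (4 * pi)) * sin(th) * sin(ph))
})

test_that("attraction step matches a scalar evaluation of the update rule", {
  # two nodes, one neighbour link; one cycle with negligible repulsion
  p1 <- c(1, 0, 0)
  p2 <- c(cos(0.6), sin(0.6), 0)
  u <- rbind(p1, p2)
  ca1 <- 0.07; ca2 <- 0.2; cr <- 1e-12
  res <- pcarad:::ar_cycles(u, nb_idx = c(1L, 0L), nb_ptr = c(0L, 1L, 2L),
                            ca1, ca2, cr, max_cycles = 1, tol = 0)
  # hand evaluation: delta_i = CA1 * (d * ||d||^2 + CA2 * d), then unit norm
  d12 <- p2 - p1
  want1 <- p1 + ca1 * (d12 * sum(d12^2) + ca2 * d12)
  want1 <- want1 / sqrt(sum(want1^2))
  d21 <- -d12
  want2 <- p2 + ca1 * (d21 * sum(d21^2) + ca2 * d21)
  want2 <- want2 / sqrt(sum(want2^2))
  expect_equal(res$coords[1, ], want1, tolerance = 1e-9)
  expect_equal(res$coords[2, ], want2, tolerance = 1e-9)
})

test_that("every cycle keeps all nodes on the unit sphere", {
  mesh <- icosphere_mesh(2)
  set.seed(1)
  u <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.05),
                              ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  nb_ptr <- cumsum(c(0L, lengths(mesh$neighbors)))
  nb_idx <- unlist(mesh$neighbors) - 1L
  for (cyc in 1:5) {
    res <- pcarad:::ar_cycles(u, nb_idx, nb_ptr, 0.1, 0.2, 0.5,
                              max_cycles = cyc, tol = 0)
    expect_equal(sqrt(rowSums(res$coords^2)),
                 rep(1, nrow(u)), tolerance = 1e-9)
  }
})

test_that("a uniform sphere triangulation is near a fixed point", {
  mesh <- icosphere_mesh(3)
  mp <- attraction_repulsion(mesh, c(0, 0, 0))
  expect_lt(mp$mean_disp, 1e-4)
  expect_lt(max(sqrt(rowSums((mp$unit_coords - mesh$vertices)^2))), 0.05)
})

test_that("spherical mapping of a phantom lesion is fold-free and unit-norm", {
  cs <- cohort_small()[[1]]
  m <- mesh_from_mask(cs$lesion_mask, max_vertices = 700)
  mp <- attraction_repulsion(m, choose_origin(m))
  expect_equal(sqrt(rowSums(mp$unit_coords^2)),
               rep(1, nrow(mp$unit_coords)), tolerance = 1e-9)
  expect_equal(pcarad:::spherical_flips(mp$unit_coords, m$triangles), 0)
  th <- mp$angles$theta; ph <- mp$angles$phi
  expect_true(all(th >= 0 & th <= pi))
  expect_true(all(ph >= 0 & ph < 2 * pi))
  # angles consistent with the unit coordinates
  expect_equal(cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
               mp$unit_coords, tolerance = 1e-9, ignore_attr = TRUE)
})

synthetic_mapping <- function(radii_fun, n = 2500, seed = 1) {
  set.seed(seed)
  z <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi)
  th <- acos(z)
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  structure(list(unit_coords = u, angles = list(theta = th, phi = ph),
                 radii = radii_fun(th, ph), triangles = NULL),
            class = "spherical_mapping")
}

test_that("an exact sphere is captured entirely by the order-0 term", {
  mp <- synthetic_mapping(function(th, ph) rep(3.7, length(th)))
  sm <- fit_sh(mp, 10)
  expect_lt(sm$rmse0, 1e-10)
  expect_true(all(sm$reconstruction_errors < 1e-10))
  c0 <- sm$coefficients$value[sm$coefficients$degree == 0]
  expect_equal(c0, 3.7 * sqrt(4 * pi), tolerance = 1e-9)
})

test_that("a planted degree-3 coefficient is recovered to 1e-3", {
  mp <- synthetic_mapping(function(th, ph)
    1 + 0.2 * sh_basis_block(3, th, ph)[, "Y3_+2"])
  sm <- fit_sh(mp, 8)
  cf <- sm$coefficients
  planted <- cf$value[cf$degree == 3 & cf$order == 2]
  expect_equal(planted, 0.2, tolerance = 1e-3)
  others <- cf$value[!(cf$degree == 3 & cf$order == 2) & cf$degree > 0]
  expect_lt(max(abs(others)), 1e-3)
})

test_that("coefficient bookkeeping and error monotonicity hold", {
  cs <- cohort_small()[[2]]
  m <- mesh_from_mask(cs$lesion_mask, max_vertices = 600)
  mp <- attraction_repulsion(m, choose_origin(m))
  sm <- fit_sh(mp, 85)
  expect_equal(nrow(sm$coefficients), 86^2)        # (tau_max + 1)^2
  sf <- shape_feature_vector(sm)
  expect_length(sf, 85)
  expect_true(all(diff(sf) <= 1e-10))              # nested least squares
  expect_true(all(sf >= 0))
})

test_that("markers scale with the lesion and normalize to scale invariance", {
  mp <- synthetic_mapping(function(th, ph)
    2 + 0.3 * sin(2 * th) * cos(2 * ph), n = 1500)
  sm1 <- fit_sh(mp, 12)
  mp2 <- mp; mp2$radii <- 2 * mp$radii
  sm2 <- fit_sh(mp2, 12)
  expect_equal(sm2$reconstruction_errors, 2 * sm1$reconstruction_errors,
               tolerance = 1e-9)
  f1 <- shape_feature_vector(sm1, n_markers = 12, normalize = TRUE)
  f2 <- shape_feature_vector(sm2, n_markers = 12, normalize = TRUE)
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("markers are robust to 90-degree rotations of the mask", {
  mask <- ellipsoid_mask(c(26, 26, 26), c(9, 7, 5))
  rot <- aperm(mask, c(2, 1, 3))[dim(mask)[2]:1, , ]
  f1 <- lesion_shape_features(list(lesion_mask = mask), max_vertices = 900)
  f2 <- lesion_shape_features(list(lesion_mask = rot), max_vertices = 900)
  rel <- abs(f2 - f1) / pmax(abs(f1), 1e-9)
  expect_lt(max(rel[f1 > 1e-8]), 0.05)
})
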
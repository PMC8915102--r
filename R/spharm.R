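# Real orthonormal spherical harmonics and the spherical-harmonics shape
# model: attraction-repulsion spherical parameterization of the lesion
# surface followed by a nested least-squares expansion of the radius
# function, whose per-order reconstruction errors are the shape markers.

# Iterator over degree blocks of the real orthonormal SH basis, built with
# the stable normalized associated-Legendre recursions (factorial-free, so
# degrees up to ~85 and beyond stay finite). Column order within degree l:
# beta = 0, then for m = 1..l the cos (beta = +m) and sin (beta = -m) terms.
sh_basis_iterator <- function(theta, phi) {
  x <- cos(theta); s <- sin(theta)
  env <- new.env()
  env$l <- -1L
  env$P_prev <- NULL   # normalized P for degree l-1 (columns m = 0..l-1)
  env$P_prev2 <- NULL
  next_block <- function() {
    l <- env$l + 1L
    n <- length(x)
    P <- matrix(0, n, l + 1L)
    if (l == 0L) {
      P[, 1] <- 1 / sqrt(4 * pi)
    } else {
      Pp <- env$P_prev
      P[, l + 1L] <- s * sqrt((2 * l + 1) / (2 * l)) * Pp[, l]      # m = l
      P[, l] <- x * sqrt(2 * l + 1) * Pp[, l]                       # m = l-1
      if (l >= 2L) {
        Pp2 <- env$P_prev2
        for (m in 0:(l - 2L)) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[, m + 1L] <- a * (x * Pp[, m + 1L] - b * Pp2[, m + 1L])
        }
      }
    }
    env$P_prev2 <- env$P_prev
    env$P_prev <- P
    env$l <- l
    B <- matrix(0, n, 2L * l + 1L)
    cn <- character(2L * l + 1L)
    B[, 1] <- P[, 1]
    cn[1] <- sprintf("Y%d_0", l)
    if (l >= 1L) for (m in 1:l) {
      B[, 2L * m] <- sqrt(2) * P[, m + 1L] * cos(m * phi)
      B[, 2L * m + 1L] <- sqrt(2) * P[, m + 1L] * sin(m * phi)
      cn[2L * m] <- sprintf("Y%d_+%d", l, m)
      cn[2L * m + 1L] <- sprintf("Y%d_-%d", l, m)
    }
    colnames(B) <- cn
    B
  }
  next_block
}

#' Real orthonormal spherical-harmonics basis block of one degree
#'
#' @param l degree.
#' @param theta polar angles from +z, in `[0, pi]`.
#' @param phi azimuth angles from +x, in `[0, 2*pi)`.
#' @return matrix `length(theta) x (2l + 1)`; columns ordered beta = 0, +1,
#'   -1, ..., +l, -l (cos terms positive beta, sin terms negative).
#' @export
sh_basis_block <- function(l, theta, phi) {
  it <- sh_basis_iterator(theta, phi)
  B <- it()
  if (l > 0) for (k in 1:l) B <- it()
  B
}

#' Attraction-repulsion configuration
#'
#' @param C_A1,C_A2 attraction strengths (unitless).
#' @param C_R repulsion constant in `(0, 1]`; values around 0.3-0.7 trade
#'   accuracy against processing time.
#' @param max_cycles iteration cap.
#' @param displacement_tol mean per-node movement below which the relaxation
#'   is declared converged.
#' @return an `ar_config` object.
#' @export
ar_config <- function(C_A1 = 0.1, C_A2 = 0.2, C_R = 0.5,
                      max_cycles = 500L, displacement_tol = 1e-4) {
  stopifnot(C_A1 > 0, C_A2 > 0, C_R > 0, C_R <= 1, max_cycles >= 1,
            displacement_tol > 0)
  structure(list(C_A1 = C_A1, C_A2 = C_A2, C_R = C_R,
                 max_cycles = as.integer(max_cycles),
                 displacement_tol = displacement_tol),
            class = "ar_config")
}

#' Attraction-repulsion mapping of a surface mesh onto the unit sphere
#'
#' Nodes start as radial projections of the mesh vertices (relative to
#' `origin`) onto the unit sphere. Each cycle applies the attraction step
#' (each node is pulled toward its mesh neighbours with weight
#' `||d||^2 + C_A2` on the difference vector, scaled by `C_A1`), the
#' repulsion step (each node is pushed away from every other node with
#' magnitude `1/||d||`, scaled by `C_R / (2I)`), and a projection back onto
#' the unit sphere. Iteration stops at `max_cycles` or when the mean node
#' displacement drops below `displacement_tol`. The final map must be
#' fold-free: any flipped spherical triangle is an error.
#'
#' @param mesh a `surface_mesh`.
#' @param origin interior origin from [choose_origin()].
#' @param config an [ar_config()].
#' @return a `spherical_mapping`: `unit_coords` (I x 3), `angles` (`theta`,
#'   `phi`), `radii` (distance of each original vertex from the origin),
#'   `cycles`, `mean_disp`.
#' @export
attraction_repulsion <- function(mesh, origin, config = ar_config()) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(config, "ar_config"))
  v <- sweep(mesh$vertices, 2, origin)
  radii <- sqrt(rowSums(v^2))
  if (any(radii < 1e-9)) stop("origin coincides with a surface vertex")
  u0 <- v / radii
  # A handful of sliver flips in the initial projection is tolerable (the
  # relaxation unfolds them); a large fraction means the region is genuinely
  # not star-shaped from this origin.
  flipped0 <- spherical_flips(u0, mesh$triangles)
  if (flipped0 > 0.2 * nrow(mesh$triangles))
    stop("initial radial projection has ", flipped0,
         " flipped triangles; region is not star-shaped from the origin")
  nb <- mesh$neighbors
  nb_ptr <- cumsum(c(0L, lengths(nb)))
  nb_idx <- unlist(nb, use.names = FALSE) - 1L
  # Coarse meshes have O(1) edge lengths on the sphere, where the nominal
  # step sizes overshoot; on oscillation restart with the attraction
  # strength halved. Residual sliver folds after convergence are removed by
  # local Laplacian untangling (affected nodes moved to the normalized mean
  # of their neighbours).
  ca1 <- config$C_A1
  for (attempt in 1:5) {
    res <- ar_cycles(u0, nb_idx, nb_ptr, ca1, config$C_A2, config$C_R,
                     config$max_cycles, config$displacement_tol)
    u <- res$coords
    u <- untangle_folds(u, mesh$triangles, mesh$neighbors)
    nflip <- spherical_flips(u, mesh$triangles)
    converged <- res$mean_disp < max(config$displacement_tol, 1e-3)
    if (nflip == 0 && converged) break
    ca1 <- ca1 / 2
  }
  if (nflip > 0)
    stop("spherical mapping invalid: ", nflip, " flipped triangles ",
         "after attraction-repulsion")
  theta <- acos(pmin(pmax(u[, 3], -1), 1))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  structure(list(unit_coords = u, angles = list(theta = theta, phi = phi),
                 radii = radii, cycles = res$cycles,
                 mean_disp = res$mean_disp, triangles = mesh$triangles),
            class = "spherical_mapping")
}

# Local untangling: while flipped spherical triangles remain (and progress
# is being made), move their vertices to the normalized mean of their
# neighbours. Resolves isolated sliver folds left by the relaxation.
untangle_folds <- function(u, tri, neighbors, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    a <- u[tri[, 1], , drop = FALSE]
    b <- u[tri[, 2], , drop = FALSE]
    cc <- u[tri[, 3], , drop = FALSE]
    s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
         a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
         a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    bad <- which(s < 0)
    if (!length(bad)) break
    for (vi in unique(as.vector(tri[bad, ]))) {
      p <- colMeans(u[neighbors[[vi]], , drop = FALSE])
      nrm <- sqrt(sum(p^2))
      if (nrm > 1e-12) u[vi, ] <- p / nrm
    }
  }
  u
}

# Count spherical triangles with negative orientation (scalar triple product
# of the three unit node vectors).
spherical_flips <- function(u, tri) {
  a <- u[tri[, 1], , drop = FALSE]
  b <- u[tri[, 2], , drop = FALSE]
  cc <- u[tri[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
       a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(s < 0)
}

#' Spherical-harmonics expansion of the lesion radius function
#'
#' Fits `r(theta_i, phi_i)` in the real orthonormal SH basis by nested least
#' squares: degree blocks are orthogonalized sequentially (block Gram-Schmidt
#' QR with re-orthogonalization), so `reconstruction_errors[k]` is the exact
#' RMS residual of the least-squares fit of orders `0..k` and is
#' non-increasing in `k`. Basis columns that become numerically dependent
#' once the design saturates (more coefficients than vertices) are dropped
#' with coefficient 0 — a rank-revealing fallback whose dropped-column count
#' is recorded.
#'
#' @param mapping a `spherical_mapping`.
#' @param max_order maximum degree tau_max (default 85).
#' @return an `sh_model`: `coefficients` (data frame degree / order / value),
#'   `reconstruction_errors` (length `max_order`), `rmse0` (order-0
#'   residual), `mean_radius`, `n_dropped`, `max_order`.
#' @export
fit_sh <- function(mapping, max_order = 85L) {
  stopifnot(inherits(mapping, "spherical_mapping"), max_order >= 1)
  th <- mapping$angles$theta; ph <- mapping$angles$phi
  y <- mapping$radii
  I <- length(y)
  nextb <- sh_basis_iterator(th, ph)
  maxcols <- min((max_order + 1L)^2, I + 2L * max_order + 1L)
  Q <- matrix(0, I, maxcols)
  Rm <- matrix(0, maxcols, maxcols)
  qty <- numeric(maxcols)
  m <- 0L
  coef_deg <- integer(0); coef_ord <- integer(0); kept <- logical(0)
  r <- y
  errs <- numeric(max_order)
  err0 <- NA_real_
  tiny <- 1e-12 * max(1, mean(abs(y)))
  saturated <- FALSE
  for (l in 0:max_order) {
    if (saturated) {
      if (l >= 1) errs[l] <- err_last
      nb <- 2L * l + 1L
      coef_deg <- c(coef_deg, rep(l, nb))
      coef_ord <- c(coef_ord, block_orders(l))
      kept <- c(kept, rep(FALSE, nb))
      next
    }
    B <- nextb()
    norms0 <- sqrt(colSums(B^2))
    Rblock <- matrix(0, m, ncol(B))
    for (pass in 1:2) if (m > 0) {
      Qm <- Q[, seq_len(m), drop = FALSE]
      pr <- crossprod(Qm, B)
      B <- B - Qm %*% pr
      Rblock <- Rblock + pr
    }
    m0 <- m
    ords <- block_orders(l)
    for (cix in seq_len(ncol(B))) {
      b <- B[, cix]
      rloc <- numeric(m - m0)
      if (m > m0) {
        Qb <- Q[, (m0 + 1L):m, drop = FALSE]
        pr <- crossprod(Qb, b)
        b <- b - Qb %*% pr
        rloc <- as.vector(pr)
      }
      nrm <- sqrt(sum(b^2))
      coef_deg <- c(coef_deg, l); coef_ord <- c(coef_ord, ords[cix])
      if (nrm > 1e-10 * max(norms0[cix], 1e-300)) {
        m <- m + 1L
        Q[, m] <- b / nrm
        if (m0 > 0) Rm[seq_len(m0), m] <- Rblock[, cix]
        if (length(rloc)) Rm[(m0 + 1L):(m - 1L), m] <- rloc
        Rm[m, m] <- nrm
        qty[m] <- sum(Q[, m] * y)
        r <- r - Q[, m] * sum(Q[, m] * r)
        kept <- c(kept, TRUE)
      } else {
        kept <- c(kept, FALSE)
      }
    }
    e <- sqrt(mean(r^2))
    if (l == 0) err0 <- e else errs[l] <- e
    if (e < tiny || m >= I) { saturated <- TRUE; err_last <- e }
  }
  coefs <- numeric(length(kept))
  if (m > 0)
    coefs[kept] <- backsolve(Rm[seq_len(m), seq_len(m), drop = FALSE],
                             qty[seq_len(m)])
  structure(list(
    coefficients = data.frame(degree = coef_deg, order = coef_ord,
                              value = coefs),
    reconstruction_errors = errs,
    rmse0 = err0,
    mean_radius = mean(y),
    n_dropped = sum(!kept),
    max_order = as.integer(max_order)
  ), class = "sh_model")
}

# Orders beta within a degree block, matching the basis column layout.
block_orders <- function(l) {
  if (l == 0) return(0L)
  c(0L, as.vector(rbind(1:l, -(1:l))))
}

#' Shape marker vector: per-order SH reconstruction errors
#'
#' Marker `k` (k = 1..85) is the RMS radial reconstruction error of the
#' truncated series using orders `0..k`. Smooth (benign-like) lesions are
#' rebuilt by a low-order series, so their error curve collapses early;
#' complex (malignant-like) surfaces keep residual energy out to higher
#' orders.
#'
#' @param sh_model an `sh_model` fitted with `max_order >= n_markers`.
#' @param n_markers number of markers (default 85).
#' @param normalize divide by the mean radius, making markers scale
#'   invariant (default `FALSE`).
#' @return named numeric vector of length `n_markers`, non-increasing.
#' @export
shape_feature_vector <- function(sh_model, n_markers = 85L,
                                 normalize = FALSE) {
  stopifnot(inherits(sh_model, "sh_model"),
            sh_model$max_order >= n_markers)
  v <- sh_model$reconstruction_errors[seq_len(n_markers)]
  if (normalize) v <- v / sh_model$mean_radius
  names(v) <- sprintf("sh_err_%02d", seq_len(n_markers))
  v
}

#' Lesion shape markers for one case
#'
#' Convenience wrapper: mesh the lesion mask, choose the origin, run the
#' attraction-repulsion mapping, fit the SH expansion and return the 85
#' reconstruction-error markers.
#'
#' @param case a `prostate_case`.
#' @param config an [ar_config()].
#' @param max_order SH expansion order (default 85).
#' @param ... passed to [mesh_from_mask()].
#' @return named numeric vector of length `max_order`.
#' @export
lesion_shape_features <- function(case, config = ar_config(),
                                  max_order = 85L, ...) {
  mesh <- mesh_from_mask(case$lesion_mask, ...)
  origin <- choose_origin(mesh)
  mapping <- attraction_repulsion(mesh, origin, config)
  model <- fit_sh(mapping, max_order = max_order)
  shape_feature_vector(model, n_markers = max_order)
}
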
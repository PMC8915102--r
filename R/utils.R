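# Internal array utilities shared by the phantom generator and mesh extraction.

#' @useDynLib pcarad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Separable 3D Gaussian smoothing with zero padding. `sigma` in voxels,
# recycled to length 3. Kernel truncated at 3 sigma.
gauss_smooth3d <- function(vol, sigma) {
  sigma <- rep_len(sigma, 3L)
  out <- vol
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution of a 3D array along axis `ax` (zero padded), vectorised by
# shifting whole planes.
convolve_axis <- function(vol, kernel, ax) {
  d <- dim(vol)
  half <- (length(kernel) - 1L) / 2L
  acc <- array(0, d)
  for (o in seq_along(kernel)) {
    w <- kernel[o]
    s <- o - half - 1L            # shift in [-half, half]
    src <- seq_len(d[ax]) + s
    ok <- src >= 1L & src <= d[ax]
    if (!any(ok)) next
    dst <- seq_len(d[ax])[ok]
    src <- src[ok]
    idx_dst <- switch(ax,
      list(dst, TRUE, TRUE), list(TRUE, dst, TRUE), list(TRUE, TRUE, dst))
    idx_src <- switch(ax,
      list(src, TRUE, TRUE), list(TRUE, src, TRUE), list(TRUE, TRUE, src))
    acc <- do.call(`[<-`, c(list(acc), idx_dst, list(
      do.call(`[`, c(list(acc), idx_dst, list(drop = FALSE))) +
        w * do.call(`[`, c(list(vol), idx_src, list(drop = FALSE))))))
  }
  acc
}

# Label 6-connected components of a logical 3D array. Returns an integer array
# (0 = background) and the component count.
label_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  n <- 0L
  idx_all <- which(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- function(i) arrayInd(i, d)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        ok <- ci[, ax] + s >= 1L & ci[, ax] + s <= d[ax]
        if (!any(ok)) next
        nb <- cur[ok] + s * strides[ax]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- n
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  list(labels = lab, n = n)
}

# 6-neighbour binary erosion (voxels whose full 6-neighbourhood is in-mask).
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(FALSE, d)
    src <- seq_len(d[ax])
    keep <- src + s >= 1L & src + s <= d[ax]
    idx_dst <- switch(ax, list(src[keep], TRUE, TRUE),
      list(TRUE, src[keep], TRUE), list(TRUE, TRUE, src[keep]))
    idx_src <- switch(ax, list(src[keep] + s, TRUE, TRUE),
      list(TRUE, src[keep] + s, TRUE), list(TRUE, TRUE, src[keep] + s))
    shifted <- do.call(`[<-`, c(list(shifted), idx_dst,
      list(do.call(`[`, c(list(mask), idx_src, list(drop = FALSE))))))
    out <- out & shifted
  }
  out
}

# Erosion depth of every in-mask voxel (1 = boundary layer). Used to pick a
# deep interior origin for non-star-shaped lesions.
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    cur <- erode6(cur)
  }
  depth
}

# Trilinear sampling of a 3D array at fractional voxel coordinates (1-based).
# Points outside the grid clamp to the border.
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
              fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
          fy * ((1 - fx) * v011 + fx * v111))
}

# Stratified fold assignment for binary labels; returns an integer vector of
# fold ids in 1..k.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
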
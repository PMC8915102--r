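# Independent brute-force oracles, deliberately written as plain scalar loops
# so they share no code with the package implementations.

# All 26 neighbour offsets.
offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# GLCM counts by looping over every voxel and every offset.
brute_glcm <- function(levels) {
  d <- dim(levels)
  counts <- matrix(0, 256, 256)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offsets26))) {
      xx <- x + offsets26[r, 1]; yy <- y + offsets26[r, 2]
      zz <- z + offsets26[r, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      b <- levels[xx, yy, zz]
      if (is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  counts
}

# GLRLM by scanning each line / column with an explicit run loop.
brute_glrlm <- function(levels) {
  d <- dim(levels)
  runs <- list()
  scan_line <- function(vals) {
    out <- list()
    cur <- NA; len <- 0
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) out[[length(out) + 1]] <- c(cur, len)
        cur <- v; len <- 1
      }
    }
    out
  }
  for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    runs <- c(runs, scan_line(levels[, y, z]))
  for (x in seq_len(d[1])) for (y in seq_len(d[2]))
    runs <- c(runs, scan_line(levels[x, y, ]))
  if (!length(runs)) return(matrix(0, 256, 0))
  rg <- vapply(runs, `[`, 0, 1); rl <- vapply(runs, `[`, 0, 2)
  p <- matrix(0, 256, max(rl))
  for (i in seq_along(rg)) p[rg[i] + 1, rl[i]] <- p[rg[i] + 1, rl[i]] + 1
  p
}

# AUC as the Mann-Whitney concordance probability by pair counting.
brute_auc <- function(scores, labels) {
  pos <- which(labels == "malignant" | labels == 1)
  neg <- setdiff(seq_along(scores), pos)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Scalar per-voxel ADC evaluation.
brute_adc <- function(s0, sn, b, mask) {
  d <- dim(s0)
  out <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] && s0[x, y, z] > 0 && sn[x, y, z] > 0)
      out[x, y, z] <- log(s0[x, y, z] / sn[x, y, z]) / b
  }
  out
}

# Ellipsoid / ball / star masks used across tests.
mask_from_radius <- function(d, radius_fun) {
  ctr <- (d + 1) / 2
  gx <- slice.index(array(0, d), 1) - ctr[1]
  gy <- slice.index(array(0, d), 2) - ctr[2]
  gz <- slice.index(array(0, d), 3) - ctr[3]
  rr <- sqrt(gx^2 + gy^2 + gz^2)
  th <- acos(pmin(pmax(gz / pmax(rr, 1e-9), -1), 1))
  ph <- atan2(gy, gx)
  rr <= radius_fun(th, ph)
}

ball_mask <- function(d, r) mask_from_radius(d, function(th, ph) r)

ellipsoid_mask <- function(d, ax) {
  ctr <- (d + 1) / 2
  gx <- slice.index(array(0, d), 1) - ctr[1]
  gy <- slice.index(array(0, d), 2) - ctr[2]
  gz <- slice.index(array(0, d), 3) - ctr[3]
  (gx / ax[1])^2 + (gy / ax[2])^2 + (gz / ax[3])^2 <= 1
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Subdivided-icosahedron triangulation of the unit sphere, as a
# surface_mesh-shaped object (vertices already on the sphere).
icosphere_mesh <- function(subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; cc <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  nb <- vector("list", nrow(v))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  structure(list(vertices = v, triangles = f, neighbors = nb,
                 mask = NULL, voxel_spacing = c(1, 1, 1)),
            class = "surface_mesh")
}
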
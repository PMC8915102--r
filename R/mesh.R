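#' Triangulated surface mesh of a lesion mask
#'
#' Extracts a closed genus-0 isosurface at level 0.5 by marching tetrahedra.
#' The binary mask is first smoothed with a small Gaussian so the surface
#' tracks the underlying shape rather than the voxel staircase; for very
#' small lesions, where smoothing would push the whole field below the iso
#' level, the raw binary field is meshed instead. If the mesh exceeds
#' `max_vertices` it is re-extracted from a coarsened (trilinearly resampled)
#' field, which preserves closedness by construction.
#'
#' @param lesion_mask logical 3D array; must be one 6-connected component.
#' @param voxel_spacing physical voxel size, length 3 (default 1).
#' @param sigma Gaussian pre-smoothing in voxels.
#' @param max_vertices decimation target for the spherical parameterization.
#' @return a `surface_mesh`: list with `vertices` (I x 3, physical
#'   coordinates), `triangles` (index triples, consistently outward
#'   oriented), `neighbors` (per-vertex index sets), plus the source mask and
#'   spacing for origin selection.
#' @export
mesh_from_mask <- function(lesion_mask, voxel_spacing = c(1, 1, 1),
                           sigma = 0.6, max_vertices = 2000L) {
  mask <- lesion_mask > 0
  if (!any(mask)) stop("empty lesion mask")
  comp <- label_components6(mask)
  if (comp$n > 1)
    stop("lesion mask has ", comp$n,
         " 6-connected components; keep the largest before meshing")
  pad <- 2L
  d <- dim(mask)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask + 0
  if (sigma > 0) {
    sm <- gauss_smooth3d(field, sigma)
    if (max(sm) > 0.55) field <- sm       # tiny lesions keep the binary field
  }
  mesh <- mt_mesh_capped(field, max_vertices)
  v <- mesh$vertices
  v <- sweep(v, 2, c(pad, pad, pad))                 # undo padding
  v <- sweep(v, 2, voxel_spacing, `*`)
  tri <- orient_triangles(v, mesh$triangles)
  nb <- vertex_neighbors(nrow(v), tri)
  chi <- euler_characteristic(nrow(v), tri)
  if (chi != 2)
    stop("lesion surface is not genus 0 (Euler characteristic ", chi, ")")
  structure(list(vertices = v, triangles = tri, neighbors = nb,
                 mask = mask, voxel_spacing = voxel_spacing),
            class = "surface_mesh")
}

# Mesh the field; if too many vertices, resample on a coarser grid and retry,
# tracking the affine map back to the original grid coordinates.
mt_mesh_capped <- function(field, max_vertices) {
  scale <- c(1, 1, 1)      # orig = scale * (cur - 1) + 1
  repeat {
    m <- mt_isosurface(as.vector(field), dim(field), 0.5)
    if (nrow(m$vertices) == 0) stop("isosurface is empty")
    if (nrow(m$vertices) <= max_vertices) {
      m$vertices <- sweep(sweep(m$vertices, 2, 1), 2, scale, `*`) + 1
      return(m)
    }
    d <- dim(field)
    h <- sqrt(nrow(m$vertices) / max_vertices) * 1.05
    new_d <- pmax(6L, ceiling(d / h))
    g <- as.matrix(expand.grid(
      x = seq(1, d[1], length.out = new_d[1]),
      y = seq(1, d[2], length.out = new_d[2]),
      z = seq(1, d[3], length.out = new_d[3])))
    field <- array(trilinear_sample(field, g), new_d)
    scale <- scale * (d - 1) / pmax(new_d - 1, 1)
  }
}

# Consistent outward orientation: propagate across shared edges, then flip
# globally if the signed volume is negative.
orient_triangles <- function(v, tri) {
  nt <- nrow(tri)
  if (nt == 0) stop("mesh has no triangles")
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
                 cbind(tri[, 3], tri[, 1]))
  keys <- ekey(edges[, 1], edges[, 2])
  tid <- rep(seq_len(nt), 3)
  by_edge <- split(seq_along(keys), keys)
  done <- logical(nt)
  flip <- logical(nt)
  queue <- 1L; done[1] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    o <- if (flip[cur]) tri[cur, c(1, 3, 2)] else tri[cur, ]
    dir_edges <- rbind(o[c(1, 2)], o[c(2, 3)], o[c(3, 1)])
    for (r in 1:3) {
      k <- ekey(dir_edges[r, 1], dir_edges[r, 2])
      for (slot in by_edge[[k]]) {
        other <- tid[slot]
        if (other == cur || done[other]) next
        oo <- if (flip[other]) tri[other, c(1, 3, 2)] else tri[other, ]
        other_dir <- rbind(oo[c(1, 2)], oo[c(2, 3)], oo[c(3, 1)])
        same <- any(other_dir[, 1] == dir_edges[r, 1] &
                    other_dir[, 2] == dir_edges[r, 2])
        if (same) flip[other] <- !flip[other]   # must traverse opposite ways
        done[other] <- TRUE
        queue <- c(queue, other)
      }
    }
  }
  tri[flip, ] <- tri[flip, c(1, 3, 2), drop = FALSE]
  vol6 <- sum(vapply(seq_len(nt), function(i) {
    a <- v[tri[i, 1], ]; b <- v[tri[i, 2], ]; cc <- v[tri[i, 3], ]
    det(rbind(a, b, cc))
  }, 0))
  if (vol6 < 0) tri <- tri[, c(1, 3, 2)]
  tri
}

vertex_neighbors <- function(nv, tri) {
  nb <- vector("list", nv)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  nb
}

euler_characteristic <- function(nv, tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nv - nrow(e) + nrow(tri)
}

#' Mesh surface area
#' @param mesh a `surface_mesh`.
#' @return total triangle area in physical units.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tri <- mesh$triangles
  a <- v[tri[, 2], ] - v[tri[, 1], ]
  b <- v[tri[, 3], ] - v[tri[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Choose the expansion origin inside a lesion surface
#'
#' Default: centroid of the in-mask voxels, verified to lie strictly inside
#' the mesh. If the region is not star-shaped enough for the centroid to be
#' interior (e.g. a crescent), falls back to the deepest interior voxel by
#' erosion depth.
#'
#' @param mesh a `surface_mesh` from [mesh_from_mask()].
#' @return numeric 3-vector in the mesh's physical coordinates.
#' @export
choose_origin <- function(mesh) {
  idx <- which(mesh$mask, arr.ind = TRUE)
  centroid <- colMeans(idx) * mesh$voxel_spacing
  if (point_in_mesh(centroid, mesh)) return(unname(centroid))
  depth <- erosion_depth(mesh$mask)
  ord <- order(depth[mesh$mask], decreasing = TRUE)
  for (k in ord[seq_len(min(20, length(ord)))]) {
    p <- idx[k, ] * mesh$voxel_spacing
    if (point_in_mesh(p, mesh)) return(unname(p))
  }
  stop("no interior origin found: region has an empty kernel at voxel scale")
}

# Ray casting along +x with Moeller-Trumbore; odd crossing count = inside.
point_in_mesh <- function(p, mesh) {
  v <- mesh$vertices; tri <- mesh$triangles
  v0 <- v[tri[, 1], , drop = FALSE]
  e1 <- v[tri[, 2], , drop = FALSE] - v0
  e2 <- v[tri[, 3], , drop = FALSE] - v0
  # ray direction (1, eps1, eps2): tilt slightly to dodge edge-on hits
  dir <- c(1, 1e-4, 2e-4)
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > 1e-12
  s1 <- p[1] - v0[, 1]; s2 <- p[2] - v0[, 2]; s3 <- p[3] - v0[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  vv <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / a
  t <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  hits <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & t > 1e-9
  sum(hits, na.rm = TRUE) %% 2 == 1
}
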
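# Shared small helpers: label codes, world/voxel coordinate conversions,
# trilinear sampling. Conventions used throughout the package:
#   * voxel indices are 0-based; world = origin + (index + 0.5) * voxel_size
#     (voxel centers); axes x = lateral, y = anterior, z = superior.
#   * lengths in mm, pressures/moduli in kPa.

#' Tissue label codes
#'
#' Integer codes used in every labelmap handled by the package.
#'
#' @format Named integer vector: background = 0, bone = 1, fat = 2,
#'   muscle = 3, bulbus = 4, temporalis = 5.
#' @export
TISSUE_LABELS <- c(background = 0L, bone = 1L, fat = 2L, muscle = 3L,
                   bulbus = 4L, temporalis = 5L)

# labels that deform elastically (bone and temporalis are rigid obstacles)
DEFORMABLE_LABELS <- c(2L, 3L, 4L)

# boundary facet tags
FACET_TAGS <- c("LATERAL_WALL", "FLOOR_WALL", "MEDIAL_WALL", "ROOF_WALL",
                "APEX_FIXED", "ANTERIOR_FREE")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' World coordinates of voxel centers
#'
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @param voxel_size voxel edge length (mm).
#' @param origin world position (mm) of the corner of voxel (0,0,0).
#' @return n x 3 matrix of world coordinates (mm).
#' @keywords internal
voxel_to_world <- function(idx, voxel_size, origin) {
  sweep((idx + 0.5) * voxel_size, 2L, origin, `+`)
}

#' @rdname voxel_to_world
#' @param pts n x 3 matrix of world coordinates.
#' @keywords internal
world_to_voxel <- function(pts, voxel_size, origin) {
  sweep(pts, 2L, origin, `-`) / voxel_size - 0.5
}

# Axis coordinate vectors of voxel centers for a grid.
grid_axes <- function(dim, voxel_size, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 0.5) * voxel_size)
}

# Sample a 3D array at fractional 0-based voxel coordinates by trilinear
# interpolation; coordinates outside the grid are clamped to the border.
trilinear <- function(arr, vox) {
  d <- dim(arr)
  cl <- function(x, n) pmin(pmax(x, 0), n - 1)
  x <- cl(vox[, 1L], d[1L]); y <- cl(vox[, 2L], d[2L]); z <- cl(vox[, 3L], d[3L])
  x0 <- pmin(floor(x), d[1L] - 2L); y0 <- pmin(floor(y), d[2L] - 2L)
  z0 <- pmin(floor(z), d[3L] - 2L)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i + 1L, j + 1L, k + 1L)]
  i0 <- as.integer(x0); j0 <- as.integer(y0); k0 <- as.integer(z0)
  at(i0, j0, k0)             * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i0 + 1L, j0, k0)      * fx       * (1 - fy) * (1 - fz) +
    at(i0, j0 + 1L, k0)      * (1 - fx) * fy       * (1 - fz) +
    at(i0 + 1L, j0 + 1L, k0) * fx       * fy       * (1 - fz) +
    at(i0, j0, k0 + 1L)      * (1 - fx) * (1 - fy) * fz +
    at(i0 + 1L, j0, k0 + 1L) * fx       * (1 - fy) * fz +
    at(i0, j0 + 1L, k0 + 1L) * (1 - fx) * fy       * fz +
    at(i0 + 1L, j0 + 1L, k0 + 1L) * fx  * fy       * fz
}

# Nearest-neighbour label lookup at world points; returns 0 outside the grid.
label_at <- function(volume, pts) {
  vox <- world_to_voxel(pts, volume$voxel_size, volume$origin)
  idx <- round(vox)
  d <- dim(volume$labels)
  inside <- idx[, 1L] >= 0 & idx[, 1L] < d[1L] &
    idx[, 2L] >= 0 & idx[, 2L] < d[2L] &
    idx[, 3L] >= 0 & idx[, 3L] < d[3L]
  out <- integer(nrow(pts))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE] + 1L
    out[inside] <- volume$labels[ii]
  }
  out
}

# Separable box blur (mean filter) of a 3D array, k passes of radius 1.
box_blur3 <- function(arr, passes = 2L) {
  d <- dim(arr)
  for (p in seq_len(passes)) {
    for (a in 1:3) {
      lo <- arr; hi <- arr
      n <- d[a]
      idx_lo <- c(1L, seq_len(n - 1L)); idx_hi <- c(seq_len(n - 1L) + 1L, n)
      if (a == 1L) { lo <- arr[idx_lo, , , drop = FALSE]; hi <- arr[idx_hi, , , drop = FALSE] }
      if (a == 2L) { lo <- arr[, idx_lo, , drop = FALSE]; hi <- arr[, idx_hi, , drop = FALSE] }
      if (a == 3L) { lo <- arr[, , idx_lo, drop = FALSE]; hi <- arr[, , idx_hi, drop = FALSE] }
      arr <- (lo + arr + hi) / 3
    }
  }
  arr
}

# Exact squared Euclidean distance transform (separable min-convolution),
# vectorised across scanlines: D[i] = min_k ((i-k)^2 + G[k]).  O(n^2) per
# axis but fully vectorised, which is fast at labelmap sizes.
squared_edt <- function(mask) {
  d <- dim(mask)
  G <- array(ifelse(mask, 0, 1e12), dim = d)
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    A <- aperm(G, perm)
    da <- dim(A)
    n <- da[1]
    Am <- matrix(A, nrow = n)
    D <- matrix(Inf, nrow = n, ncol = ncol(Am))
    for (k in seq_len(n)) {
      shift2 <- (seq_len(n) - k)^2
      D <- pmin(D, shift2 + rep(Am[k, ], each = n))
    }
    A <- array(D, dim = da)
    G <- aperm(A, order(perm))
  }
  G
}

# Signed distance (voxel units, negative inside) to the boundary of a
# logical mask, evaluated at voxel centres.
signed_distance <- function(mask) {
  din <- sqrt(squared_edt(!mask))    # distance of inside voxels to outside
  dout <- sqrt(squared_edt(mask))
  # half-voxel shift puts the zero level midway between the phases
  ifelse(mask, -(din - 0.5), dout - 0.5)
}

# Signed tet volume for node coordinate matrices (n x 3 each), right-handed
# ordering convention: positive when (b-a, c-a, d-a) is a right-handed frame.
tet_volume_signed <- function(a, b, c, d) {
  u <- b - a; v <- c - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# Triangle areas and (unnormalised) normals for coordinate matrices.
tri_normal <- function(a, b, c) {
  u <- b - a; v <- c - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

tri_area <- function(a, b, c) {
  n <- tri_normal(a, b, c)
  sqrt(rowSums(n^2)) / 2
}

row_norms <- function(m) sqrt(rowSums(m^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
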
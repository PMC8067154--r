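# Independent geometric oracles used across the suite. These never call
# the code paths they check.

# Exact doubled area gain between the elevated-contour ellipse and the
# original ellipse, from the antiderivative of sqrt(1 - u^2):
# F(u) = (u*sqrt(1-u^2) + asin(u)) / 2.
closed_form_new_area <- function(h, k, a = 65, b = 75) {
  Fu <- function(u) (u * sqrt(1 - u^2) + asin(u)) / 2
  b_h <- b * sqrt(1 - h^2 / a^2)
  a_h <- a + k - h
  2 * (a_h * b_h * Fu(1) - a * b * (Fu(1) - Fu(h / a)))
}

# Maximal elevation height by one-dimensional root finding on the
# perimeter-ratio equation: the elevated ellipse's (approximate) arc
# must be exactly `ext` mm longer than the original's.
scalp_K_root_oracle <- function(a, b, X, ext = 4.1, pic = pi) {
  per <- function(K) 2 * pic * (b + K) + 4 * (a - b - K)
  stats::uniroot(function(K) (X + ext) / X - per(K) / per(0),
                 c(0, 1e4), tol = 1e-12)$root
}

# Brute-force voxel-counting volume of a closed triangle mesh: vertical
# rays through voxel centres, ray/triangle crossings by barycentric
# point-in-triangle on the xy projection, parity counting of voxel
# z-centres between crossings. Grid offset dodges edge-exact hits.
voxel_volume_oracle <- function(mesh, voxel = 1) {
  v <- mesh$vertices
  f <- mesh$faces
  x <- matrix(v[f, 1], ncol = 3)
  y <- matrix(v[f, 2], ncol = 3)
  z <- matrix(v[f, 3], ncol = 3)
  off <- 0.376  # fractional grid offset, avoids edge-on-ray ties
  gx0 <- min(x) - voxel; gy0 <- min(y) - voxel; gz0 <- min(z) - voxel
  cx0 <- ceiling((apply(x, 1, min) - gx0) / voxel - off)
  cx1 <- floor((apply(x, 1, max) - gx0) / voxel - off)
  cy0 <- ceiling((apply(y, 1, min) - gy0) / voxel - off)
  cy1 <- floor((apply(y, 1, max) - gy0) / voxel - off)
  nx <- pmax(0L, cx1 - cx0 + 1L)
  ny <- pmax(0L, cy1 - cy0 + 1L)
  nxy <- nx * ny
  keep <- nxy > 0
  tri <- rep(which(keep), nxy[keep])
  local <- sequence(nxy[keep]) - 1L
  ix <- cx0[tri] + local %% nx[tri]
  iy <- cy0[tri] + local %/% nx[tri]
  px <- gx0 + (ix + off) * voxel
  py <- gy0 + (iy + off) * voxel
  d <- (x[tri, 2] - x[tri, 1]) * (y[tri, 3] - y[tri, 1]) -
       (x[tri, 3] - x[tri, 1]) * (y[tri, 2] - y[tri, 1])
  w2 <- ((px - x[tri, 1]) * (y[tri, 3] - y[tri, 1]) -
         (py - y[tri, 1]) * (x[tri, 3] - x[tri, 1])) / d
  w3 <- ((py - y[tri, 1]) * (x[tri, 2] - x[tri, 1]) -
         (px - x[tri, 1]) * (y[tri, 2] - y[tri, 1])) / d
  w1 <- 1 - w2 - w3
  ok <- abs(d) > 1e-12 & w1 >= 0 & w2 >= 0 & w3 >= 0
  zc <- w1[ok] * z[tri, 1][ok] + w2[ok] * z[tri, 2][ok] +
    w3[ok] * z[tri, 3][ok]
  col <- ix[ok] * 1e6 + iy[ok]
  cnt <- 0L
  for (zz in split(zc, col)) {
    zz <- sort(zz)
    if (length(zz) %% 2 != 0) next  # grazing hit; skip the column
    lo <- zz[seq(1, length(zz), by = 2)]
    hi <- zz[seq(2, length(zz), by = 2)]
    # voxel z-centres (k + off) * voxel + gz0 inside (lo, hi)
    cnt <- cnt + sum(floor((hi - gz0) / voxel - off) -
                       ceiling((lo - gz0) / voxel - off) + 1)
  }
  cnt * voxel^3 / 1000  # cm^3
}

# analytic outer-ellipse radius at polar angle theta
ellipse_radius <- function(theta, a, b) {
  1 / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

# small reusable phantoms (built once per test run)
tiny_defect_spec <- function(grid = 192L, half = 0.7) {
  phantom_spec(
    n_slices = ellipsoid_n_slices(50, 2.5),
    semi_axes = ellipsoid_profile(45, 55, 50, 2.5, floor_mm = 8),
    grid = grid, fov_mm = 300, slice_thickness = 2.5, bone_thickness = 6,
    defect = defect_spec("right", -half, half, slice_range = c(12, 30)))
}
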
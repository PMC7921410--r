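#' Viewing orientation
#'
#' ZYZ Euler angles in degrees (`alpha` about z, then `beta` about the new
#' y, then `gamma` about the new z), counterclockwise when viewed from the
#' positive axis. The volume is actively rotated by the composed matrix and
#' then integrated along the z axis of the rotated frame.
#'
#' @param alpha,beta,gamma Angles in degrees; finite.
#' @return An object of class `orientation`.
#' @export
orientation <- function(alpha = 0, beta = 0, gamma = 0) {
  e <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(e))) stop("Euler angles must be finite")
  structure(list(euler = e), class = "orientation")
}

# Rotation matrix for ZYZ Euler angles in degrees: R = Rz(a) Ry(b) Rz(g).
euler_zyz_matrix <- function(alpha, beta, gamma) {
  rz <- function(t) {
    c <- cos(t * pi / 180); s <- sin(t * pi / 180)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    c <- cos(t * pi / 180); s <- sin(t * pi / 180)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Trilinear interpolation of a 3D array at continuous 0-based indices,
# zero outside the grid. xi, yi, zi are equal-length vectors.
sample_trilinear <- function(a, xi, yi, zi) {
  d <- dim(a)
  i0 <- floor(xi); j0 <- floor(yi); k0 <- floor(zi)
  fx <- xi - i0; fy <- yi - j0; fz <- zi - k0
  out <- numeric(length(xi))
  gather <- function(i, j, k) {
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    v <- numeric(length(i))
    idx <- i[ok] + j[ok] * d[1] + k[ok] * d[1] * d[2] + 1
    v[ok] <- a[idx]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
         (if (dk) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- gather(i0 + di, j0 + dj, k0 + dk)
      out <- out + w * v
    }
  }
  out
}

# Bilinear interpolation of a matrix at continuous 0-based indices,
# zero outside.
sample_bilinear <- function(a, xi, yi) {
  d <- dim(a)
  i0 <- floor(xi); j0 <- floor(yi)
  fx <- xi - i0; fy <- yi - j0
  gather <- function(i, j) {
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1
    v <- numeric(length(i))
    idx <- i[ok] + j[ok] * d[1] + 1
    v[ok] <- a[idx]
    v
  }
  (1 - fx) * (1 - fy) * gather(i0,     j0) +
  fx       * (1 - fy) * gather(i0 + 1, j0) +
  (1 - fx) * fy       * gather(i0,     j0 + 1) +
  fx       * fy       * gather(i0 + 1, j0 + 1)
}

# Rotate (counterclockwise in (x, y) index coordinates, about the centre
# pixel floor(N/2)) then shift a pixel matrix, bilinear, zero fill.
transform_pixels <- function(px, dx = 0, dy = 0, theta_deg = 0) {
  d <- dim(px)
  cx <- floor(d[1] / 2); cy <- floor(d[2] / 2)
  X <- rep(seq_len(d[1]) - 1L, times = d[2])
  Y <- rep(seq_len(d[2]) - 1L, each = d[1])
  u <- X - dx - cx; v <- Y - dy - cy
  t <- -theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  xs <- ct * u - st * v + cx
  ys <- st * u + ct * v + cy
  matrix(sample_bilinear(px, xs, ys), d[1], d[2])
}

#' Project a density volume along the viewing axis
#'
#' Actively rotates the volume by the ZYZ Euler angles of `orient`
#' (trilinear interpolation about the centre voxel `floor(N/2)`, zero
#' outside the box) and sums along z. Pixel values are summed densities, so
#' the image pixel sum equals the volume voxel sum up to interpolation
#' losses at the box boundary (within 1% for phantoms with a 3-sigma
#' interior margin). The resulting pixel size equals the voxel size.
#'
#' @param volume A `density_volume` from [build_phantom()].
#' @param orient An [orientation()].
#' @return An [em_image()].
#' @export
#' @examples
#' vol <- build_phantom(mediator_phantom())
#' img <- project(vol, orientation(30, 45, 10))
project <- function(volume, orient = orientation()) {
  stopifnot(inherits(volume, "density_volume"))
  if (!inherits(orient, "orientation")) stop("orient must be an orientation()")
  a <- volume$data
  if (any(!is.finite(a))) stop("volume contains non-finite voxels")
  d <- dim(a)
  if (all(orient$euler == 0)) {  # identity view: plain sum along z
    img <- matrix(rowSums(matrix(a, nrow = d[1] * d[2], ncol = d[3])),
                  d[1], d[2])
    return(em_image(img, volume$voxel_size))
  }
  R <- euler_zyz_matrix(orient$euler[1], orient$euler[2], orient$euler[3])
  ctr <- floor(d / 2)
  # rotated volume V'(p) = V(R^T (p - ctr) + ctr); sample all voxels at once
  X <- rep(seq_len(d[1]) - 1L, times = d[2] * d[3]) - ctr[1]
  Y <- rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]) - ctr[2]
  Z <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2]) - ctr[3]
  Rt <- t(R)
  xs <- Rt[1, 1] * X + Rt[1, 2] * Y + Rt[1, 3] * Z + ctr[1]
  ys <- Rt[2, 1] * X + Rt[2, 2] * Y + Rt[2, 3] * Z + ctr[2]
  zs <- Rt[3, 1] * X + Rt[3, 2] * Y + Rt[3, 3] * Z + ctr[3]
  vals <- sample_trilinear(a, xs, ys, zs)
  img <- matrix(rowSums(matrix(vals, nrow = d[1] * d[2], ncol = d[3])),
                d[1], d[2])
  em_image(img, volume$voxel_size)
}
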
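#' Projection image
#'
#' A 2D real image of the projected potential, `integral dz U(R r' )`,
#' sampled at pixel centers `(i - n/2) * pixel_size` (0-based index i).
#'
#' @param pixels 2D numeric array (ny x nx).
#' @param pixel_size Pixel edge in Angstrom.
#' @return A `projection_image` object.
#' @export
projection_image <- function(pixels, pixel_size) {
  if (length(dim(pixels)) != 2) stopf("pixels must be a 2D array")
  if (!all(is.finite(pixels))) stopf("pixels must be finite")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<projection_image> %d x %d at %.3f A/px\n", d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Fourier slice
#'
#' The centered 2D spectrum of a projection, either computed directly from a
#' projection image or extracted from the central plane of a 3D spectrum.
#'
#' @param coefficients 2D complex array on the centered (qx, qy) grid.
#' @param pixel_size Real-space pixel size in Angstrom.
#' @param n_clipped Count of requested frequencies that fell outside the
#'   source volume's Nyquist box and were zeroed.
#' @return A `fourier_slice` object.
#' @export
fourier_slice <- function(coefficients, pixel_size, n_clipped = 0L) {
  if (length(dim(coefficients)) != 2) stopf("coefficients must be a 2D array")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(list(coefficients = coefficients, pixel_size = pixel_size,
                 n_clipped = as.integer(n_clipped)),
            class = "fourier_slice")
}

#' Analytic projection of a Gaussian mixture
#'
#' Integrating an isotropic 3D Gaussian along the lab z-axis leaves a 2D
#' Gaussian: each center contributes
#' `a_i (2 pi b_i)^(-1) exp(-((x - u_i)^2 + (y - v_i)^2) / (2 b_i))`
#' where `(u_i, v_i)` are the first two components of the actively rotated
#' center `R c_i`. In-plane translation is *not* applied here; it is applied
#' in Fourier space by [simulate_image()].
#'
#' @param vol A [gaussian_mixture_volume()].
#' @param rot A [rotation()] (or pose; its translation is ignored).
#' @param shape Length-2 integer `(ny, nx)`, both even.
#' @param pixel_size Angstrom per pixel.
#' @return A [projection_image()]. Pixels are indexed `[y, x]`.
#' @export
project_gmm_analytic <- function(vol, rot, shape, pixel_size) {
  stopifnot(inherits(vol, "gaussian_mixture_volume"))
  if (inherits(rot, "cryosim_pose")) rot <- pose_rotation(rot)
  shape <- as.integer(rep_len(shape, 2))
  check_even_shape(shape)
  rc <- apply_rotation(rot, vol$centers)
  xs <- centered_coords(shape[2], pixel_size)
  ys <- centered_coords(shape[1], pixel_size)
  img <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(rc))) {
    b <- vol$variances[i]
    a <- vol$amplitudes[i] / (2 * pi * b)
    gy <- exp(-(ys - rc[i, 2])^2 / (2 * b))
    gx <- exp(-(xs - rc[i, 1])^2 / (2 * b))
    img <- img + a * outer(gy, gx)
  }
  projection_image(img, pixel_size)
}

#' Extract a central Fourier slice
#'
#' Implements the Fourier slice theorem: the 2D transform of the projection
#' along the rotated z-axis is the central plane `{R^-1 (qx, qy, 0)}` of the
#' 3D spectrum. The plane is sampled by trilinear interpolation on the
#' centered frequency grid; requested frequencies outside the volume's
#' Nyquist box are set to zero and counted in `n_clipped`.
#'
#' @param vol A [fourier_voxel_volume()].
#' @param rot A [rotation()] describing the active rotation of the volume.
#' @param shape Length-2 `(ny, nx)`, both even, each `<=` the volume side.
#' @return A [fourier_slice()] at the volume's voxel size.
#' @export
extract_fourier_slice <- function(vol, rot, shape = NULL) {
  stopifnot(inherits(vol, "fourier_voxel_volume"))
  if (inherits(rot, "cryosim_pose")) rot <- pose_rotation(rot)
  n <- dim(vol$grid)[1]
  if (is.null(shape)) shape <- c(n, n)
  shape <- as.integer(rep_len(shape, 2))
  check_even_shape(shape)
  if (any(shape > n)) stopf("slice shape must not exceed the volume side")
  Rinv <- rotation_to_matrix(invert_rotation(rot))
  # Slice frequencies in cycles/A; convert to continuous 0-based grid index
  # offsets from the spectrum center (spacing 1/(n*voxel_size) per index).
  qx <- centered_freqs(shape[2], vol$voxel_size)
  qy <- centered_freqs(shape[1], vol$voxel_size)
  pts <- cbind(rep(qx, each = shape[1]), rep(qy, times = shape[2]), 0)
  rp <- pts %*% t(Rinv) * (n * vol$voxel_size)  # index units, center-origin
  idx <- rp + (n %/% 2L)                        # 0-based array index
  vals <- trilinear_complex(vol$grid, idx)
  slice <- matrix(vals$values, shape[1], shape[2])
  fourier_slice(slice, vol$voxel_size, n_clipped = vals$n_clipped)
}

# Trilinear interpolation of a complex 3D array at continuous 0-based indices
# (M x 3). Out-of-range points are zeroed and counted.
trilinear_complex <- function(grid, idx) {
  n <- dim(grid)
  i0 <- floor(idx)
  f <- idx - i0
  # points landing exactly on the upper grid face still have a valid cell
  for (d in 1:3) {
    hit <- i0[, d] == n[d] - 1 & f[, d] == 0
    i0[hit, d] <- n[d] - 2
    f[hit, d] <- 1
  }
  inside <- i0[, 1] >= 0 & i0[, 1] <= n[1] - 2 &
    i0[, 2] >= 0 & i0[, 2] <= n[2] - 2 &
    i0[, 3] >= 0 & i0[, 3] <= n[3] - 2
  out <- complex(length.out = nrow(idx))
  if (any(inside)) {
    a <- i0[inside, , drop = FALSE] + 1L  # 1-based corner
    fx <- f[inside, 1]; fy <- f[inside, 2]; fz <- f[inside, 3]
    g <- function(dx, dy, dz) {
      grid[cbind(a[, 1] + dx, a[, 2] + dy, a[, 3] + dz)]
    }
    out[inside] <-
      g(0L, 0L, 0L) * (1 - fx) * (1 - fy) * (1 - fz) +
      g(1L, 0L, 0L) * fx * (1 - fy) * (1 - fz) +
      g(0L, 1L, 0L) * (1 - fx) * fy * (1 - fz) +
      g(0L, 0L, 1L) * (1 - fx) * (1 - fy) * fz +
      g(1L, 1L, 0L) * fx * fy * (1 - fz) +
      g(1L, 0L, 1L) * fx * (1 - fy) * fz +
      g(0L, 1L, 1L) * (1 - fx) * fy * fz +
      g(1L, 1L, 1L) * fx * fy * fz
  }
  list(values = out, n_clipped = sum(!inside))
}

#' Projection image from a Fourier slice
#'
#' Inverse-transforms an extracted slice back to real space; scaled by the
#' voxel size so values match a z-line-integral (sum along z times voxel
#' size) of the originating volume.
#'
#' @param slice A [fourier_slice()].
#' @return A [projection_image()].
#' @export
projection_from_slice <- function(slice) {
  stopifnot(inherits(slice, "fourier_slice"))
  img <- Re(cifft(slice$coefficients)) * slice$pixel_size
  projection_image(img, slice$pixel_size)
}

#' Brute-force real-space projection oracle
#'
#' Reference implementation used for testing: rotates voxel sampling
#' coordinates by `R^-1`, resamples the volume with trilinear interpolation,
#' sums along z and multiplies by the voxel size. Quadratic-to-cubic cost;
#' intended for small test volumes.
#'
#' @param vol A [real_voxel_volume()].
#' @param rot A [rotation()] (active rotation of the volume).
#' @param shape Length-2 `(ny, nx)`; defaults to the volume side.
#' @return A [projection_image()].
#' @export
project_real_space_oracle <- function(vol, rot, shape = NULL) {
  stopifnot(inherits(vol, "real_voxel_volume"))
  if (inherits(rot, "cryosim_pose")) rot <- pose_rotation(rot)
  n <- dim(vol$grid)[1]
  if (is.null(shape)) shape <- c(n, n)
  shape <- as.integer(rep_len(shape, 2))
  check_even_shape(shape)
  Rinv <- rotation_to_matrix(invert_rotation(rot))
  half <- n %/% 2L
  # Lab-frame sample points (x, y, z) in index units about the center; the
  # rotated volume at lab point r equals the original volume at R^-1 r.
  xs <- seq_len(shape[2]) - 1 - shape[2] %/% 2L
  ys <- seq_len(shape[1]) - 1 - shape[1] %/% 2L
  zs <- seq_len(n) - 1 - half
  img <- matrix(0, shape[1], shape[2])
  pts_xy <- cbind(rep(xs, each = shape[1]), rep(ys, times = shape[2]))
  cgrid <- vol$grid + 0i
  for (z in zs) {
    lab <- cbind(pts_xy, z)
    body <- lab %*% t(Rinv) + half
    v <- trilinear_complex(cgrid, body)$values
    img <- img + matrix(Re(v), shape[1], shape[2])
  }
  projection_image(img * vol$voxel_size, vol$voxel_size)
}
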
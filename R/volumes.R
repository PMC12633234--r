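#' Gaussian-mixture representation of an atomic potential
#'
#' Represents a molecule's electrostatic potential as a sum of isotropic 3D
#' Gaussians, one per center (typically one per atom, or one per C-alpha in a
#' coarse-grained model). Each Gaussian is normalized to unit integral before
#' scaling by its amplitude, so the total integrated potential equals the sum
#' of the amplitudes.
#'
#' @param centers N x 3 matrix of Gaussian center positions in Angstrom.
#' @param amplitudes Length-N nonnegative amplitudes (arbitrary potential
#'   units), or a scalar recycled to all centers.
#' @param variances Length-N positive variances in Angstrom^2, or a scalar.
#' @return A `gaussian_mixture_volume` object.
#' @examples
#' gmm <- gaussian_mixture_volume(matrix(0, 1, 3), amplitudes = 1, variances = 1)
#' evaluate_gmm(gmm, matrix(0, 1, 3))  # (2*pi)^(-3/2)
#' @export
gaussian_mixture_volume <- function(centers, amplitudes = 1, variances = 1) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3 || nrow(centers) < 1)
    stopf("centers must be an N x 3 matrix with N >= 1")
  if (!all(is.finite(centers))) stopf("centers must be finite")
  n <- nrow(centers)
  amplitudes <- rep_len(as.numeric(amplitudes), n)
  variances <- rep_len(as.numeric(variances), n)
  if (any(amplitudes < 0)) stopf("amplitudes must be >= 0")
  if (any(variances <= 0)) stopf("variances must be > 0")
  structure(list(centers = unname(centers), amplitudes = amplitudes,
                 variances = variances),
            class = "gaussian_mixture_volume")
}

#' @export
print.gaussian_mixture_volume <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_volume> %d centers, total amplitude %.4g\n",
              nrow(x$centers), sum(x$amplitudes)))
  invisible(x)
}

#' Real-space voxel volume
#'
#' A cubic grid of real potential values with its voxel size. The real-space
#' origin is pinned at 0-based voxel index `side/2` along each axis (the
#' FFT-center convention), which fixes the rotation center for projections.
#'
#' @param grid Cubic 3D numeric array with even side length.
#' @param voxel_size Voxel edge length in Angstrom.
#' @return A `real_voxel_volume` object.
#' @export
real_voxel_volume <- function(grid, voxel_size) {
  d <- dim(grid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stopf("grid must be a cubic 3D array")
  check_even_shape(d)
  if (!is.numeric(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
  structure(list(grid = grid, voxel_size = voxel_size),
            class = "real_voxel_volume")
}

#' @export
print.real_voxel_volume <- function(x, ...) {
  cat(sprintf("<real_voxel_volume> %d^3 voxels at %.3f A\n",
              dim(x$grid)[1], x$voxel_size))
  invisible(x)
}

#' Fourier voxel volume
#'
#' The centered discrete Fourier transform of a cubic real-space volume,
#' stored with zero frequency at 0-based index `side/2` on each axis. Because
#' it is the transform of a real volume, the grid is Hermitian:
#' `F(-k) = Conj(F(k))`.
#'
#' @param grid Cubic 3D complex array (centered spectrum).
#' @param voxel_size Real-space voxel size in Angstrom of the originating
#'   volume (frequency spacing is `1/(side * voxel_size)`).
#' @return A `fourier_voxel_volume` object.
#' @export
fourier_voxel_volume <- function(grid, voxel_size) {
  d <- dim(grid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stopf("grid must be a cubic 3D array")
  check_even_shape(d)
  if (!is.numeric(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
  structure(list(grid = grid, voxel_size = voxel_size),
            class = "fourier_voxel_volume")
}

#' @export
print.fourier_voxel_volume <- function(x, ...) {
  cat(sprintf("<fourier_voxel_volume> %d^3 coefficients, %.3f A voxels\n",
              dim(x$grid)[1], x$voxel_size))
  invisible(x)
}

#' Evaluate a Gaussian mixture at points
#'
#' The potential at a point p is
#' `sum_i a_i (2 pi b_i)^(-3/2) exp(-|p - c_i|^2 / (2 b_i))`
#' with amplitudes `a_i`, centers `c_i` and variances `b_i`.
#'
#' @param vol A [gaussian_mixture_volume()].
#' @param points M x 3 matrix of evaluation points in Angstrom.
#' @return Length-M numeric vector of potential values.
#' @export
evaluate_gmm <- function(vol, points) {
  stopifnot(inherits(vol, "gaussian_mixture_volume"))
  points <- as.matrix(points)
  if (ncol(points) != 3) stopf("points must be an M x 3 matrix")
  if (!all(is.finite(points))) stopf("points must be finite")
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (points[i, 1] - vol$centers[, 1])^2 +
      (points[i, 2] - vol$centers[, 2])^2 +
      (points[i, 3] - vol$centers[, 3])^2
    out[i] <- sum(vol$amplitudes * (2 * pi * vol$variances)^(-1.5) *
                    exp(-d2 / (2 * vol$variances)))
  }
  out
}

#' Rasterize a Gaussian mixture onto a voxel grid
#'
#' Samples [evaluate_gmm()] at voxel centers `(i - side/2) * voxel_size`
#' (0-based index i). For mixtures that are well contained and resolved by the
#' grid (`sigma >= 2 * voxel_size`, centers well inside the box) the Riemann
#' sum `sum(grid) * voxel_size^3` approximates the total amplitude to within
#' about 1%. Centers outside the box raise a warning (their mass is clipped),
#' not an error.
#'
#' @param vol A [gaussian_mixture_volume()].
#' @param side Even number of voxels per axis.
#' @param voxel_size Voxel edge in Angstrom.
#' @return A [real_voxel_volume()].
#' @export
rasterize_gmm <- function(vol, side, voxel_size) {
  stopifnot(inherits(vol, "gaussian_mixture_volume"))
  side <- as.integer(side)
  check_even_shape(side)
  if (voxel_size <= 0) stopf("voxel_size must be > 0")
  x <- centered_coords(side, voxel_size)
  half <- max(abs(range(x)))
  if (any(abs(vol$centers) > half))
    warning("some Gaussian centers lie outside the voxel box; mass is clipped",
            call. = FALSE)
  grid <- array(0, dim = c(side, side, side))
  # separable accumulation: one outer product per Gaussian
  for (i in seq_len(nrow(vol$centers))) {
    b <- vol$variances[i]
    a <- vol$amplitudes[i] * (2 * pi * b)^(-1.5)
    gx <- exp(-(x - vol$centers[i, 1])^2 / (2 * b))
    gy <- exp(-(x - vol$centers[i, 2])^2 / (2 * b))
    gz <- exp(-(x - vol$centers[i, 3])^2 / (2 * b))
    grid <- grid + a * outer(outer(gx, gy), gz)
  }
  real_voxel_volume(grid, voxel_size)
}

#' Fourier transform of a real voxel volume
#'
#' Forward (unnormalized) centered FFT: the zero-frequency coefficient equals
#' the sum of the voxel values and sits at 0-based index `side/2` on each
#' axis. The output is Hermitian because the input is real. An integer `pad`
#' factor zero-pads the real volume (about its center) to `pad * side`
#' before transforming, which samples the spectrum more finely and reduces
#' interpolation error in central-slice extraction at the cost of memory.
#'
#' @param vol A [real_voxel_volume()].
#' @param pad Integer oversampling factor (1 = no padding).
#' @return A [fourier_voxel_volume()].
#' @export
fourier_from_real <- function(vol, pad = 1L) {
  stopifnot(inherits(vol, "real_voxel_volume"))
  pad <- as.integer(pad)
  if (pad < 1) stopf("pad must be a positive integer")
  grid <- vol$grid
  if (pad > 1) {
    n <- dim(grid)[1]
    np <- pad * n
    big <- array(0, dim = rep(np, 3))
    off <- (np - n) %/% 2L
    big[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <- grid
    grid <- big
  }
  fourier_voxel_volume(cfft(grid), vol$voxel_size)
}

#' Inverse transform of a Fourier voxel volume
#'
#' @param vol A [fourier_voxel_volume()].
#' @return A [real_voxel_volume()] (imaginary residue discarded).
#' @export
real_from_fourier <- function(vol) {
  stopifnot(inherits(vol, "fourier_voxel_volume"))
  real_voxel_volume(Re(cifft(vol$grid)), vol$voxel_size)
}
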
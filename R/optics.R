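#' Contrast transfer function parameters
#'
#' Holds everything needed to evaluate the aberration function chi and the
#' CTF `sin(chi)` on a frequency grid, in the CTFFIND-style astigmatic
#' defocus model. On entry the defocus pair is canonicalized so that
#' `defocus_u >= defocus_v` (swapping rotates the astigmatism angle by 90
#' degrees) and the angle is wrapped to `[0, 180)`. Positive defocus means
#' underfocus.
#'
#' @param defocus_u,defocus_v Defocus along the two principal astigmatism
#'   axes, in Angstrom.
#' @param astig_angle Azimuth of the `defocus_u` axis in degrees.
#' @param cs Spherical aberration in mm.
#' @param voltage Accelerating voltage in kV.
#' @param amplitude_contrast Amplitude-contrast fraction `w` in `[0, 1)`.
#' @param phase_shift Additional phase shift (phase plate) in degrees.
#' @return A `ctf_params` object.
#' @examples
#' p <- ctf_params(defocus_u = 10000, defocus_v = 10000, voltage = 300)
#' @export
ctf_params <- function(defocus_u = 10000, defocus_v = defocus_u,
                       astig_angle = 0, cs = 0, voltage = 300,
                       amplitude_contrast = 0, phase_shift = 0) {
  if (!is.finite(voltage) || voltage <= 0) stopf("voltage must be > 0 kV")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stopf("amplitude_contrast must lie in [0, 1)")
  if (defocus_u < defocus_v) {
    tmp <- defocus_u; defocus_u <- defocus_v; defocus_v <- tmp
    astig_angle <- astig_angle + 90
  }
  astig_angle <- astig_angle %% 180
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, cs = cs, voltage = voltage,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(
    "<ctf_params> df = (%.0f, %.0f) A @ %.1f deg, Cs = %.2f mm, %g kV, w = %.3f\n",
    x$defocus_u, x$defocus_v, x$astig_angle, x$cs, x$voltage,
    x$amplitude_contrast))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' `lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2)))`, in Angstrom.
#' At 300 kV this is about 0.0197 A.
#'
#' @param voltage Accelerating voltage in kV.
#' @return Wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage) {
  if (!is.finite(voltage) || voltage <= 0) stopf("voltage must be > 0 kV")
  h <- 6.62607015e-34    # J s
  m0 <- 9.1093837015e-31 # kg
  e <- 1.602176634e-19   # C
  c <- 299792458         # m/s
  V <- voltage * 1000
  lam_m <- h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2)))
  lam_m * 1e10
}

#' Centered 2D frequency grid
#'
#' Spatial frequencies for an even image shape at a given pixel size, laid
#' out to match the centered spectra used throughout the package: frequency
#' `k/(n * pixel_size)` at 0-based index `k + n/2`, so the maximum magnitude
#' per axis is the Nyquist frequency `1/(2 * pixel_size)`.
#'
#' @param shape Length-2 `(ny, nx)`, both even.
#' @param pixel_size Angstrom per pixel.
#' @return A `frequency_grid_2d`: list of matrices `qx`, `qy` (1/Angstrom),
#'   indexed `[y, x]` like the image.
#' @export
frequency_grid_2d <- function(shape, pixel_size) {
  shape <- as.integer(rep_len(shape, 2))
  check_even_shape(shape)
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  fx <- centered_freqs(shape[2], pixel_size)
  fy <- centered_freqs(shape[1], pixel_size)
  structure(list(qx = matrix(fx, shape[1], shape[2], byrow = TRUE),
                 qy = matrix(fy, shape[1], shape[2]),
                 pixel_size = pixel_size, shape = shape),
            class = "frequency_grid_2d")
}

#' Defocus-only aberration phase
#'
#' The defocus term of the aberration function,
#' `chi(q) = -pi * lambda * defocus * |q|^2`, in radians.
#'
#' @param q A [frequency_grid_2d()].
#' @param defocus Defocus in Angstrom (positive = underfocus).
#' @param wavelength Electron wavelength in Angstrom.
#' @return 2D numeric array of phases, shaped like the grid.
#' @export
aberration_phase_defocus <- function(q, defocus, wavelength) {
  stopifnot(inherits(q, "frequency_grid_2d"))
  -pi * wavelength * defocus * (q$qx^2 + q$qy^2)
}

#' Astigmatic aberration phase
#'
#' CTFFIND-style astigmatic defocus plus spherical aberration and phase
#' shift:
#' `chi(q, phi) = -pi lambda df(phi) |q|^2 + (pi/2) Cs lambda^3 |q|^4 + ps`
#' with `df(phi) = (du + dv)/2 + (du - dv)/2 * cos(2 (phi - astig_angle))`
#' and `phi` the polar angle of `q`. Reduces exactly to
#' [aberration_phase_defocus()] when `du = dv`, `Cs = 0` and the phase shift
#' is zero.
#'
#' @param q A [frequency_grid_2d()].
#' @param p A [ctf_params()].
#' @return 2D numeric array of phases in radians.
#' @export
aberration_phase_astigmatic <- function(q, p) {
  stopifnot(inherits(q, "frequency_grid_2d"), inherits(p, "ctf_params"))
  lam <- electron_wavelength(p$voltage)
  q2 <- q$qx^2 + q$qy^2
  ang <- atan2(q$qy, q$qx)
  df <- 0.5 * (p$defocus_u + p$defocus_v +
                 (p$defocus_u - p$defocus_v) *
                 cos(2 * (ang - p$astig_angle * pi / 180)))
  cs_A <- p$cs * 1e7  # mm -> Angstrom
  -pi * lam * df * q2 + (pi / 2) * cs_A * lam^3 * q2^2 +
    p$phase_shift * pi / 180
}

#' Evaluate the contrast transfer function
#'
#' `CTF = sqrt(1 - w^2) * sin(chi) + w * cos(chi)` with amplitude-contrast
#' fraction `w`; with `w = 0` this is exactly `sin(chi)`. The aberration
#' phase is supplied by a plug-in function so custom optical models can be
#' used with the rest of the pipeline: any function mapping
#' `(frequency_grid_2d, ctf_params)` to a phase array of the grid's shape
#' satisfies the contract. The default is [aberration_phase_astigmatic()].
#'
#' @param q A [frequency_grid_2d()].
#' @param p A [ctf_params()].
#' @param chi_fn Aberration-phase function `(q, p) -> 2D radians array`.
#' @param sign Global contrast sign flag (+1 or -1); downstream contrast
#'   sign is convention-dependent, so it is exposed once here.
#' @return 2D numeric array with values in `[-1, 1]`.
#' @export
evaluate_ctf <- function(q, p, chi_fn = aberration_phase_astigmatic, sign = 1) {
  stopifnot(inherits(q, "frequency_grid_2d"), inherits(p, "ctf_params"))
  if (!sign %in% c(-1, 1)) stopf("sign must be +1 or -1")
  chi <- chi_fn(q, p)
  if (!is.numeric(chi) || !identical(dim(chi), dim(q$qx)))
    stopf("chi_fn must return a numeric array of the grid's shape")
  w <- p$amplitude_contrast
  sign * (sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

#' Gaussian B-factor envelope
#'
#' Optional multiplicative damping envelope `exp(-B |q|^2 / 4)` for
#' noise-matching experiments; not part of the default image model.
#'
#' @param q A [frequency_grid_2d()].
#' @param b_factor B factor in Angstrom^2.
#' @return 2D numeric array in `(0, 1]`.
#' @export
ctf_envelope <- function(q, b_factor) {
  stopifnot(inherits(q, "frequency_grid_2d"))
  exp(-b_factor * (q$qx^2 + q$qy^2) / 4)
}
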
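#' Image configuration
#'
#' Shape, pixel size and contrast scale shared by all images of a simulated
#' stack. `sigma_e` is the electron interaction constant, the linear scale
#' relating projected electrostatic potential to phase contrast; with
#' potentials in arbitrary units it defaults to 1 and only sets the overall
#' image scale.
#'
#' @param shape Length-2 `(ny, nx)` in pixels, both even.
#' @param pixel_size Angstrom per pixel.
#' @param sigma_e Electron interaction constant (scale factor, > 0).
#' @return An `image_config` object.
#' @export
image_config <- function(shape, pixel_size, sigma_e = 1) {
  shape <- as.integer(rep_len(shape, 2))
  check_even_shape(shape)
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (!is.finite(sigma_e) || sigma_e <= 0) stopf("sigma_e must be > 0")
  structure(list(shape = shape, pixel_size = pixel_size, sigma_e = sigma_e),
            class = "image_config")
}

#' @export
print.image_config <- function(x, ...) {
  cat(sprintf("<image_config> %d x %d px at %.3f A, sigma_e = %g\n",
              x$shape[1], x$shape[2], x$pixel_size, x$sigma_e))
  invisible(x)
}

#' Translate a Fourier slice in-plane
#'
#' Multiplies the coefficients by the shift phase
#' `exp(-2 pi i (qx tx + qy ty))`; in real space this is a periodic
#' (wrap-around) shift of the projection by `(tx, ty)`.
#'
#' @param slice A [fourier_slice()].
#' @param tx,ty Translation in Angstrom.
#' @return A translated [fourier_slice()].
#' @export
apply_translation <- function(slice, tx, ty) {
  stopifnot(inherits(slice, "fourier_slice"))
  if (tx == 0 && ty == 0) return(slice)
  d <- dim(slice$coefficients)
  q <- frequency_grid_2d(d, slice$pixel_size)
  phase <- exp(-2i * pi * (q$qx * tx + q$qy * ty))
  fourier_slice(slice$coefficients * phase, slice$pixel_size, slice$n_clipped)
}

#' Simulate a cryo-EM contrast image
#'
#' The linear contrast model: project the volume along the posed z-axis
#' (analytically for Gaussian mixtures; by central-slice extraction for
#' Fourier voxel volumes, with a real voxel volume transformed on the fly),
#' translate in Fourier space, multiply by the CTF and by `sigma_e`, and
#' inverse-transform to real pixels. With `ctf = NULL` (no-CTF mode) the
#' output is `sigma_e` times the shifted projection.
#'
#' @param vol A [gaussian_mixture_volume()], [real_voxel_volume()] or
#'   [fourier_voxel_volume()].
#' @param pose A [euler_pose()] or [quaternion_pose()] (or bare rotation,
#'   meaning zero shift).
#' @param ctf A [ctf_params()], or `NULL` for no-CTF mode.
#' @param cfg An [image_config()]. For voxel volumes the pixel size must
#'   equal the voxel size.
#' @param chi_fn Aberration-phase plug-in forwarded to [evaluate_ctf()].
#' @param ctf_sign Contrast sign forwarded to [evaluate_ctf()].
#' @return A `simulated_image`: list with `pixels` (ny x nx), and the
#'   `pose`, `ctf`, `cfg` metadata used.
#' @export
simulate_image <- function(vol, pose, ctf, cfg,
                           chi_fn = aberration_phase_astigmatic,
                           ctf_sign = 1) {
  stopifnot(inherits(cfg, "image_config"))
  pose <- as_pose(pose)
  pf <- projection_spectrum(vol, pose, cfg)
  q <- frequency_grid_2d(cfg$shape, cfg$pixel_size)
  coef <- pf * exp(-2i * pi * (q$qx * pose$tx + q$qy * pose$ty))
  if (!is.null(ctf)) {
    stopifnot(inherits(ctf, "ctf_params"))
    coef <- coef * evaluate_ctf(q, ctf, chi_fn = chi_fn, sign = ctf_sign)
  }
  pixels <- Re(cifft(coef)) * cfg$sigma_e
  structure(list(pixels = pixels, pose = pose, ctf = ctf, cfg = cfg),
            class = "simulated_image")
}

# Centered 2D spectrum of the (untranslated) projection, in image units:
# cfft of the real-space projection image.
projection_spectrum <- function(vol, pose, cfg) {
  rot <- pose_rotation(pose)
  if (inherits(vol, "gaussian_mixture_volume")) {
    proj <- project_gmm_analytic(vol, rot, cfg$shape, cfg$pixel_size)
    return(cfft(proj$pixels))
  }
  if (inherits(vol, "real_voxel_volume")) vol <- fourier_from_real(vol)
  if (inherits(vol, "fourier_voxel_volume")) {
    if (abs(vol$voxel_size - cfg$pixel_size) > 1e-9)
      stopf("voxel volumes must be sampled at the image pixel size")
    slice <- extract_fourier_slice(vol, rot, cfg$shape)
    # slice * voxel_size is the centered DFT of the z-line-integral image
    return(slice$coefficients * vol$voxel_size)
  }
  stopf("unsupported volume representation: %s", class(vol)[1])
}

#' @export
print.simulated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<simulated_image> %d x %d px at %.3f A%s\n", d[1], d[2],
              x$cfg$pixel_size, if (is.null(x$ctf)) " (no CTF)" else ""))
  invisible(x)
}

#' Noise models
#'
#' `noise_model_white(variance)` is i.i.d. zero-mean Gaussian pixel noise.
#' `noise_model_colored(profile)` is a zero-mean Gaussian random field built
#' by shaping white noise in Fourier space so that its expected radially
#' averaged power spectrum follows `profile(|q|)`; the profile is expressed
#' in pixel-variance units, so a flat profile at `v` is statistically
#' identical to white noise of variance `v`.
#' `noise_profile_power_law(amplitude, exponent, offset)` is a two-parameter
#' power-law-plus-constant convenience family
#' `amplitude * |q|^(-exponent) + offset` (value at `q = 0` taken from the
#' first nonzero frequency to keep the DC power finite).
#'
#' @param variance Pixel variance (> 0).
#' @return A `noise_model` object.
#' @export
noise_model_white <- function(variance = 1) {
  if (!is.finite(variance) || variance <= 0) stopf("variance must be > 0")
  structure(list(kind = "white", variance = variance), class = "noise_model")
}

#' @rdname noise_model_white
#' @param profile Function of `|q|` (1/Angstrom) returning nonnegative power
#'   in variance units.
#' @export
noise_model_colored <- function(profile) {
  if (!is.function(profile)) stopf("profile must be a function of |q|")
  structure(list(kind = "colored", profile = profile), class = "noise_model")
}

#' @rdname noise_model_white
#' @param amplitude,exponent,offset Power-law family parameters.
#' @export
noise_profile_power_law <- function(amplitude, exponent, offset = 0) {
  force(amplitude); force(exponent); force(offset)
  function(qmag) {
    p <- amplitude * ifelse(qmag > 0, qmag^(-exponent), NA_real_) + offset
    p[is.na(p)] <- p[which(qmag > 0)[1]]
    p
  }
}

#' Sample a noise field
#'
#' White noise is drawn i.i.d. per pixel. Colored noise is white noise
#' shaped in Fourier space: coefficients are scaled by `sqrt(profile(|q|))`,
#' so the expected radially averaged power spectrum (as computed by
#' [radial_power_spectrum()]) equals `profile(|q|) * n_pixels` -- the same
#' normalization as white noise of variance `profile`. The expected pixel
#' variance of a colored field is therefore the mean of the profile over
#' the frequency grid.
#'
#' @param model A `noise_model`.
#' @param shape Length-2 `(ny, nx)`.
#' @param pixel_size Angstrom per pixel (sets the frequency scale of a
#'   colored profile).
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return 2D numeric array of noise values.
#' @export
sample_noise <- function(model, shape, pixel_size = 1, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  shape <- as.integer(rep_len(shape, 2))
  w <- with_seed(seed, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
  if (model$kind == "white") return(sqrt(model$variance) * w)
  q <- frequency_grid_2d(shape, pixel_size)
  p <- model$profile(sqrt(q$qx^2 + q$qy^2))
  if (any(!is.finite(p)) || any(p < 0))
    stopf("colored-noise profile must be finite and nonnegative")
  shaped <- cfft(w) * sqrt(p)
  Re(cifft(shaped))
}

# Expected pixel variance of a sampled noise field (used for SNR scaling).
noise_expected_variance <- function(model, shape, pixel_size = 1) {
  if (model$kind == "white") return(model$variance)
  q <- frequency_grid_2d(shape, pixel_size)
  mean(model$profile(sqrt(q$qx^2 + q$qy^2)))
}

#' Radially averaged power spectrum
#'
#' Mean of `|FT(img)|^2` (unnormalized centered DFT) over annular bins of
#' `|q|`. Binning satisfies Parseval consistency: the power-weighted bin
#' counts sum back to the total spectral energy.
#'
#' @param img 2D numeric array.
#' @param pixel_size Angstrom per pixel.
#' @param n_bins Number of annular bins (>= 2) between 0 and Nyquist.
#' @return A tibble with `q` (bin center, 1/Angstrom), `power` (mean
#'   `|FT|^2`), and `n_modes` (Fourier modes per bin).
#' @export
radial_power_spectrum <- function(img, pixel_size = 1, n_bins = NULL) {
  if (length(dim(img)) != 2) stopf("img must be a 2D array")
  d <- dim(img)
  if (is.null(n_bins)) n_bins <- min(d) %/% 2L
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  q <- frequency_grid_2d(d, pixel_size)
  qmag <- sqrt(q$qx^2 + q$qy^2)
  pw <- Mod(cfft(img))^2
  nyq <- 1 / (2 * pixel_size)
  edges <- seq(0, nyq * sqrt(2), length.out = n_bins + 1)
  bin <- pmin(findInterval(qmag, edges, rightmost.closed = TRUE), n_bins)
  power <- tapply(as.vector(pw), as.vector(bin), mean)
  count <- tapply(as.vector(pw), as.vector(bin), length)
  idx <- as.integer(names(power))
  tibble::tibble(
    q = (edges[idx] + edges[idx + 1]) / 2,
    power = as.numeric(power),
    n_modes = as.integer(count)
  )
}

#' Add noise at a target signal-to-noise ratio
#'
#' SNR is defined as the ratio of per-pixel signal variance to noise
#' variance. The sampled noise field is scaled so its variance is
#' `var(signal) / snr` in expectation, then added to the image.
#'
#' @param img A `simulated_image` or 2D numeric array.
#' @param model A `noise_model` (its own variance scale is overridden by the
#'   SNR calibration).
#' @param snr Target SNR (> 0).
#' @param seed Optional integer seed.
#' @return Same type as `img`, with noise added.
#' @export
add_noise_at_snr <- function(img, model, snr, seed = NULL) {
  pixels <- if (inherits(img, "simulated_image")) img$pixels else img
  if (!is.finite(snr) || snr <= 0) stopf("snr must be > 0")
  sv <- stats::var(as.vector(pixels))
  if (sv <= 0) stopf("signal has zero variance; SNR is undefined")
  pixel_size <- if (inherits(img, "simulated_image")) img$cfg$pixel_size else 1
  noise <- sample_noise(model, dim(pixels), pixel_size, seed = seed)
  ev <- noise_expected_variance(model, dim(pixels), pixel_size)
  noise <- noise * sqrt(sv / (snr * ev))
  if (inherits(img, "simulated_image")) {
    img$pixels <- pixels + noise
    img
  } else {
    pixels + noise
  }
}

#' Fit a radial noise profile to a target power spectrum
#'
#' Least-squares fit of the power-law-plus-constant noise family to a target
#' radial power spectrum (for example one measured from experimental
#' images), mirroring the empirical procedure of tuning noise parameters
#' until simulated and observed power spectra align. The DC bin is excluded.
#'
#' @param target A tibble from [radial_power_spectrum()] (columns `q`,
#'   `power`).
#' @param offset_floor Lower bound for the constant term.
#' @return A list with the fitted `noise_model`, the parameters
#'   `(amplitude, exponent, offset)`, and the residual sum of squares.
#' @export
fit_noise_profile <- function(target, offset_floor = 0) {
  stopifnot(all(c("q", "power") %in% names(target)))
  dat <- target[target$q > 0 & is.finite(target$power), ]
  if (nrow(dat) < 3) stopf("need at least 3 nonzero-frequency bins to fit")
  obj <- function(par) {
    amp <- exp(par[1]); ex <- par[2]; off <- offset_floor + exp(par[3])
    sum((amp * dat$q^(-ex) + off - dat$power)^2)
  }
  p0 <- c(log(max(dat$power[1], 1e-12)), 1, log(max(min(dat$power), 1e-12)))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  pars <- c(amplitude = exp(fit$par[1]), exponent = fit$par[2],
            offset = offset_floor + exp(fit$par[3]))
  list(model = noise_model_colored(
         noise_profile_power_law(pars[1], pars[2], pars[3])),
       parameters = pars, rss = fit$value)
}
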
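#' Image stack with per-image metadata
#'
#' A set of 2D real images sharing one [image_config()], with one pose and
#' one set of CTF parameters per image. This is the observed-data container
#' for refinement and the output container for batch simulation.
#'
#' @param pixels 3D numeric array `(ny, nx, n_images)`.
#' @param poses List of `cryosim_pose`, length `n_images`.
#' @param ctfs List of [ctf_params()] (length `n_images`), a single
#'   `ctf_params` recycled to all images, or `NULL` for no-CTF stacks.
#' @param cfg An [image_config()].
#' @return An `image_stack` object.
#' @export
image_stack <- function(pixels, poses, ctfs, cfg) {
  stopifnot(inherits(cfg, "image_config"))
  d <- dim(pixels)
  if (length(d) != 3) stopf("pixels must be a 3D (ny, nx, n_images) array")
  if (any(d[1:2] != cfg$shape)) stopf("image shape does not match the config")
  n <- d[3]
  if (length(poses) != n) stopf("need one pose per image")
  poses <- lapply(poses, as_pose)
  if (inherits(ctfs, "ctf_params")) ctfs <- rep(list(ctfs), n)
  if (!is.null(ctfs) && length(ctfs) != n)
    stopf("need one ctf_params per image (or a single one, or NULL)")
  structure(list(pixels = pixels, poses = poses, ctfs = ctfs, cfg = cfg),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d images of %d x %d px at %.3f A\n",
              d[3], d[1], d[2], x$cfg$pixel_size))
  invisible(x)
}

#' @export
length.image_stack <- function(x) dim(x$pixels)[3]

#' Simulate a full image stack
#'
#' Runs [simulate_image()] per pose/CTF pair and optionally adds noise at a
#' target SNR with [add_noise_at_snr()] (one independent noise field per
#' image, split deterministically from `seed`).
#'
#' @param vol A volume representation accepted by [simulate_image()].
#' @param poses List of poses.
#' @param ctfs Per-image CTFs, a single [ctf_params()], or `NULL`.
#' @param cfg An [image_config()].
#' @param noise A `noise_model`, or `NULL` for noiseless images.
#' @param snr Target per-image SNR when `noise` is given.
#' @param seed Optional integer seed for the noise.
#' @return An [image_stack()].
#' @export
simulate_stack <- function(vol, poses, ctfs, cfg, noise = NULL, snr = NULL,
                           seed = NULL) {
  n <- length(poses)
  if (inherits(ctfs, "ctf_params")) ctfs <- rep(list(ctfs), n)
  pixels <- array(0, dim = c(cfg$shape, n))
  for (i in seq_len(n)) {
    img <- simulate_image(vol, poses[[i]],
                          if (is.null(ctfs)) NULL else ctfs[[i]], cfg)
    if (!is.null(noise)) {
      if (is.null(snr)) stopf("snr must be given with a noise model")
      img <- add_noise_at_snr(img, noise, snr,
                              seed = if (is.null(seed)) NULL else seed + i)
    }
    pixels[, , i] <- img$pixels
  }
  image_stack(pixels, poses, ctfs, cfg)
}

#' Per-image metadata table
#'
#' Flattens the stack's poses and CTFs into one row per image with the
#' documented column schema: `image`, `phi`, `theta`, `psi` (degrees), `tx`,
#' `ty` (Angstrom), `defocus_u`, `defocus_v` (Angstrom), `astig_angle`
#' (degrees), `voltage` (kV), `cs` (mm), `amplitude_contrast`, `phase_shift`
#' (degrees), `pixel_size` (Angstrom).
#'
#' @param stack An [image_stack()].
#' @return A tibble with one row per image.
#' @export
stack_metadata <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack)
  rows <- lapply(seq_len(n), function(i) {
    p <- stack$poses[[i]]
    ang <- if (!is.null(p$angles)) p$angles else euler_from_rotation(p$rotation)
    ctf <- if (is.null(stack$ctfs)) {
      list(defocus_u = NA_real_, defocus_v = NA_real_, astig_angle = NA_real_,
           voltage = NA_real_, cs = NA_real_, amplitude_contrast = NA_real_,
           phase_shift = NA_real_)
    } else stack$ctfs[[i]]
    tibble::tibble(
      image = i, phi = ang[["phi"]], theta = ang[["theta"]], psi = ang[["psi"]],
      tx = p$tx, ty = p$ty,
      defocus_u = ctf$defocus_u, defocus_v = ctf$defocus_v,
      astig_angle = ctf$astig_angle, voltage = ctf$voltage, cs = ctf$cs,
      amplitude_contrast = ctf$amplitude_contrast,
      phase_shift = ctf$phase_shift,
      pixel_size = stack$cfg$pixel_size)
  })
  do.call(rbind, rows)
}

#' Rebuild poses and CTFs from a metadata table
#'
#' Inverse of [stack_metadata()]: turns the documented CSV schema back into
#' pose and CTF lists.
#'
#' @param meta A data frame with the [stack_metadata()] columns.
#' @return List with elements `poses`, `ctfs`, `pixel_size`.
#' @export
metadata_to_params <- function(meta) {
  need <- c("phi", "theta", "psi", "tx", "ty")
  if (!all(need %in% names(meta)))
    stopf("metadata table is missing pose columns: %s",
          paste(setdiff(need, names(meta)), collapse = ", "))
  poses <- lapply(seq_len(nrow(meta)), function(i)
    euler_pose(meta$phi[i], meta$theta[i], meta$psi[i], meta$tx[i], meta$ty[i]))
  ctfs <- NULL
  if ("defocus_u" %in% names(meta) && all(is.finite(meta$defocus_u))) {
    ctfs <- lapply(seq_len(nrow(meta)), function(i)
      ctf_params(defocus_u = meta$defocus_u[i], defocus_v = meta$defocus_v[i],
                 astig_angle = meta$astig_angle[i], cs = meta$cs[i],
                 voltage = meta$voltage[i],
                 amplitude_contrast = meta$amplitude_contrast[i],
                 phase_shift = meta$phase_shift[i]))
  }
  list(poses = poses, ctfs = ctfs,
       pixel_size = if ("pixel_size" %in% names(meta)) meta$pixel_size[1] else NA)
}
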
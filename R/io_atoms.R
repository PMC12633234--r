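# element symbol -> atomic number, H through Rn (enough for biomolecules)
element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, W = 74, Pt = 78,
  Au = 79, Hg = 80, Pb = 82, U = 92)

#' Read atomic records from PDB or mmCIF
#'
#' Parses coordinates with bio3d and returns one row per selected atom with
#' element, atomic number and position. `ca_only` keeps only alpha-carbons,
#' the coarse-grained representation used for Gaussian-mixture models of
#' large assemblies.
#'
#' @param path A `.pdb` or `.cif` / `.mmcif` file.
#' @param ca_only Keep only CA atoms.
#' @return A tibble with columns `element`, `atomic_number`, `x`, `y`, `z`
#'   (Angstrom), `chain`, `resno`, `atom_name`, `is_ca`.
#' @export
read_atoms <- function(path, ca_only = FALSE) {
  if (!file.exists(path)) stopf("no such coordinate file: %s", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    suppressWarnings(
      if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
      else bio3d::read.pdb(path)),
    error = function(e) stopf("could not parse %s: %s", path, conditionMessage(e)))
  at <- parsed$atom
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0)
    stopf("no atoms left in %s after filtering (ca_only = %s)", path, ca_only)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    # fall back to the first letter of the atom name
    elem <- sub("^([A-Za-z]).*", "\\1", at$elety)
  }
  elem <- sub("^(\\w)(\\w?)$", "\\1\\L\\2", trimws(elem), perl = TRUE)
  z <- unname(element_numbers[elem])
  if (any(is.na(z)))
    stopf("unknown element symbol(s): %s",
          paste(unique(elem[is.na(z)]), collapse = ", "))
  if (!all(is.finite(c(at$x, at$y, at$z)))) stopf("non-finite coordinates in %s", path)
  tibble::tibble(
    element = elem, atomic_number = as.integer(z),
    x = at$x, y = at$y, z = at$z,
    chain = at$chain, resno = at$resno, atom_name = at$elety,
    is_ca = at$elety == "CA")
}

#' Build a Gaussian mixture from atom records
#'
#' Assigns the same caller-chosen amplitude and variance to every atom
#' ("equal weight and variance"); per-atom parameters can be supplied as
#' vectors for tabulated scattering-factor models.
#'
#' @param atoms A tibble from [read_atoms()], or any data frame with `x`,
#'   `y`, `z` columns.
#' @param amplitude,variance Shared (or per-atom) Gaussian parameters.
#' @param center Subtract the centroid so the model is centered at the
#'   origin (the rotation center).
#' @return A [gaussian_mixture_volume()].
#' @export
gmm_from_atoms <- function(atoms, amplitude = 1, variance = 4, center = TRUE) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (center) xyz <- sweep(xyz, 2, colMeans(xyz))
  gaussian_mixture_volume(xyz, amplitude, variance)
}

#' Read/write Gaussian centers as CSV
#'
#' Plain-text interchange for refined coordinates: columns `x`, `y`, `z`,
#' `amplitude`, `variance`.
#'
#' @param vol A [gaussian_mixture_volume()].
#' @param path CSV path.
#' @return `write_centers_csv`: `path` invisibly; `read_centers_csv`: a
#'   [gaussian_mixture_volume()].
#' @export
write_centers_csv <- function(vol, path) {
  stopifnot(inherits(vol, "gaussian_mixture_volume"))
  df <- data.frame(x = vol$centers[, 1], y = vol$centers[, 2],
                   z = vol$centers[, 3], amplitude = vol$amplitudes,
                   variance = vol$variances)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centers_csv
#' @export
read_centers_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) stopf("centers CSV needs x, y, z columns")
  gaussian_mixture_volume(
    as.matrix(df[, need]),
    if ("amplitude" %in% names(df)) df$amplitude else 1,
    if ("variance" %in% names(df)) df$variance else 1)
}

#' Read/write the per-image metadata table as CSV
#'
#' The schema is documented in [stack_metadata()].
#'
#' @param meta A data frame in the [stack_metadata()] schema.
#' @param path CSV path.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
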
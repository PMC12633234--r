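# Centered-FFT helpers. All spectra in this package use the "FFT-center"
# convention: the real-space origin sits at 0-based index n/2 of each (even)
# axis, and the zero-frequency coefficient sits at the same index of the
# spectrum. Shifting is exact for even sides, where fftshift == ifftshift.

#' @keywords internal
fft_shift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- n %/% 2L
    c(seq_len(n - h) + h, seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @keywords internal
ifft_shift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- ceiling(n / 2)
    c(seq_len(n - h) + h, seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Forward centered FFT: unnormalized, DC at 0-based index n/2.
#' @keywords internal
cfft <- function(x) fft_shift(stats::fft(ifft_shift(x)))

# Inverse centered FFT, normalized by the number of elements.
#' @keywords internal
cifft <- function(x) fft_shift(stats::fft(ifft_shift(x), inverse = TRUE)) / length(x)

# Centered DFT frequencies in cycles per unit length for an even side n and
# sampling interval delta: k/(n*delta), k = -n/2, ..., n/2 - 1.
#' @keywords internal
centered_freqs <- function(n, delta = 1) {
  (seq_len(n) - 1 - n %/% 2L) / (n * delta)
}

# Centered real-space coordinates: (i - n/2)*delta for 0-based index i.
#' @keywords internal
centered_coords <- function(n, delta = 1) {
  (seq_len(n) - 1 - n %/% 2L) * delta
}

# Evaluate a scalar-valued RNG task under a temporary seed without disturbing
# the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
check_even_shape <- function(shape) {
  if (any(shape %% 2L != 0L))
    stopf("image/volume sides must be even, got (%s)", paste(shape, collapse = ", "))
}
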
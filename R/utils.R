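# Internal helpers shared across the package.

# Vacuum permeability, T m / A.
.mu0 <- 4e-7 * pi

# Standard gravity, m / s^2.
.g0 <- 9.80665

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}

.assert_image <- function(img, min_dim = 3L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(sprintf("image must be at least %dx%d pixels", min_dim, min_dim), call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite pixel values", call. = FALSE)
  invisible(img)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Signed centred DFT frequencies in cycles per pixel.
.fft_freq <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

# Isotropic Gaussian blur via the analytic transfer function exp(-2 pi^2 s^2 f^2).
# Periodic boundaries; exactly translation-equivariant and mean-preserving.
.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fr <- .fft_freq(nr); fc <- .fft_freq(nc)
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / (nr * nc)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)
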
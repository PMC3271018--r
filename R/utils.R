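#' Derive a child seed from a master seed
#'
#' Deterministic counter-based derivation so that pipeline stages, subjects
#' and surrogate draws each get an independent, reproducible stream. Kept
#' below 2^31 so the result is always a valid integer seed.
#'
#' @param seed master seed (single integer)
#' @param ... integer offsets identifying the consumer (stage index,
#'   subject index, surrogate index, ...)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in c(offs, 0)) {
    # LCG-style mix (Park-Miller multiplier), stays in 32-bit integer range
    x <- (x * 48271 + as.double(o) * 2654435761 + 1) %% 2147483647
  }
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Fisher z-transform and its inverse
#'
#' @param r correlation value(s) in (-1, 1)
#' @param z z value(s)
#' @return transformed values
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Phase-randomized surrogate of a multivariate time series
#'
#' Produces surrogate series that preserve each column's amplitude spectrum
#' (hence its autocorrelation and variance) exactly while destroying all
#' cross-column temporal dependence: each column's Fourier phases are
#' replaced by independent uniform draws (with the Hermitian symmetry needed
#' for a real-valued inverse transform).
#'
#' @param x numeric matrix (time x region)
#' @return matrix of the same dimension
#' @keywords internal
phase_randomize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  M <- ncol(x)
  half <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  z <- stats::mvfft(x)
  ph <- matrix(runif(n * M), n, M) * 2 * pi
  ph[1, ] <- 0                        # DC stays real
  if (n %% 2 == 0) ph[half + 1, ] <- 0  # Nyquist stays real
  idx <- 2:(half + if (n %% 2 == 0) 0 else 1)
  ph[n + 2 - idx, ] <- -ph[idx, ]     # Hermitian symmetry
  out <- Re(stats::mvfft(Mod(z) * exp(1i * ph), inverse = TRUE) / n)
  dimnames(out) <- dimnames(x)
  out
}

#' Empirical p-value with add-one correction
#'
#' `(r + 1) / (n + 1)` where `r` counts null values at least as extreme as
#' the observed statistic.
#'
#' @param stat observed statistic (scalar)
#' @param null numeric vector of null statistics
#' @param two_sided compare absolute values (default)
#' @return p-value in (0, 1]
#' @export
empirical_p <- function(stat, null, two_sided = TRUE) {
  if (two_sided) {
    r <- sum(abs(null) >= abs(stat))
  } else {
    r <- sum(null >= stat)
  }
  (r + 1) / (length(null) + 1)
}

# BH-FDR on the off-diagonal entries of an M x M p-value matrix;
# returns a matrix of q-values (diagonal NA)
fdr_offdiag <- function(p_mat) {
  M <- nrow(p_mat)
  off <- which(row(p_mat) != col(p_mat))
  q <- matrix(NA_real_, M, M, dimnames = dimnames(p_mat))
  q[off] <- p.adjust(p_mat[off], method = "BH")
  q
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stopf("`alpha` must be a single number in (0, 1), got %s",
          paste(format(alpha), collapse = ", "))
  }
  invisible(alpha)
}
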
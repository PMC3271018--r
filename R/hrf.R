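#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout the package: a difference of two gamma
#' densities with response peak at 6 s, undershoot peak at 16 s and a
#' peak-to-undershoot ratio of 6, scaled so the response peak equals 1.
#'
#' @param t numeric vector of times in seconds (>= 0; negative times give 0)
#' @return numeric vector of HRF values
#' @export
#' @examples
#' canonical_hrf(seq(0, 30, by = 0.5))
canonical_hrf <- function(t) {
  h <- ifelse(t >= 0,
              stats::dgamma(t, shape = 7, rate = 1) -
                stats::dgamma(t, shape = 17, rate = 1) / 6,
              0)
  # normalize so the continuous peak (at t = 6 s for mode (shape-1)/rate) is 1
  peak <- stats::dgamma(6, shape = 7, rate = 1) -
    stats::dgamma(6, shape = 17, rate = 1) / 6
  h / peak
}

#' Temporal derivative of the canonical HRF
#'
#' Finite-difference derivative basis: `(h(t) - h(t - delta)) / delta` with a
#' 1 s offset, the usual companion basis that absorbs small onset shifts of
#' the response.
#'
#' @param t numeric vector of times in seconds
#' @param delta finite-difference offset in seconds
#' @return numeric vector
#' @export
hrf_derivative <- function(t, delta = 1) {
  (canonical_hrf(t) - canonical_hrf(t - delta)) / delta
}

#' Build a two-basis HRF matrix on a lag grid
#'
#' Samples the canonical HRF and its temporal derivative on the lag grid
#' `(0, TR, 2 TR, ..., (n_lags - 1) TR)`. The resulting `2 x n_lags` matrix
#' is the basis \eqn{\Phi} whose rows span the region-wise HRFs in the
#' state-space observation model: region m's HRF is \eqn{b_m' \Phi} for a
#' weight vector \eqn{b_m}.
#'
#' @param TR sampling interval in seconds (> 0)
#' @param n_lags number of lags (grid length); `n_lags * TR >= 24` s is
#'   recommended so the full response and undershoot are covered
#' @return an object of class `hrf_basis`: list with `basis_matrix`
#'   (2 x n_lags, rows `canonical` and `derivative`), `TR`, `n_bases`,
#'   `n_lags`, `lag_times`, and `short_support` flag (TRUE when the grid does
#'   not reach the 6 s response peak)
#' @export
#' @examples
#' b <- build_hrf_basis(TR = 2, n_lags = 16)
#' which.max(b$basis_matrix["canonical", ])  # peak at 6 s (4th lag)
build_hrf_basis <- function(TR, n_lags) {
  if (!is.numeric(TR) || length(TR) != 1 || TR <= 0) {
    stopf("`TR` must be a single positive number")
  }
  if (!is.numeric(n_lags) || length(n_lags) != 1 || n_lags < 2) {
    stopf("`n_lags` must be a single integer >= 2")
  }
  n_lags <- as.integer(n_lags)
  lag_times <- (seq_len(n_lags) - 1) * TR
  basis <- rbind(canonical = canonical_hrf(lag_times),
                 derivative = hrf_derivative(lag_times))
  short <- max(lag_times) < 6
  if (short) {
    warnf("HRF basis support (%.1f s) does not cover the 6 s response peak",
          max(lag_times))
  }
  structure(list(basis_matrix = basis, TR = TR, n_bases = 2L,
                 n_lags = n_lags, lag_times = lag_times,
                 short_support = short),
            class = "hrf_basis")
}

#' @export
print.hrf_basis <- function(x, ...) {
  cat(sprintf("<hrf_basis> %d bases x %d lags, TR = %g s (support %g s)\n",
              x$n_bases, x$n_lags, x$TR, max(x$lag_times) + x$TR))
  invisible(x)
}
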
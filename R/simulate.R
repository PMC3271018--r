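#' Parameters of the bilinear latent state-space model
#'
#' Bundles the generative parameters of the model
#' \deqn{s(t) = \sum_j v_j(t) C_j s(t-1) + D u(t) + w(t), \quad
#'       w(t) \sim N(0, Q)}
#' \deqn{y_m(t) = b_m' \Phi x_m(t) + e_m(t), \quad
#'       e_m(t) \sim N(0, \sigma_m^2)}
#' where `s(t)` is the latent neuronal signal of M regions, the `C_j` are
#' the M x M coupling matrices active under modulatory input j (entry
#' `(m, n)` = strength of n -> m), `D` is the diagonal external-input
#' strength matrix, and `x_m(t)` holds the `L` past values of `s_m` so the
#' observation is a linear HRF convolution.
#'
#' @param modulatory_matrices list of M x M matrices (one per modulatory
#'   input); each must have spectral radius < 1
#' @param input_strengths numeric vector of length M (diagonal of D)
#' @param state_noise_cov M x M symmetric PSD matrix Q (scalar recycled to
#'   `diag(Q, M)`)
#' @param hrf_basis_weights M x B matrix of per-region basis weights
#'   (row m = b_m); default weights `(1, 0)` give every region the canonical
#'   HRF
#' @param obs_noise_var per-region observation noise variances (length M or
#'   scalar)
#' @param embedding_lags number of past latent samples L entering the
#'   convolution (>= 1)
#' @param region_names region labels
#' @return object of class `mds_params`
#' @export
mds_parameters <- function(modulatory_matrices, input_strengths,
                           state_noise_cov = 1, hrf_basis_weights = NULL,
                           obs_noise_var = 1, embedding_lags = 16L,
                           region_names = NULL) {
  if (!is.list(modulatory_matrices)) {
    modulatory_matrices <- list(modulatory_matrices)
  }
  M <- nrow(modulatory_matrices[[1]])
  for (Cj in modulatory_matrices) {
    if (!is.matrix(Cj) || nrow(Cj) != M || ncol(Cj) != M) {
      stopf("all modulatory matrices must be %d x %d", M, M)
    }
    if (spectral_radius(Cj) >= 1) {
      stopf("modulatory matrix has spectral radius >= 1; the simulated latent process would be non-stationary")
    }
  }
  if (length(input_strengths) == 1) input_strengths <- rep(input_strengths, M)
  if (length(input_strengths) != M) {
    stopf("`input_strengths` must have length %d", M)
  }
  if (length(state_noise_cov) == 1) {
    state_noise_cov <- diag(as.numeric(state_noise_cov), M)
  }
  if (max(abs(state_noise_cov - t(state_noise_cov))) > 1e-8) {
    stopf("`state_noise_cov` must be symmetric")
  }
  ev <- eigen(state_noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("`state_noise_cov` must be positive semi-definite")
  if (is.null(hrf_basis_weights)) {
    hrf_basis_weights <- cbind(rep(1, M), rep(0, M))
  }
  if (nrow(hrf_basis_weights) != M) {
    stopf("`hrf_basis_weights` must have one row per region")
  }
  if (length(obs_noise_var) == 1) obs_noise_var <- rep(obs_noise_var, M)
  if (any(obs_noise_var < 0)) stopf("`obs_noise_var` must be >= 0")
  if (embedding_lags < 1) stopf("`embedding_lags` must be >= 1")
  if (is.null(region_names)) {
    region_names <- rownames(modulatory_matrices[[1]])
  }
  if (is.null(region_names)) region_names <- paste0("R", seq_len(M))
  structure(list(n_regions = M,
                 modulatory_matrices = modulatory_matrices,
                 input_strengths = input_strengths,
                 state_noise_cov = state_noise_cov,
                 hrf_basis_weights = hrf_basis_weights,
                 obs_noise_var = obs_noise_var,
                 embedding_lags = as.integer(embedding_lags),
                 region_names = region_names),
            class = "mds_params")
}

#' @export
print.mds_params <- function(x, ...) {
  cat(sprintf("<mds_params> %d regions, %d modulatory input(s), L = %d\n",
              x$n_regions, length(x$modulatory_matrices), x$embedding_lags))
  invisible(x)
}

#' Simulate the latent neuronal process
#'
#' Runs the bilinear recursion
#' `s(t) = sum_j v_j(t) C_j s(t-1) + D u(t) + w(t)` from a zero initial
#' state. By default the stimulus boxcar of `design` serves as both the
#' external input `u` (all regions) and the single modulatory input `v`.
#'
#' @param params an `mds_params`
#' @param design an `event_design` (or NULL when `u` and `v` are given)
#' @param n_timepoints number of samples (defaults to `run_length / TR`)
#' @param seed integer seed for the state noise
#' @param u optional T x M external input matrix
#' @param v optional T x J modulatory input matrix
#' @return a `latent_series`: list with `values` (T x M), `TR`, `u`, `v`
#' @export
simulate_latent <- function(params, design = NULL, n_timepoints = NULL,
                            seed = 1, u = NULL, v = NULL) {
  stopifnot(inherits(params, "mds_params"))
  M <- params$n_regions
  J <- length(params$modulatory_matrices)
  TR <- if (!is.null(design)) design$TR else 2
  if (is.null(n_timepoints)) {
    if (is.null(design) && is.null(u)) {
      stopf("give `design`, `u` or `n_timepoints`")
    }
    n_timepoints <- if (!is.null(u)) nrow(u) else
      floor(design$run_length / design$TR)
  }
  n_timepoints <- as.integer(n_timepoints)
  if (is.null(u)) {
    box <- design_boxcar(design, n_timepoints)
    u <- matrix(box, n_timepoints, M)
  }
  if (is.null(v)) {
    v <- matrix(if (!is.null(design)) design_boxcar(design, n_timepoints)
                else u[, 1], n_timepoints, J)
  }
  if (nrow(u) != n_timepoints || nrow(v) != n_timepoints) {
    stopf("`u` and `v` must have %d rows", n_timepoints)
  }
  Q <- params$state_noise_cov
  cQ <- if (max(abs(Q)) == 0) NULL else chol(Q + 1e-12 * diag(M))
  w <- with_seed(seed, {
    if (is.null(cQ)) matrix(0, n_timepoints, M)
    else matrix(rnorm(n_timepoints * M), n_timepoints, M) %*% cQ
  })
  s <- matrix(0, n_timepoints, M)
  d <- params$input_strengths
  s_prev <- rep(0, M)
  for (t in seq_len(n_timepoints)) {
    A <- matrix(0, M, M)
    for (j in seq_len(J)) A <- A + v[t, j] * params$modulatory_matrices[[j]]
    s[t, ] <- A %*% s_prev + d * u[t, ] + w[t, ]
    s_prev <- s[t, ]
  }
  colnames(s) <- params$region_names
  structure(list(values = s, TR = TR, u = u, v = v),
            class = "latent_series")
}

#' Simulate BOLD observations from a latent series
#'
#' Convolves each region's latent signal with its HRF (`b_m' Phi` over the
#' `embedding_lags` past samples, treating pre-run latents as zero) and adds
#' independent Gaussian observation noise.
#'
#' @param latent a `latent_series`
#' @param params an `mds_params`
#' @param hrf_basis an `hrf_basis` with `n_lags >= embedding_lags`
#' @param seed integer seed for the observation noise
#' @param subject_id,group_label metadata for the result
#' @return an `roi_timeseries`
#' @export
simulate_bold <- function(latent, params, hrf_basis, seed = 1,
                          subject_id = NA_character_,
                          group_label = NA_character_) {
  stopifnot(inherits(latent, "latent_series"),
            inherits(params, "mds_params"),
            inherits(hrf_basis, "hrf_basis"))
  L <- params$embedding_lags
  if (L > hrf_basis$n_lags) {
    stopf("embedding_lags (%d) exceeds HRF basis support (%d lags)", L,
          hrf_basis$n_lags)
  }
  if (ncol(params$hrf_basis_weights) != hrf_basis$n_bases) {
    stopf("hrf_basis_weights has %d columns but the basis has %d rows",
          ncol(params$hrf_basis_weights), hrf_basis$n_bases)
  }
  s <- latent$values
  Tn <- nrow(s)
  if (Tn <= L) stopf("latent series shorter than the embedding window")
  M <- params$n_regions
  Phi <- hrf_basis$basis_matrix[, seq_len(L), drop = FALSE]
  y <- matrix(0, Tn, M)
  for (m in seq_len(M)) {
    hm <- drop(params$hrf_basis_weights[m, , drop = FALSE] %*% Phi)
    # causal convolution, zero-padded before the run start
    sm <- c(rep(0, L - 1), s[, m])
    for (t in seq_len(Tn)) {
      y[t, m] <- sum(hm * sm[(t + L - 1):t])
    }
  }
  e <- with_seed(seed, {
    matrix(rnorm(Tn * M), Tn, M) %*% diag(sqrt(params$obs_noise_var), M)
  })
  roi_timeseries(y + e, region_names = params$region_names, TR = latent$TR,
                 subject_id = subject_id, group_label = group_label)
}
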
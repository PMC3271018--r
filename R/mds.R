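#' Default configuration for state-space (MDS) model fitting
#'
#' @param max_iter maximum EM iterations
#' @param tol relative objective-change convergence tolerance
#' @param ridge Gaussian prior precision on coupling / input coefficients
#' @param ridge_hrf Gaussian prior precision on HRF basis weights
#' @param q_mode `"shared"` (one state-noise variance for all regions; the
#'   default, which anchors relative latent scales), `"free"` (per-region)
#'   or `"fixed"` (held at 1)
#' @param sigma0 prior variance of the initial augmented state
#' @param stability_cap spectral-radius cap applied to coupling updates
#' @param verbose print the objective per iteration
#' @return a named list of settings
#' @export
mds_config <- function(max_iter = 500, tol = 1e-6, ridge = 1e-3,
                       ridge_hrf = 1e-3, q_mode = c("shared", "free", "fixed"),
                       sigma0 = 1, stability_cap = 0.97,
                       init = c("deconv", "zero"), verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, ridge = ridge, ridge_hrf = ridge_hrf,
       q_mode = match.arg(q_mode), sigma0 = sigma0,
       stability_cap = stability_cap, init = match.arg(init),
       verbose = verbose)
}

# Wiener-deconvolution initialization: estimate each region's latent signal
# by regularized inverse filtering with the canonical HRF, then initialize
# couplings / input strengths by least squares on the deconvolved series.
# Puts the EM close to its optimum so few iterations are needed.
mds_init_deconv <- function(Y, u, v, Phi, lam) {
  M <- ncol(Y[[1]]); Tn <- nrow(Y[[1]]); J <- ncol(v); L <- ncol(Phi)
  h0 <- c(Phi[1, ], rep(0, Tn - L))
  Hf <- fft(h0)
  lam_w <- 0.1 * max(Mod(Hf)^2)
  S_all <- lapply(Y, function(y) {
    s <- sapply(seq_len(M), function(m) {
      Re(fft(fft(y[, m]) * Conj(Hf) / (Mod(Hf)^2 + lam_w), inverse = TRUE)) / Tn
    })
    s
  })
  K <- J * M + 1
  C <- array(0, c(M, M, J))
  d <- rep(0, M)
  G <- array(0, c(K, K, M))
  rhs <- matrix(0, K, M)
  for (s in S_all) {
    sprev <- s[-Tn, , drop = FALSE]
    scur <- s[-1, , drop = FALSE]
    for (m in seq_len(M)) {
      X <- cbind(do.call(cbind, lapply(seq_len(J), function(j) {
        v[-1, j] * sprev
      })), u[-1, m])
      G[, , m] <- G[, , m] + crossprod(X)
      rhs[, m] <- rhs[, m] + crossprod(X, scur[, m])
    }
  }
  for (m in seq_len(M)) {
    theta <- solve(G[, , m] + (lam + 1e-6) * diag(K), rhs[, m])
    for (j in seq_len(J)) C[m, , j] <- theta[((j - 1) * M + 1):(j * M)]
    d[m] <- theta[K]
  }
  list(C = C, d = d)
}

# shared input checks + regressor construction for a list of subjects
mds_prepare <- function(ts_list, design, basis) {
  if (inherits(ts_list, "cohort")) ts_list <- ts_list$timeseries
  if (inherits(ts_list, "roi_timeseries")) ts_list <- list(ts_list)
  stopifnot(length(ts_list) >= 1, inherits(basis, "hrf_basis"))
  regions <- ts_list[[1]]$region_names
  TRs <- unique(vapply(ts_list, function(t) t$TR, 0))
  if (length(TRs) != 1) stopf("all subjects must share the same TR")
  for (ts in ts_list) {
    if (!identical(ts$region_names, regions)) {
      stopf("all subjects must share the same region set and order")
    }
  }
  Y <- lapply(ts_list, function(ts) preprocess_timeseries(ts)$values)
  Tn <- unique(vapply(Y, nrow, 0L))
  if (length(Tn) != 1) stopf("all subjects must have the same series length")
  M <- length(regions)
  box <- design_boxcar(design, Tn)
  # the external-input regressor is mean-centered so the model's predicted
  # BOLD is itself approximately zero-mean, matching the detrended/demeaned
  # series (the modulatory input keeps its on/off semantics)
  list(Y = Y, regions = regions, M = M, Tn = Tn,
       u = matrix(box - mean(box), Tn, M), v = matrix(box, Tn, 1))
}

# one EM fit with shared parameters across the supplied subjects
mds_em <- function(Y, u, v, Phi, config) {
  M <- ncol(Y[[1]]); Tn <- nrow(Y[[1]]); S <- length(Y)
  L <- ncol(Phi); B <- nrow(Phi); J <- ncol(v)
  lam <- config$ridge; lamb <- config$ridge_hrf
  if (Tn <= 3 * L) stopf("series too short for embedding length L = %d", L)

  C <- array(0, c(M, M, J))
  d <- rep(0.5, M)
  if (identical(config$init, "deconv")) {
    ini <- mds_init_deconv(Y, u, v, Phi, lam)
    for (j in seq_len(J)) {
      rho <- spectral_radius(ini$C[, , j])
      if (rho >= config$stability_cap) {
        ini$C[, , j] <- ini$C[, , j] * (config$stability_cap / rho)
      }
    }
    C <- ini$C
    d <- ini$d
  }
  bmat <- matrix(0, M, B); bmat[, 1] <- 1
  h <- bmat %*% Phi
  q <- rep(1, M)
  cvec <- rep(0, M)   # observation baseline (absorbs the removed series mean)
  r <- vapply(Y, function(y) apply(y, 2, var), numeric(M))
  r <- pmax(rowMeans(matrix(r, M)) / 2, 1e-4)
  Sy1 <- Reduce(`+`, lapply(Y, colSums))

  prior_term <- function() {
    -0.5 * lam * (sum(C^2) + sum(d^2)) - 0.5 * lamb * sum(bmat^2)
  }
  trace <- numeric(0)
  converged <- FALSE
  theta_cov <- vector("list", M)

  for (it in seq_len(config$max_iter)) {
    Yc <- lapply(Y, function(y) sweep(y, 2, cvec))
    acc <- kalman_smooth_stats_multi(Yc, u, v, C, d, h, q, r, config$sigma0)
    ll <- acc$loglik
    trace <- c(trace, ll + prior_term())
    if (config$verbose) {
      message(sprintf("  EM iter %3d  objective %.6f", it, trace[it]))
    }
    if (it > 1) {
      rel <- (trace[it] - trace[it - 1]) / (abs(trace[it - 1]) + 1e-12)
      if (abs(rel) < config$tol) {
        converged <- TRUE
        break
      }
    }

    n_trans <- S * (Tn - 1)
    n_obs <- S * Tn
    # --- couplings and input strengths, per target region ---
    K <- J * M + 1
    resid_q <- numeric(M)
    for (m in seq_len(M)) {
      G <- matrix(0, K, K)
      rhs <- numeric(K)
      for (j in seq_len(J)) {
        for (k in seq_len(J)) {
          G[((j - 1) * M + 1):(j * M), ((k - 1) * M + 1):(k * M)] <-
            acc$Gvv[, , (j - 1) * J + k]
        }
        G[K, ((j - 1) * M + 1):(j * M)] <- acc$Gvu[, m, j]
        G[((j - 1) * M + 1):(j * M), K] <- acc$Gvu[, m, j]
        rhs[((j - 1) * M + 1):(j * M)] <- acc$Gvy[m, , j]
      }
      G[K, K] <- acc$Guu[m]
      rhs[K] <- acc$Guy[m]
      prec <- G / q[m] + lam * diag(K)
      theta <- solve(prec, rhs / q[m])
      theta_cov[[m]] <- solve(prec)
      for (j in seq_len(J)) {
        C[m, , j] <- theta[((j - 1) * M + 1):(j * M)]
      }
      d[m] <- theta[K]
      resid_q[m] <- acc$Scur[m, m] - 2 * sum(theta * rhs) +
        drop(t(theta) %*% G %*% theta)
    }
    # stability guard (rarely triggered; breaks strict monotonicity when it is)
    for (j in seq_len(J)) {
      rho <- spectral_radius(C[, , j])
      if (rho >= config$stability_cap) {
        C[, , j] <- C[, , j] * (config$stability_cap / rho)
      }
    }
    # --- state noise ---
    if (config$q_mode == "free") {
      q <- pmax(resid_q / n_trans, 1e-6)
    } else if (config$q_mode == "shared") {
      q <- rep(max(sum(resid_q) / (M * n_trans), 1e-6), M)
    }  # "fixed": leave at 1
    # --- HRF weights, observation noise and baseline ---
    for (m in seq_len(M)) {
      Gb <- Phi %*% acc$Gx[, , m] %*% t(Phi)
      gb <- Phi %*% acc$Gxy[, m]
      prec <- Gb / r[m] + lamb * diag(B)
      bm <- solve(prec, gb / r[m])
      bmat[m, ] <- bm
      r[m] <- max((acc$Syy[m] - 2 * sum(bm * gb) +
                     drop(t(bm) %*% Gb %*% bm)) / n_obs, 1e-8)
      # baseline: mean residual of the centered series under the new weights
      cvec[m] <- cvec[m] +
        ((Sy1[m] - n_obs * cvec[m]) -
           sum(bm * (Phi %*% acc$Gex[, m]))) / n_obs
    }
    h <- bmat %*% Phi
  }

  # canonicalize latent signs: each region's HRF should correlate positively
  # with the canonical basis row (sign flips leave the likelihood unchanged)
  for (m in seq_len(M)) {
    if (sum(h[m, ] * Phi[1, ]) < 0) {
      bmat[m, ] <- -bmat[m, ]
      h[m, ] <- -h[m, ]
      d[m] <- -d[m]
      for (j in seq_len(J)) {
        keep <- C[m, m, j]
        C[m, , j] <- -C[m, , j]
        C[, m, j] <- -C[, m, j]
        C[m, m, j] <- keep
      }
    }
  }
  list(C = C, d = d, b = bmat, q = q, r = r, baseline = cvec,
       trace = trace, converged = converged, theta_cov = theta_cov,
       n_iter = length(trace))
}

#' Fit the bilinear state-space (MDS) model
#'
#' Estimates modulatory coupling matrices, external-input strengths,
#' per-region HRF basis weights and noise variances from multi-subject ROI
#' time series by penalized EM: each iteration runs an exact Kalman
#' forward-backward smoother over the lag-embedded latent state (so the
#' objective trace is the exact marginal log-likelihood plus Gaussian prior
#' terms, and is monotone non-decreasing up to the stability guard), then
#' performs conjugate closed-form updates of couplings, input strengths,
#' HRF weights and noise variances.
#'
#' In `"group"` mode all subjects share one parameter set (sufficient
#' statistics are pooled); in `"subject"` mode each subject is fitted
#' separately and per-subject coupling estimates are returned alongside
#' their mean.
#'
#' @param ts_list list of `roi_timeseries` (or a `cohort`); all subjects
#'   must share regions, TR and design. Series are detrended/demeaned
#'   internally (idempotent).
#' @param design the shared `event_design`
#' @param basis an `hrf_basis`; its `n_lags` sets the embedding length L
#' @param config list from [mds_config()]
#' @param mode `"group"` or `"subject"`
#' @return an `mds_fit`: list with `connections` (list per modulatory input
#'   of M x M posterior-mean coupling matrices, entry (m, n) = n -> m),
#'   `connection_se`, `input_strengths`, `hrf_weights`, `state_noise`,
#'   `obs_noise`, `logevidence_trace`, `converged`, `n_subjects`,
#'   `per_subject` (subject mode), `region_names`
#' @export
fit_mds <- function(ts_list, design, basis, config = mds_config(),
                    mode = c("group", "subject")) {
  mode <- match.arg(mode)
  config <- modifyList(mds_config(), config)
  prep <- mds_prepare(ts_list, design, basis)
  Phi <- basis$basis_matrix
  M <- prep$M; J <- 1L

  run_one <- function(Ys) mds_em(Ys, prep$u, prep$v, Phi, config)

  if (mode == "group") {
    em <- run_one(prep$Y)
    per_subject <- NULL
    conn <- lapply(seq_len(J), function(j) {
      m <- em$C[, , j]
      dimnames(m) <- list(prep$regions, prep$regions)
      m
    })
    trace <- em$trace
    converged <- em$converged
  } else {
    fits <- lapply(prep$Y, function(y) run_one(list(y)))
    per_subject <- lapply(fits, function(f) {
      m <- f$C[, , 1]
      dimnames(m) <- list(prep$regions, prep$regions)
      m
    })
    names(per_subject) <- names(prep$Y)
    conn <- list(Reduce(`+`, per_subject) / length(per_subject))
    em <- fits[[1]]
    trace <- lapply(fits, function(f) f$trace)
    converged <- all(vapply(fits, function(f) f$converged, TRUE))
  }

  se <- matrix(NA_real_, M, M, dimnames = list(prep$regions, prep$regions))
  if (mode == "group") {
    for (m in seq_len(M)) {
      se[m, ] <- sqrt(pmax(diag(em$theta_cov[[m]])[seq_len(M)], 0))
    }
  } else if (length(per_subject) > 1) {
    arr <- simplify2array(per_subject)
    se[] <- apply(arr, c(1, 2), sd) / sqrt(length(per_subject))
  }

  structure(list(connections = conn, connection_se = se,
                 input_strengths = em$d,
                 hrf_weights = em$b, state_noise = em$q, obs_noise = em$r,
                 logevidence_trace = trace, converged = converged,
                 n_subjects = length(prep$Y), mode = mode,
                 per_subject = per_subject, region_names = prep$regions,
                 config = config),
            class = "mds_fit")
}

#' @export
print.mds_fit <- function(x, ...) {
  cat(sprintf("<mds_fit> %d regions, %d subjects (%s mode), converged: %s\n",
              length(x$region_names), x$n_subjects, x$mode, x$converged))
  cat("coupling matrix (entry (m, n) = strength n -> m):\n")
  print(round(x$connections[[1]], 3))
  invisible(x)
}

# coupling-strength statistic of a fit (first modulatory input)
mds_edge_stat <- function(fit) fit$connections[[1]]

#' Surrogate null distribution for state-space coupling strengths
#'
#' Builds an empirical null under "no causal interactions between regions":
#' each subject's series is phase-randomized per region (preserving every
#' region's amplitude spectrum, hence autocorrelation and variance, while
#' destroying cross-region temporal dependence), and the full group model is
#' refitted on each surrogate cohort. The distribution of every
#' off-diagonal coupling estimate across surrogates is returned.
#'
#' @param ts_list list of `roi_timeseries` (or a `cohort`)
#' @param design,basis as in [fit_mds()]
#' @param n_surrogates number of surrogate cohorts (>= 100)
#' @param method surrogate scheme; only `"phase"` (per-region
#'   amplitude-preserving phase randomization) is implemented
#' @param seed integer seed
#' @param config fitting configuration for surrogate fits; defaults to a
#'   shortened EM (`max_iter = 15`) since only the coupling statistic is
#'   needed
#' @return a `null_distribution`: list with `statistic_name`, `values`
#'   (M x M x n_surrogates array), `n_surrogates`, `method`, `seed`
#' @export
surrogate_null_mds <- function(ts_list, design, basis, n_surrogates = 199,
                               method = "phase", seed = 1,
                               config = mds_config(max_iter = 15,
                                                   tol = 1e-4)) {
  if (!identical(method, "phase")) {
    stopf("unknown surrogate method '%s'; supported: \"phase\"", method)
  }
  if (n_surrogates < 100) {
    stopf("`n_surrogates` must be >= 100 for stable tail estimates")
  }
  config <- modifyList(mds_config(max_iter = 15, tol = 1e-4), config)
  prep <- mds_prepare(ts_list, design, basis)
  Phi <- basis$basis_matrix
  M <- prep$M
  vals <- array(NA_real_, c(M, M, n_surrogates),
                dimnames = list(prep$regions, prep$regions, NULL))
  for (k in seq_len(n_surrogates)) {
    Ys <- lapply(seq_along(prep$Y), function(s) {
      with_seed(derive_seed(seed, k, s), phase_randomize(prep$Y[[s]]))
    })
    em <- mds_em(Ys, prep$u, prep$v, Phi, config)
    vals[, , k] <- em$C[, , 1]
  }
  structure(list(statistic_name = "mds_coupling", values = vals,
                 n_surrogates = n_surrogates, method = method, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s, %d surrogates (%s)\n",
              x$statistic_name, x$n_surrogates, x$method))
  invisible(x)
}

#' Significant causal edges against a surrogate null
#'
#' Per-edge empirical p-value with add-one correction,
#' `p = (r + 1) / (n + 1)` where `r` counts surrogate values at least as
#' extreme (in absolute value) as the group statistic; Benjamini-Hochberg
#' FDR across the `M (M - 1)` off-diagonal edges; significance mask at
#' `q < alpha` (or raw `p < alpha` when `fdr = FALSE`). Diagonal entries
#' are never part of edge inference.
#'
#' @param fit an `mds_fit` (or any object with a coupling statistic matrix;
#'   a plain M x M matrix is accepted)
#' @param null a matching `null_distribution`
#' @param alpha significance threshold in (0, 1)
#' @param fdr apply BH correction (default TRUE)
#' @param p_method `"empirical"` (add-one empirical p; resolution limited to
#'   `1 / (n_surrogates + 1)`) or `"normal"` (Gaussian tail fitted to the
#'   surrogate null's mean and sd, the parametric test of the statistic
#'   against the null distribution's location)
#' @return a `causal_graph`: list with `region_names`, `edge_strength`,
#'   `edge_p`, `edge_q`, `significant`, `alpha`
#' @export
significant_edges <- function(fit, null, alpha = 0.01, fdr = TRUE,
                              p_method = c("empirical", "normal")) {
  check_alpha(alpha)
  p_method <- match.arg(p_method)
  stopifnot(inherits(null, "null_distribution"))
  stat <- if (inherits(fit, "mds_fit")) mds_edge_stat(fit) else as.matrix(fit)
  M <- nrow(stat)
  if (!all(dim(null$values)[1:2] == M)) {
    stopf("null distribution and fit have different edge sets")
  }
  regions <- rownames(stat) %||% paste0("R", seq_len(M))
  p <- matrix(NA_real_, M, M, dimnames = list(regions, regions))
  for (m in seq_len(M)) {
    for (n in seq_len(M)) {
      if (m == n) next
      nv <- null$values[m, n, ]
      p[m, n] <- if (p_method == "empirical") {
        empirical_p(stat[m, n], nv)
      } else {
        2 * pnorm(-abs(stat[m, n] - mean(nv)) / max(sd(nv), 1e-12))
      }
    }
  }
  q <- if (fdr) fdr_offdiag(p) else p
  sig <- !is.na(q) & q < alpha
  structure(list(region_names = regions, edge_strength = stat,
                 edge_p = p, edge_q = q, significant = sig, alpha = alpha,
                 fdr = fdr),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  n_sig <- sum(x$significant, na.rm = TRUE)
  cat(sprintf("<causal_graph> %d regions, %d significant edge(s) at %s < %g\n",
              length(x$region_names), n_sig,
              if (isTRUE(x$fdr)) "q" else "p", x$alpha))
  if (n_sig > 0) {
    idx <- which(x$significant, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      cat(sprintf("  %s -> %s  strength %.3f (q = %.4f)\n",
                  x$region_names[idx[i, 2]], x$region_names[idx[i, 1]],
                  x$edge_strength[idx[i, 1], idx[i, 2]],
                  x$edge_q[idx[i, 1], idx[i, 2]]))
    }
  }
  invisible(x)
}

# cross-paired null of differences: p-value per edge for |diff| under
# independent draws from the two surrogate nulls
diff_null_p <- function(diff, nullA, nullB, p_method = "empirical") {
  M <- nrow(diff)
  p <- matrix(NA_real_, M, M, dimnames = dimnames(diff))
  for (m in seq_len(M)) {
    for (n in seq_len(M)) {
      if (m == n) next
      a <- nullA$values[m, n, ]
      b <- nullB$values[m, n, ]
      if (p_method == "empirical") {
        dnull <- outer(a, b, `-`)
        p[m, n] <- (sum(abs(dnull) >= abs(diff[m, n])) + 1) /
          (length(dnull) + 1)
      } else {
        mu <- mean(a) - mean(b)
        sdd <- sqrt(var(a) + var(b))
        p[m, n] <- 2 * pnorm(-abs(diff[m, n] - mu) / max(sdd, 1e-12))
      }
    }
  }
  p
}

#' Between-group comparison of state-space coupling strengths
#'
#' Per-edge difference statistic = difference of the group coupling
#' estimates; its null is the distribution of differences of surrogate
#' statistics (all cross pairs of the two groups' surrogate draws, which
#' are independent across groups); BH-FDR across off-diagonal edges.
#'
#' @param fitA,fitB `mds_fit` objects for the two groups (same regions)
#' @param nullA,nullB matching `null_distribution`s
#' @param alpha significance threshold
#' @return a `group_comparison`: list with `difference` (A - B), `edge_p`,
#'   `edge_q`, `significant`, `direction` (+1 where A > B)
#' @export
compare_groups_mds <- function(fitA, fitB, nullA, nullB, alpha = 0.01,
                               p_method = c("empirical", "normal")) {
  check_alpha(alpha)
  p_method <- match.arg(p_method)
  statA <- if (inherits(fitA, "mds_fit")) mds_edge_stat(fitA) else as.matrix(fitA)
  statB <- if (inherits(fitB, "mds_fit")) mds_edge_stat(fitB) else as.matrix(fitB)
  if (!identical(dim(statA), dim(statB)) ||
      !identical(rownames(statA), rownames(statB))) {
    stopf("the two groups must share the same region set")
  }
  diff <- statA - statB
  p <- diff_null_p(diff, nullA, nullB, p_method)
  q <- fdr_offdiag(p)
  structure(list(difference = diff, edge_p = p, edge_q = q,
                 significant = !is.na(q) & q < alpha,
                 direction = sign(diff), alpha = alpha,
                 statistic = "mds_coupling"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  n_sig <- sum(x$significant, na.rm = TRUE)
  cat(sprintf("<group_comparison> (%s) %d significant difference(s) at q < %g\n",
              x$statistic, n_sig, x$alpha))
  if (n_sig > 0) {
    idx <- which(x$significant, arr.ind = TRUE)
    rn <- rownames(x$difference)
    for (i in seq_len(nrow(idx))) {
      cat(sprintf("  %s -> %s  diff %.3f (q = %.4f)\n",
                  rn[idx[i, 2]], rn[idx[i, 1]],
                  x$difference[idx[i, 1], idx[i, 2]],
                  x$edge_q[idx[i, 1], idx[i, 2]]))
    }
  }
  invisible(x)
}
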
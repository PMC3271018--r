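# shared fixtures, built once per test run and cached in this environment
.fx <- new.env(parent = emptyenv())

# small hub cohort: 5 regions, rAI outflow hub, 24 trials (~104 scans)
hub_cohort <- function() {
  if (is.null(.fx$hub)) {
    spec <- default_cohort_spec(n_subjects = c(adult = 6, child = 6),
                                n_trials = 36, embedding_lags = 8,
                                seed = 42)
    .fx$hub_spec <- spec
    .fx$hub <- generate_cohort(spec)
  }
  .fx$hub
}

hub_spec <- function() {
  hub_cohort()
  .fx$hub_spec
}

hub_group <- function(g) {
  Filter(function(ts) ts$group_label == g, hub_cohort()$timeseries)
}

# group-mode MDS fit of the adult half of the hub cohort (full EM)
hub_fit <- function() {
  if (is.null(.fx$hub_fit)) {
    coh <- hub_cohort()
    basis <- build_hrf_basis(2, 8)
    .fx$hub_fit <- fit_mds(hub_group("adult"), coh$design, basis,
                           mds_config(max_iter = 40, tol = 1e-6))
  }
  .fx$hub_fit
}

# independent Floyd-Warshall all-pairs shortest paths on a (target, source)
# adjacency matrix; returns D[from, to]
fw_distances <- function(A) {
  M <- nrow(A)
  D <- matrix(Inf, M, M)
  diag(D) <- 0
  for (m in seq_len(M)) {
    for (n in seq_len(M)) {
      if (m != n && A[m, n] != 0) D[n, m] <- 1  # source n -> target m
    }
  }
  for (k in seq_len(M)) {
    for (i in seq_len(M)) {
      for (j in seq_len(M)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# independent proximal-gradient (ISTA) lasso solver for the glmnet oracle
# comparison; minimizes 1/(2n) ||y - b0 - X b||^2 + lambda ||b||_1
ista_lasso <- function(X, y, lambda, n_iter = 50000, tol = 1e-12) {
  n <- nrow(X)
  b <- rep(0, ncol(X))
  b0 <- mean(y)
  step <- 1 / (max(eigen(crossprod(X) / n, only.values = TRUE)$values) + 1e-8)
  for (i in seq_len(n_iter)) {
    r <- y - b0 - X %*% b
    gb <- -crossprod(X, r) / n
    bn <- b - step * gb
    bn <- sign(bn) * pmax(abs(bn) - step * lambda, 0)
    b0n <- b0 + step * mean(r)
    if (max(abs(bn - b), abs(b0n - b0)) < tol) {
      b <- bn; b0 <- b0n
      break
    }
    b <- bn; b0 <- b0n
  }
  list(b0 = b0, b = as.numeric(b))
}
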
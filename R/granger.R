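
# residual variances (full + per-source reduced) from cross-products;
# shared by fit_var() and the lean surrogate path so both produce
# identical influence statistics
var_resid_core <- function(XtX, XtY, YtY, n, M, order, check = TRUE) {
  ridge <- 1e-10 * mean(diag(XtX))
  solve_rss <- function(keep) {
    A <- XtX[keep, keep, drop = FALSE]
    diag(A) <- diag(A) + ridge
    if (check) {
      cond <- tryCatch(rcond(A), error = function(e) 0)
      if (cond < 1e-9) {
        stopf("VAR design is numerically singular (duplicated or collinear region series)")
      }
    }
    beta <- solve(A, XtY[keep, , drop = FALSE])
    list(beta = beta,
         rss = diag(YtY) - 2 * colSums(XtY[keep, , drop = FALSE] * beta) +
           diag(t(beta) %*% XtX[keep, keep, drop = FALSE] %*% beta))
  }
  full <- solve_rss(seq_len(M * order))
  resid_var_full <- pmax(full$rss / n, .Machine$double.eps)
  resid_var_reduced <- matrix(NA_real_, M, M)
  for (x in seq_len(M)) {
    keep <- setdiff(seq_len(M * order), x + M * (seq_len(order) - 1))
    resid_var_reduced[x, ] <- pmax(solve_rss(keep)$rss / n,
                                   .Machine$double.eps)
  }
  list(full = full, resid_var_full = resid_var_full,
       resid_var_reduced = resid_var_reduced)
}

# F matrix straight from a data matrix, minimal allocations (surrogate path)
influence_F_lean <- function(mat, order) {
  M <- ncol(mat)
  Tn <- nrow(mat)
  n <- Tn - order
  Ymat <- mat[(order + 1):Tn, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(l) {
    mat[(order + 1 - l):(Tn - l), , drop = FALSE]
  }))
  cp <- var_resid_core(crossprod(X), crossprod(X, Ymat), crossprod(Ymat),
                       n, M, order, check = FALSE)
  Fm <- log(cp$resid_var_reduced / rep(cp$resid_var_full, each = M))
  Fm[Fm < 0] <- 0
  diag(Fm) <- 0
  Fm
}

#' Fit a vector autoregressive model with per-source reduced models
#'
#' Least-squares VAR(p) on a (preprocessed) multi-region series, together
#' with, for every source region x, the reduced model that omits all lags
#' of x from every equation. The pair of residual variances per target
#' feeds the conditional Granger influence terms.
#'
#' @param ts an `roi_timeseries` or numeric matrix (time x region)
#' @param order VAR lag order (>= 1)
#' @return a `var_fit`: list with `order`, `coef` (array M x M x order:
#'   entry (m, n, l) = effect of region n's lag l on region m), `residuals`
#'   (full-model), `resid_var_full` (per target), `resid_var_reduced`
#'   (M x M: entry (x, y) = residual variance of target y when source x is
#'   omitted), `n_used`, `region_names`
#' @export
fit_var <- function(ts, order = 1) {
  mat <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  M <- ncol(mat)
  Tn <- nrow(mat)
  if (order < 1) stopf("`order` must be >= 1")
  if (order >= Tn) stopf("`order` (%d) must be below the series length (%d)",
                         order, Tn)
  min_len <- 10 * order * M
  if (Tn <= min_len) {
    stopf("series too short for a VAR(%d) on %d regions: need > %d samples, have %d",
          order, M, min_len, Tn)
  }
  regions <- colnames(mat) %||% paste0("R", seq_len(M))
  n <- Tn - order
  Ymat <- mat[(order + 1):Tn, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(l) {
    mat[(order + 1 - l):(Tn - l), , drop = FALSE]
  }))  # n x (M * order); columns grouped by lag, region within lag
  cp <- var_resid_core(crossprod(X), crossprod(X, Ymat), crossprod(Ymat),
                       n, M, order)
  resid_var_full <- cp$resid_var_full
  names(resid_var_full) <- regions
  coef_arr <- array(0, c(M, M, order), dimnames = list(regions, regions, NULL))
  for (l in seq_len(order)) {
    coef_arr[, , l] <- t(cp$full$beta[((l - 1) * M + 1):(l * M),
                                      , drop = FALSE])
  }
  resid_var_reduced <- cp$resid_var_reduced
  dimnames(resid_var_reduced) <- list(regions, regions)
  residuals <- Ymat - X %*% cp$full$beta
  structure(list(order = as.integer(order), coef = coef_arr,
                 residuals = residuals, resid_var_full = resid_var_full,
                 resid_var_reduced = resid_var_reduced, n_used = n,
                 region_names = regions),
            class = "var_fit")
}

#' Conditional Granger influence and difference-of-influence matrices
#'
#' The influence of x on y, conditional on all other regions, is
#' `F(x -> y) = ln(reduced residual variance of y without x / full residual
#' variance of y)`, clipped at 0. The difference-of-influence (doi) matrix
#' `doi[x, y] = F(x -> y) - F(y -> x)` is exactly antisymmetric; its sign
#' assigns net causal direction.
#'
#' @param ts an `roi_timeseries` or matrix
#' @param order VAR order
#' @return an `influence_matrix`: list with `F_values` (entry (x, y) =
#'   F(x -> y)), `doi`, `order`, `region_names`
#' @export
influence_terms <- function(ts, order = 1) {
  vf <- fit_var(ts, order)
  M <- length(vf$region_names)
  Fm <- matrix(0, M, M, dimnames = list(vf$region_names, vf$region_names))
  for (x in seq_len(M)) {
    for (y in seq_len(M)) {
      if (x == y) next
      Fm[x, y] <- max(log(vf$resid_var_reduced[x, y] /
                            vf$resid_var_full[y]), 0)
    }
  }
  structure(list(F_values = Fm, doi = doi_matrix(Fm), order = vf$order,
                 region_names = vf$region_names),
            class = "influence_matrix")
}

#' Difference-of-influence matrix
#'
#' @param F_values M x M matrix of influence terms, entry (x, y) =
#'   F(x -> y), or an `influence_matrix`
#' @return exactly antisymmetric M x M matrix `F - t(F)`
#' @export
doi_matrix <- function(F_values) {
  Fm <- if (inherits(F_values, "influence_matrix")) F_values$F_values
        else as.matrix(F_values)
  if (any(!is.finite(Fm))) stopf("influence matrix must be finite")
  Fm - t(Fm)
}

# per-subject influence and doi stacks for a list of subjects
cohort_influences <- function(ts_list, order) {
  if (inherits(ts_list, "cohort")) ts_list <- ts_list$timeseries
  if (inherits(ts_list, "roi_timeseries")) ts_list <- list(ts_list)
  lapply(ts_list, function(ts) {
    influence_terms(preprocess_timeseries(ts), order)
  })
}

#' Surrogate null distribution for Granger statistics
#'
#' Phase-randomizes every subject's series per region (destroying
#' cross-region dependence while preserving each region's spectrum) and
#' recomputes the group-mean influence (F) and difference-of-influence
#' (doi) statistics on each surrogate cohort.
#'
#' @param ts_list list of `roi_timeseries` (or a `cohort`)
#' @param order VAR order
#' @param n_surrogates number of surrogate cohorts (>= 100)
#' @param method only `"phase"` is implemented
#' @param seed integer seed
#' @return a `null_distribution` with `values` (doi, M x M x n_surrogates)
#'   and `F_values` (same shape)
#' @export
surrogate_null_granger <- function(ts_list, order = 1, n_surrogates = 999,
                                   method = "phase", seed = 1) {
  if (!identical(method, "phase")) {
    stopf("unknown surrogate method '%s'; supported: \"phase\"", method)
  }
  if (n_surrogates < 100) {
    stopf("`n_surrogates` must be >= 100 for stable tail estimates")
  }
  if (inherits(ts_list, "cohort")) ts_list <- ts_list$timeseries
  Y <- lapply(ts_list, function(ts) preprocess_timeseries(ts)$values)
  M <- ncol(Y[[1]])
  regions <- colnames(Y[[1]])
  doi_vals <- array(NA_real_, c(M, M, n_surrogates),
                    dimnames = list(regions, regions, NULL))
  f_vals <- doi_vals
  for (k in seq_len(n_surrogates)) {
    f_sum <- matrix(0, M, M)
    for (s in seq_along(Y)) {
      ys <- with_seed(derive_seed(seed, k, s), phase_randomize(Y[[s]]))
      f_sum <- f_sum + influence_F_lean(ys, order)
    }
    f_mean <- f_sum / length(Y)
    doi_vals[, , k] <- f_mean - t(f_mean)
    f_vals[, , k] <- f_mean
  }
  structure(list(statistic_name = "doi", values = doi_vals,
                 F_values = f_vals, n_surrogates = n_surrogates,
                 method = method, seed = seed),
            class = "null_distribution")
}

#' Group-level causal graph from Granger statistics
#'
#' Computes per-subject doi matrices, tests each edge's group mean against
#' the surrogate null (add-one empirical p, BH-FDR over off-diagonal
#' edges), and keeps edge x -> y when the doi difference is significant
#' with `doi[x, y] > 0` (positive sign assigns direction; exact ties give
#' no edge).
#'
#' @param ts_list list of `roi_timeseries` (or a `cohort`)
#' @param order VAR order
#' @param null a `null_distribution` from [surrogate_null_granger()]
#' @param alpha FDR threshold
#' @param p_method `"empirical"` (add-one rule) or `"normal"` (Gaussian tail
#'   fitted to the surrogate null), as in [significant_edges()]
#' @return a `causal_graph` (edge_strength holds group-mean doi oriented
#'   source -> target in the package's (target, source) convention)
#' @export
group_causal_graph <- function(ts_list, order = 1, null, alpha = 0.01,
                               p_method = c("empirical", "normal")) {
  check_alpha(alpha)
  p_method <- match.arg(p_method)
  stopifnot(inherits(null, "null_distribution"))
  if (inherits(ts_list, "cohort")) ts_list <- ts_list$timeseries
  if (length(ts_list) < 3) {
    warnf("fewer than 3 subjects in the group; group inference is fragile")
  }
  infs <- cohort_influences(ts_list, order)
  doi_mean <- Reduce(`+`, lapply(infs, function(i) i$doi)) / length(infs)
  M <- nrow(doi_mean)
  regions <- rownames(doi_mean)
  # doi is indexed (x, y) = F(x->y) - F(y->x); convert to the package's
  # (target, source) convention for the graph: strength[m, n] = doi[n, m]
  p <- matrix(NA_real_, M, M, dimnames = list(regions, regions))
  for (x in seq_len(M)) {
    for (y in seq_len(M)) {
      if (x == y) next
      nv <- null$values[x, y, ]
      p[y, x] <- if (p_method == "empirical") {
        empirical_p(doi_mean[x, y], nv)
      } else {
        2 * pnorm(-abs(doi_mean[x, y] - mean(nv)) / max(sd(nv), 1e-12))
      }
    }
  }
  q <- fdr_offdiag(p)
  strength <- t(doi_mean)
  sig <- !is.na(q) & q < alpha & strength > 0
  structure(list(region_names = regions, edge_strength = strength,
                 edge_p = p, edge_q = q, significant = sig, alpha = alpha,
                 fdr = TRUE, per_subject_doi = lapply(infs, `[[`, "doi"),
                 per_subject_F = lapply(infs, `[[`, "F_values")),
            class = "causal_graph")
}

#' Between-group comparison of difference-of-influence terms
#'
#' Difference statistic per edge = difference of group-mean doi; null =
#' differences of the two groups' surrogate statistics (all cross pairs);
#' BH-FDR across off-diagonal edges.
#'
#' @param tsA,tsB subject lists (or `cohort`s) for the two groups
#' @param order VAR order
#' @param nullA,nullB `null_distribution`s for the two groups
#' @param alpha FDR threshold
#' @return a `group_comparison` (difference indexed (x, y) like doi)
#' @export
compare_groups_doi <- function(tsA, tsB, order = 1, nullA, nullB,
                               alpha = 0.01,
                               p_method = c("empirical", "normal")) {
  check_alpha(alpha)
  p_method <- match.arg(p_method)
  if (inherits(tsA, "cohort")) tsA <- tsA$timeseries
  if (inherits(tsB, "cohort")) tsB <- tsB$timeseries
  infA <- cohort_influences(tsA, order)
  infB <- cohort_influences(tsB, order)
  if (!identical(infA[[1]]$region_names, infB[[1]]$region_names)) {
    stopf("the two groups must share the same region set")
  }
  meanA <- Reduce(`+`, lapply(infA, `[[`, "doi")) / length(infA)
  meanB <- Reduce(`+`, lapply(infB, `[[`, "doi")) / length(infB)
  diff <- meanA - meanB
  p <- diff_null_p(diff, nullA, nullB, p_method)
  q <- fdr_offdiag(p)
  structure(list(difference = diff, edge_p = p, edge_q = q,
                 significant = !is.na(q) & q < alpha,
                 direction = sign(diff), alpha = alpha, statistic = "doi"),
            class = "group_comparison")
}
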
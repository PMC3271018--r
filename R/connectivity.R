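#' Instantaneous functional connectivity of one subject
#'
#' Regresses a linear drift (and optional user-supplied confound columns)
#' out of every region's series, then computes the Pearson correlation for
#' every region pair.
#'
#' @param ts an `roi_timeseries` (or matrix)
#' @param confounds optional numeric matrix (time x k) of confound
#'   regressors (physiological recordings, motion, ...)
#' @return symmetric M x M correlation matrix with unit diagonal
#' @export
functional_connectivity <- function(ts, confounds = NULL) {
  mat <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  n <- nrow(mat)
  X <- cbind(1, seq_len(n))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) {
      stopf("confounds must have the same number of rows as the series")
    }
    X <- cbind(X, confounds)
  }
  resid <- mat - X %*% solve(crossprod(X), crossprod(X, mat))
  sds <- apply(resid, 2, sd)
  if (any(sds < 1e-12)) {
    stopf("constant series after confound removal: correlation undefined for %s",
          paste(colnames(mat)[sds < 1e-12], collapse = ", "))
  }
  r <- cor(resid)
  diag(r) <- 1
  r
}

#' Compare functional connectivity between two groups
#'
#' Two-sample t-tests on Fisher z-transformed per-subject correlations for
#' every region pair, BH-FDR over the `M (M - 1) / 2` pairs.
#'
#' @param fcA,fcB lists of per-subject correlation matrices (one list per
#'   group, >= 3 subjects each)
#' @param alpha FDR threshold
#' @return data.frame: region_a, region_b, mean_rA, mean_rB, mean_diff_z,
#'   t, p, q, significant
#' @export
compare_fc_groups <- function(fcA, fcB, alpha = 0.01) {
  check_alpha(alpha)
  if (length(fcA) < 3 || length(fcB) < 3) {
    stopf("need >= 3 subjects per group")
  }
  regions <- colnames(fcA[[1]])
  pairs <- utils::combn(regions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    zA <- vapply(fcA, function(m) fisher_z(clamp_r(m[a, b])), 0)
    zB <- vapply(fcB, function(m) fisher_z(clamp_r(m[a, b])), 0)
    if (sd(c(zA, zB)) < 1e-12) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(zA, zB)
    }
    data.frame(region_a = a, region_b = b,
               mean_rA = fisher_z_inv(mean(zA)),
               mean_rB = fisher_z_inv(mean(zB)),
               mean_diff_z = mean(zA) - mean(zB),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

clamp_r <- function(r) pmin(pmax(r, -0.999999), 0.999999)

#' Structure-function correlation across subjects
#'
#' Pearson correlation, across the subjects of one group, between a
#' per-subject functional measure on an edge (functional-connectivity r or
#' causal strength) and the structural measure (fiber density or mean FA)
#' of the corresponding region pair.
#'
#' @param functional named numeric vector of the per-subject functional
#'   measure (names = subject ids)
#' @param sc structural-connectivity data.frame with columns `subject_id`,
#'   `region_a`, `region_b`, `fiber_density`, `mean_FA`
#' @param edge edge label `"A->B"` or undirected `"A-B"`
#' @param measure `"fiber_density"` or `"mean_FA"`
#' @return list with `r`, `p`, `n`
#' @export
structure_function_correlation <- function(functional, sc,
                                           edge = "rAI->rPPC",
                                           measure = c("fiber_density",
                                                       "mean_FA")) {
  measure <- match.arg(measure)
  validate_structural(sc)
  ab <- if (grepl("->", edge, fixed = TRUE)) parse_edge_key(edge)
        else strsplit(edge, "-", fixed = TRUE)[[1]]
  rows <- sc[(sc$region_a == ab[1] & sc$region_b == ab[2]) |
               (sc$region_a == ab[2] & sc$region_b == ab[1]), ]
  common <- intersect(names(functional), rows$subject_id)
  if (length(common) < 5) {
    stopf("need >= 5 subjects with both measures on edge %s (have %d)",
          edge, length(common))
  }
  f <- functional[common]
  s <- rows[[measure]][match(common, rows$subject_id)]
  if (sd(f) < 1e-12 || sd(s) < 1e-12) {
    stopf("zero-variance measure: correlation undefined")
  }
  ct <- cor.test(f, s)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Compare structural connectivity between groups on one edge
#'
#' Two-sample t-tests per measure (fiber density and mean FA).
#'
#' @param scA,scB structural tables for the two groups (>= 3 subjects)
#' @param edge edge or pair label
#' @return data.frame: measure, mean_A, mean_B, t, p
#' @export
compare_structural <- function(scA, scB, edge = "rAI->rPPC") {
  validate_structural(scA)
  validate_structural(scB)
  ab <- if (grepl("->", edge, fixed = TRUE)) parse_edge_key(edge)
        else strsplit(edge, "-", fixed = TRUE)[[1]]
  pick <- function(sc) {
    sc[(sc$region_a == ab[1] & sc$region_b == ab[2]) |
         (sc$region_a == ab[2] & sc$region_b == ab[1]), ]
  }
  a <- pick(scA); b <- pick(scB)
  if (nrow(a) < 3 || nrow(b) < 3) stopf("need >= 3 subjects per group")
  rows <- lapply(c("fiber_density", "mean_FA"), function(ms) {
    tt <- t.test(a[[ms]], b[[ms]])
    data.frame(measure = ms, mean_A = mean(a[[ms]]), mean_B = mean(b[[ms]]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}

validate_structural <- function(sc) {
  need <- c("subject_id", "region_a", "region_b", "fiber_density", "mean_FA")
  if (!all(need %in% names(sc))) {
    stopf("structural table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(sc$mean_FA < 0 | sc$mean_FA > 1)) {
    stopf("mean_FA outside [0, 1]")
  }
  if (any(sc$fiber_density < 0)) stopf("fiber_density must be >= 0")
  invisible(sc)
}
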
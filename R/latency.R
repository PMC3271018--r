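#' Fit event-related responses with a canonical-plus-derivative basis
#'
#' Builds task regressors by convolving the event impulse train with the
#' canonical HRF and its temporal derivative, estimates the two basis
#' weights per region and subject by least squares, and evaluates the
#' fitted evoked response (the weighted basis combination) on a grid
#' upsampled by `upsample` relative to the TR. Fitted curves are averaged
#' across events implicitly (one weight pair per subject summarises all
#' events) and then across subjects.
#'
#' @param ts_list list of `roi_timeseries` (or a `cohort`, or a single
#'   subject); at least 5 events are required
#' @param design the shared `event_design`
#' @param basis an `hrf_basis` on the TR grid (its lag span sets the
#'   modeled window; must cover at least 20 s)
#' @param upsample upsampling factor for the evaluation grid (default 10,
#'   i.e. grid step TR / 10)
#' @return a `fitted_response`: list with `time_grid`, `fitted_values`
#'   (grid x region group-mean curves), `per_subject` (list of grid x
#'   region matrices), `weights` (subject x region x basis array),
#'   `region_names`
#' @export
fit_event_response <- function(ts_list, design, basis, upsample = 10) {
  if (inherits(ts_list, "cohort")) ts_list <- ts_list$timeseries
  if (inherits(ts_list, "roi_timeseries")) ts_list <- list(ts_list)
  stopifnot(inherits(design, "event_design"), inherits(basis, "hrf_basis"))
  if (design$n_trials < 5) stopf("need at least 5 events to fit responses")
  window_s <- basis$n_lags * basis$TR
  if (window_s < 20) {
    stopf("basis window (%g s) must cover at least 20 s post-onset", window_s)
  }
  TR <- basis$TR
  regions <- ts_list[[1]]$region_names
  M <- length(regions)
  Tn <- nrow(ts_list[[1]]$values)
  # task regressors: stimulus boxcar (duration-aware) convolved with each
  # basis, the standard epoch-model design
  box <- design_boxcar(design, Tn)
  reg <- sapply(1:2, function(b) {
    stats::convolve(box, rev(basis$basis_matrix[b, ]), type = "open")[1:Tn]
  })
  # intercept and linear drift alongside the basis regressors, so the fit is
  # consistent with the detrended/demeaned series
  X <- cbind(1, seq_len(Tn) - mean(seq_len(Tn)), reg)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf("rank-deficient design: canonical and derivative regressors are collinear for this event schedule")
  }
  # evoked-response bases on the upsampled grid: the same duration
  # convolution evaluated at step TR / upsample (scaled so curve and
  # regressor units agree)
  step <- TR / upsample
  tg <- seq(0, window_s - step, by = step)
  box_fine <- rep(1, max(1, round(design$durations[1] / step)))
  Bup <- rbind(canonical_hrf(tg), hrf_derivative(tg))
  Bup <- t(apply(Bup, 1, function(b) {
    stats::convolve(b, rev(box_fine), type = "open")[seq_along(tg)] *
      step / TR
  }))
  weights <- array(NA_real_, c(length(ts_list), M, 2),
                   dimnames = list(names(ts_list), regions,
                                   c("canonical", "derivative")))
  per_subject <- vector("list", length(ts_list))
  for (s in seq_along(ts_list)) {
    y <- preprocess_timeseries(ts_list[[s]])$values
    beta <- qr.coef(qrX, y)   # 4 x M (intercept, drift, two bases)
    weights[s, , ] <- t(beta[3:4, , drop = FALSE])
    per_subject[[s]] <- crossprod(Bup, beta[3:4, , drop = FALSE])
    colnames(per_subject[[s]]) <- regions
  }
  names(per_subject) <- names(ts_list)
  fitted_mean <- Reduce(`+`, per_subject) / length(per_subject)
  structure(list(time_grid = tg, fitted_values = fitted_mean,
                 per_subject = per_subject, weights = weights,
                 region_names = regions, TR = TR, upsample = upsample),
            class = "fitted_response")
}

#' @export
print.fitted_response <- function(x, ...) {
  cat(sprintf("<fitted_response> %d regions, %d subjects, window %g s (step %g s)\n",
              length(x$region_names), length(x$per_subject),
              max(x$time_grid), x$time_grid[2] - x$time_grid[1]))
  invisible(x)
}

# onset of a single curve via the relative-slope criterion
curve_onset <- function(tg, curve, threshold_frac = 0.10) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stopf("`threshold_frac` must be in (0, 1)")
  }
  if (diff(range(curve)) < 1e-12) {
    stopf("flat fitted curve: onset undefined")
  }
  n <- length(curve)
  step <- tg[2] - tg[1]
  slope <- c(curve[2] - curve[1],
             (curve[3:n] - curve[1:(n - 2)]) / 2,
             curve[n] - curve[n - 1]) / step
  # polarity from the first extremum of the curve after onset
  peak_idx <- which.max(abs(curve))
  ascending <- curve[peak_idx] > 0
  # initial segment: from stimulus onset to the first local extremum
  sgn <- if (ascending) 1 else -1
  sc <- sgn * curve
  ext <- which(diff(sign(diff(sc))) < 0) + 1
  seg_end <- if (length(ext) > 0) ext[1] else n
  seg <- seq_len(seg_end)
  max_slope <- max(sgn * slope[seg])
  if (max_slope <= 0) stopf("no %s segment found: onset undefined",
                            if (ascending) "ascending" else "descending")
  thr <- threshold_frac * max_slope
  hit <- which(sgn * slope[seg] >= thr)
  if (length(hit) == 0) stopf("slope never reaches threshold")
  list(onset = tg[hit[1]], slope_at_onset = slope[hit[1]],
       polarity = if (ascending) "ascending" else "descending")
}

#' Onset latency from a fitted evoked response
#'
#' The onset is the earliest time, scanning from stimulus onset, at which
#' the slope of the fitted response (central finite differences on the
#' upsampled grid) first reaches `threshold_frac` of its maximum positive
#' slope within the initial ascending segment (or of its
#' maximum-magnitude negative slope for descending responses). The
#' criterion is invariant to positive rescaling and equivariant to time
#' shifts of the curve.
#'
#' @param fr a `fitted_response`
#' @param threshold_frac slope fraction defining onset (default 0.10)
#' @return a `latency_profile`: list with `onsets` (group-mean curve
#'   onsets per region), `slope_at_onset`, `polarity`, `per_subject`
#'   (subject x region onset matrix), `region_names`
#' @export
onset_latency <- function(fr, threshold_frac = 0.10) {
  stopifnot(inherits(fr, "fitted_response"))
  M <- length(fr$region_names)
  onsets <- slopes <- setNames(numeric(M), fr$region_names)
  polarity <- setNames(character(M), fr$region_names)
  for (m in seq_len(M)) {
    o <- curve_onset(fr$time_grid, fr$fitted_values[, m], threshold_frac)
    onsets[m] <- o$onset
    slopes[m] <- o$slope_at_onset
    polarity[m] <- o$polarity
  }
  per_subject <- matrix(NA_real_, length(fr$per_subject), M,
                        dimnames = list(names(fr$per_subject),
                                        fr$region_names))
  for (s in seq_along(fr$per_subject)) {
    for (m in seq_len(M)) {
      per_subject[s, m] <- tryCatch(
        curve_onset(fr$time_grid, fr$per_subject[[s]][, m],
                    threshold_frac)$onset,
        error = function(e) NA_real_)
    }
  }
  structure(list(onsets = onsets, slope_at_onset = slopes,
                 polarity = polarity, per_subject = per_subject,
                 region_names = fr$region_names,
                 threshold_frac = threshold_frac),
            class = "latency_profile")
}

#' @export
print.latency_profile <- function(x, ...) {
  cat("<latency_profile> onsets (s):\n")
  print(round(x$onsets, 2))
  invisible(x)
}

#' Compare onset latencies across regions and groups
#'
#' Within each group: paired t-tests on per-subject onsets for every region
#' pair; across groups: per-region two-sample t-tests. BH-FDR within each
#' family. A permutation option replaces the t reference distribution with
#' a sign-flip / label-shuffle null.
#'
#' @param profiles named list of `latency_profile`s, one per group
#' @param method `"t"` (default) or `"permutation"`
#' @param n_perm permutations when `method = "permutation"`
#' @param seed seed for the permutation draw
#' @return list with `within` (data.frame: group, region_a, region_b,
#'   mean_diff, p, q) and `between` (data.frame: region, mean_diff
#'   (first group minus second), p, q)
#' @export
compare_latencies <- function(profiles, method = c("t", "permutation"),
                              n_perm = 999, seed = 1) {
  method <- match.arg(method)
  stopifnot(is.list(profiles), length(profiles) >= 1)
  for (pr in profiles) stopifnot(inherits(pr, "latency_profile"))
  regions <- profiles[[1]]$region_names
  within <- list()
  for (g in names(profiles)) {
    ons <- profiles[[g]]$per_subject
    if (sum(complete.cases(ons)) < 3) {
      stopf("group '%s' has fewer than 3 subjects with defined onsets", g)
    }
    pairs <- utils::combn(regions, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      dvec <- ons[, a] - ons[, b]
      dvec <- dvec[is.finite(dvec)]
      p <- paired_p(dvec, method, n_perm, derive_seed(seed, k))
      within[[length(within) + 1]] <- data.frame(
        group = g, region_a = a, region_b = b,
        mean_diff = mean(dvec), p = p)
    }
  }
  within <- do.call(rbind, within)
  within$q <- NA_real_
  for (g in unique(within$group)) {
    idx <- within$group == g
    within$q[idx] <- p.adjust(within$p[idx], method = "BH")
  }

  between <- NULL
  if (length(profiles) == 2) {
    gA <- profiles[[1]]$per_subject
    gB <- profiles[[2]]$per_subject
    rows <- lapply(regions, function(rg) {
      a <- gA[, rg]; b <- gB[, rg]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      p <- if (sd(c(a, b)) < 1e-12) 1 else t.test(a, b)$p.value
      data.frame(region = rg, mean_diff = mean(a) - mean(b), p = p)
    })
    between <- do.call(rbind, rows)
    between$q <- p.adjust(between$p, method = "BH")
  }
  list(within = within, between = between)
}

paired_p <- function(dvec, method, n_perm, seed) {
  if (sd(dvec) < 1e-12) {
    return(if (abs(mean(dvec)) < 1e-12) 1 else 0)
  }
  if (method == "t") {
    t.test(dvec)$p.value
  } else {
    obs <- mean(dvec)
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        mean(dvec * sample(c(-1, 1), length(dvec), replace = TRUE))
      }, 0)
    })
    empirical_p(obs, null)
  }
}
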
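# build a fitted_response object directly from known curves
make_fr <- function(curves, step = 0.2) {
  tg <- (seq_len(nrow(curves)) - 1) * step
  structure(list(time_grid = tg, fitted_values = curves,
                 per_subject = list(s1 = curves),
                 region_names = colnames(curves), TR = 2, upsample = 10),
            class = "fitted_response")
}

test_that("noiseless basis responses are recovered exactly", {
  design <- generate_event_design(12, 5, iti_fixed = 3,
                                  jitter_bounds = c(0, 2), TR = 2, seed = 2)
  basis <- build_hrf_basis(2, 12)
  Tn <- floor(design$run_length / 2)
  box <- design_boxcar(design, Tn)
  reg <- sapply(1:2, function(b) {
    convolve(box, rev(basis$basis_matrix[b, ]), type = "open")[1:Tn]
  })
  w_true <- rbind(c(1, 0), c(1, 0.5))
  y <- reg %*% t(w_true)
  colnames(y) <- c("A", "B")
  ts <- roi_timeseries(y, TR = 2)
  fr <- fit_event_response(ts, design, basis)
  expect_equal(unname(fr$weights[1, "A", ]), c(1, 0), tolerance = 1e-6)
  expect_equal(unname(fr$weights[1, "B", ]), c(1, 0.5), tolerance = 1e-6)
  # a positive derivative weight shifts the fitted peak earlier
  pkA <- fr$time_grid[which.max(fr$fitted_values[, "A"])]
  pkB <- fr$time_grid[which.max(fr$fitted_values[, "B"])]
  expect_lt(pkB, pkA)
})

test_that("zero response gives zero weights and a flat fit", {
  design <- generate_event_design(8, 5, TR = 2, seed = 3)
  basis <- build_hrf_basis(2, 12)
  Tn <- floor(design$run_length / 2)
  y <- matrix(0, Tn, 2, dimnames = list(NULL, c("A", "B")))
  y[1, ] <- 1e-30  # dodge the constant-series guard without adding signal
  fr <- suppressWarnings(
    fit_event_response(roi_timeseries(y, TR = 2), design, basis))
  expect_lt(max(abs(fr$weights)), 1e-10)
  expect_error(onset_latency(fr), "flat")
})

test_that("onset estimation is shift-equivariant", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  base <- canonical_hrf(tg)
  delayed <- canonical_hrf(tg - 1.0)
  fr <- make_fr(cbind(A = base, B = delayed), step)
  lp <- onset_latency(fr)
  expect_equal(unname(lp$onsets["B"] - lp$onsets["A"]), 1.0,
               tolerance = step + 1e-9)
  expect_equal(unname(lp$polarity), c("ascending", "ascending"))
})

test_that("onset estimation is invariant to positive rescaling", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  fr1 <- make_fr(cbind(A = canonical_hrf(tg), B = 17.3 * canonical_hrf(tg)),
                 step)
  lp <- onset_latency(fr1)
  expect_equal(unname(lp$onsets["A"]), unname(lp$onsets["B"]))
})

test_that("onset equals a brute-force threshold scan", {
  step <- 0.1
  tg <- seq(0, 30 - step, by = step)
  set.seed(11)
  for (rep in 1:10) {
    w <- c(1, runif(1, -0.5, 0.5))
    curve <- w[1] * canonical_hrf(tg) + w[2] * hrf_derivative(tg)
    fr <- make_fr(cbind(A = curve, B = curve), step)
    lp <- onset_latency(fr, threshold_frac = 0.1)
    # independent scan: central-difference slope, first local max of the
    # curve, earliest crossing of 10% of the max slope before it
    n <- length(curve)
    slope <- c(curve[2] - curve[1],
               (curve[3:n] - curve[1:(n - 2)]) / 2,
               curve[n] - curve[n - 1]) / step
    pk <- which(diff(sign(diff(curve))) < 0)[1] + 1
    thr <- 0.1 * max(slope[1:pk])
    onset_bf <- tg[which(slope[1:pk] >= thr)[1]]
    expect_equal(unname(lp$onsets["A"]), onset_bf)
  }
})

test_that("descending responses use the negative slope criterion", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  fr <- make_fr(cbind(A = -canonical_hrf(tg), B = canonical_hrf(tg)), step)
  lp <- onset_latency(fr)
  expect_equal(unname(lp$polarity["A"]), "descending")
  expect_equal(unname(lp$onsets["A"]), unname(lp$onsets["B"]))
})

test_that("threshold fractions outside (0, 1) are rejected", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  fr <- make_fr(cbind(A = canonical_hrf(tg), B = canonical_hrf(tg)), step)
  expect_error(onset_latency(fr, threshold_frac = 0), "threshold_frac")
  expect_error(onset_latency(fr, threshold_frac = 1.2), "threshold_frac")
})

test_that("onset is robust to moderate observation noise", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  clean <- canonical_hrf(tg)
  lp0 <- onset_latency(make_fr(cbind(A = clean, B = clean), step))
  set.seed(21)
  err <- replicate(100, {
    noisy <- clean + rnorm(length(clean), 0, 0.2 * max(clean))
    noisy <- stats::filter(noisy, rep(1 / 5, 5), sides = 2)
    noisy[is.na(noisy)] <- 0
    lp <- tryCatch(
      onset_latency(make_fr(cbind(A = noisy, B = noisy), step)),
      error = function(e) NULL)
    if (is.null(lp)) NA else lp$onsets["A"] - lp0$onsets["A"]
  })
  expect_lt(abs(mean(err, na.rm = TRUE)), 2)  # bias below 1 TR
})

test_that("constructed latency shifts are detected between groups", {
  step <- 0.2
  tg <- seq(0, 24 - step, by = step)
  set.seed(31)
  mk_profile <- function(shift) {
    ons <- sapply(1:6, function(s) {
      sapply(c(0, 0.4), function(extra) {
        curve <- canonical_hrf(tg - shift - extra - runif(1, 0, 0.2))
        curve_onset <- onset_latency(make_fr(cbind(A = curve, B = curve),
                                             step))
        curve_onset$onsets["A"]
      })
    })
    per_subject <- t(ons)
    colnames(per_subject) <- c("A", "B")
    structure(list(onsets = colMeans(per_subject),
                   slope_at_onset = c(A = 1, B = 1),
                   polarity = c(A = "ascending", B = "ascending"),
                   per_subject = per_subject,
                   region_names = c("A", "B"), threshold_frac = 0.1),
              class = "latency_profile")
  }
  pa <- mk_profile(0)
  pb <- mk_profile(0.5)
  cmp <- compare_latencies(list(gA = pa, gB = pb))
  expect_true(all(abs(cmp$between$mean_diff + 0.5) < 0.3))
  expect_true(all(cmp$between$q < 0.05))
  # within-group: region B lags region A by 0.4 s in both groups
  expect_true(all(cmp$within$q < 0.05))
  expect_true(all(cmp$within$mean_diff < 0))
})

test_that("identical per-subject onsets give p = 1", {
  per <- matrix(3.2, 5, 2, dimnames = list(NULL, c("A", "B")))
  prof <- structure(list(onsets = c(A = 3.2, B = 3.2),
                         slope_at_onset = c(A = 1, B = 1),
                         polarity = c(A = "ascending", B = "ascending"),
                         per_subject = per, region_names = c("A", "B"),
                         threshold_frac = 0.1),
                    class = "latency_profile")
  cmp <- compare_latencies(list(g = prof))
  expect_equal(cmp$within$p, 1)
})

test_that("a lead-lag cohort puts the hub's onset first", {
  spec <- default_cohort_spec(n_subjects = c(adult = 12, child = 3),
                              n_trials = 48, input_mode = "hub_only",
                              obs_noise_var = 0.05, state_noise_var = 0.3,
                              subject_sd = 0.05, embedding_lags = 12,
                              seed = 77)
  coh <- generate_cohort(spec)
  adult <- Filter(function(t) t$group_label == "adult", coh$timeseries)
  basis <- build_hrf_basis(2, 12)
  fr <- fit_event_response(adult, coh$design, basis)
  lp <- onset_latency(fr)
  expect_equal(names(which.min(lp$onsets)), "rAI")
  cmp <- compare_latencies(list(adult = lp))
  hub_rows <- cmp$within$region_a == "rAI" | cmp$within$region_b == "rAI"
  expect_true(all(cmp$within$q[hub_rows] < 0.01))
})
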
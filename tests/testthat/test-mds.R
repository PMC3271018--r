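test_that("the state-space fit recovers hub couplings from synthetic data", {
  spec <- hub_spec()
  fit <- hub_fit()
  truth <- spec$base_params$modulatory_matrices[[1]]
  est <- fit$connections[[1]]
  off <- row(truth) != col(truth)
  expect_gt(cor(truth[off], est[off]), 0.7)
  for (tgt in c("rVLPFC", "ACC", "rDLPFC", "rPPC")) {
    expect_gt(est[tgt, "rAI"], 0)                     # correct sign
    expect_lt(abs(est[tgt, "rAI"] - 0.5), 0.2)        # close to truth
  }
  # the four true edges dominate the estimated off-diagonals
  ranked <- order(abs(est[off]), decreasing = TRUE)
  true_idx <- which(truth[off] != 0)
  expect_true(all(true_idx %in% ranked[1:6]))
})

test_that("the objective trace is monotone non-decreasing", {
  fit <- hub_fit()
  tr <- fit$logevidence_trace
  expect_gt(length(tr), 3)
  rel <- diff(tr) / (abs(tr[-length(tr)]) + 1e-12)
  expect_true(all(rel > -1e-6))
})

test_that("estimated HRF weights load on the canonical basis", {
  fit <- hub_fit()
  w <- abs(fit$hrf_weights)
  expect_true(all(w[, 1] / (w[, 1] + w[, 2]) >= 0.8))
})

test_that("fitting is deterministic", {
  coh <- hub_cohort()
  basis <- build_hrf_basis(2, 8)
  cfg <- mds_config(max_iter = 5)
  f1 <- fit_mds(hub_group("adult")[1:3], coh$design, basis, cfg)
  f2 <- fit_mds(hub_group("adult")[1:3], coh$design, basis, cfg)
  expect_identical(f1$connections, f2$connections)
  expect_identical(f1$logevidence_trace, f2$logevidence_trace)
})

test_that("subject mode returns per-subject estimates averaging to the group", {
  coh <- hub_cohort()
  basis <- build_hrf_basis(2, 8)
  fit <- fit_mds(hub_group("adult")[1:3], coh$design, basis,
                 mds_config(max_iter = 5), mode = "subject")
  expect_length(fit$per_subject, 3)
  expect_equal(Reduce(`+`, fit$per_subject) / 3, fit$connections[[1]],
               tolerance = 1e-12)
})

test_that("a zero-coupling cohort yields small off-diagonal estimates", {
  spec <- default_cohort_spec(n_subjects = c(adult = 5, child = 3),
                              n_trials = 24, embedding_lags = 8,
                              coupling_zero = TRUE, seed = 55)
  coh <- generate_cohort(spec)
  adult <- Filter(function(t) t$group_label == "adult", coh$timeseries)
  basis <- build_hrf_basis(2, 8)
  cfg <- mds_config(max_iter = 10, tol = 1e-5)
  fit <- fit_mds(adult, coh$design, basis, cfg)
  est <- fit$connections[[1]]
  off <- row(est) != col(est)
  expect_lt(mean(abs(est[off])), mean(abs(diag(est))))
  null <- surrogate_null_mds(adult, coh$design, basis, n_surrogates = 100,
                             seed = 56, config = mds_config(max_iter = 2))
  g <- significant_edges(fit, null, alpha = 0.01)
  expect_true(all(!g$significant))
})

test_that("surrogates preserve per-region spectra but break cross-dependence", {
  coh <- hub_cohort()
  y <- preprocess_timeseries(coh$timeseries[[1]])$values
  set.seed(3)
  vr <- replicate(30, {
    ys <- causalconn:::phase_randomize(y)
    c(var_ratio = max(abs(apply(ys, 2, var) / apply(y, 2, var) - 1)),
      xcor = cor(ys[-1, 1], ys[-nrow(ys), 2]))
  })
  expect_lt(max(vr["var_ratio", ]), 0.05)
  expect_lt(abs(mean(vr["xcor", ])), 0.05)
})

test_that("surrogate nulls are reproducible and validated", {
  coh <- hub_cohort()
  basis <- build_hrf_basis(2, 8)
  adult3 <- hub_group("adult")[1:3]
  cfg <- mds_config(max_iter = 2)
  n1 <- surrogate_null_mds(adult3, coh$design, basis, n_surrogates = 100,
                           seed = 9, config = cfg)
  n2 <- surrogate_null_mds(adult3, coh$design, basis, n_surrogates = 100,
                           seed = 9, config = cfg)
  expect_identical(n1$values, n2$values)
  expect_error(surrogate_null_mds(adult3, coh$design, basis,
                                  n_surrogates = 50), ">= 100")
  expect_error(surrogate_null_mds(adult3, coh$design, basis,
                                  method = "shuffle"), "supported")
})

test_that("empirical p-values use the add-one rule", {
  # synthetic null: statistic above all 999 surrogate values -> p = 1/1000
  M <- 3
  regions <- paste0("R", 1:M)
  vals <- array(rnorm(M * M * 999, 0, 0.1), c(M, M, 999),
                dimnames = list(regions, regions, NULL))
  null <- structure(list(statistic_name = "mds_coupling", values = vals,
                         n_surrogates = 999, method = "phase", seed = 1),
                    class = "null_distribution")
  stat <- matrix(0, M, M, dimnames = list(regions, regions))
  stat[1, 2] <- 10
  g <- significant_edges(stat, null, alpha = 0.01)
  expect_equal(g$edge_p[1, 2], 1 / 1000)
  # all statistics at the null center -> nothing significant
  g0 <- significant_edges(matrix(0, M, M, dimnames = list(regions, regions)),
                          null, alpha = 0.01)
  expect_true(all(!g0$significant))
  expect_true(all(g0$edge_p[row(stat) != col(stat)] > 0.5))
  expect_error(significant_edges(stat, null, alpha = 1.5), "alpha")
})

test_that("group differences are antisymmetric under label swap", {
  M <- 3
  regions <- paste0("R", 1:M)
  vals <- array(rnorm(M * M * 120, 0, 0.1), c(M, M, 120),
                dimnames = list(regions, regions, NULL))
  null <- structure(list(statistic_name = "mds_coupling", values = vals,
                         n_surrogates = 120, method = "phase", seed = 1),
                    class = "null_distribution")
  statA <- matrix(rnorm(9), M, M, dimnames = list(regions, regions))
  statB <- matrix(rnorm(9), M, M, dimnames = list(regions, regions))
  ab <- compare_groups_mds(statA, statB, null, null, alpha = 0.05)
  ba <- compare_groups_mds(statB, statA, null, null, alpha = 0.05)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$edge_p, ba$edge_p, tolerance = 1e-12)
  # identical groups: zero differences, nothing flagged
  aa <- compare_groups_mds(statA, statA, null, null, alpha = 0.05)
  expect_true(all(aa$difference == 0))
  expect_true(all(!aa$significant, na.rm = TRUE))
})

test_that("graphs serialize to edge lists and JSON", {
  M <- 3
  regions <- paste0("R", 1:M)
  vals <- array(rnorm(M * M * 100, 0, 0.1), c(M, M, 100),
                dimnames = list(regions, regions, NULL))
  null <- structure(list(statistic_name = "mds_coupling", values = vals,
                         n_surrogates = 100, method = "phase", seed = 1),
                    class = "null_distribution")
  stat <- matrix(0, M, M, dimnames = list(regions, regions))
  stat[2, 1] <- 5
  g <- significant_edges(stat, null, alpha = 0.1)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  df <- write_causal_graph(g, tsv, js)
  expect_equal(nrow(df), M * (M - 1))
  back <- read.delim(tsv)
  row <- back[back$source == "R1" & back$target == "R2", ]
  expect_equal(row$strength, 5)
  expect_true(row$significant)
  parsed <- jsonlite::read_json(js)
  expect_equal(unlist(parsed$region_names), regions)
})
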
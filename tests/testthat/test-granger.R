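sim_var1 <- function(n, A, seed = 1, sd_noise = 1) {
  M <- nrow(A)
  set.seed(seed)
  x <- matrix(0, n, M)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + rnorm(M, 0, sd_noise)
  colnames(x) <- paste0("R", seq_len(M))
  x
}

test_that("least squares recovers VAR(1) coefficients", {
  A <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE)
  x <- sim_var1(2000, A, seed = 2)
  vf <- fit_var(x, order = 1)
  expect_lt(max(abs(vf$coef[, , 1] - A)), 0.05)
  # nesting: reduced residual variance never below the full model's
  for (src in 1:2) {
    expect_true(all(vf$resid_var_reduced[src, ] >=
                      vf$resid_var_full - 1e-12))
  }
})

test_that("white noise yields cross-coefficients near zero", {
  set.seed(3)
  x <- matrix(rnorm(3 * 2000), 2000, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  vf <- fit_var(x, order = 1)
  se <- 1 / sqrt(vf$n_used)
  off <- vf$coef[, , 1][row(diag(3)) != col(diag(3))]
  expect_true(all(abs(off) < 3.5 * se))
})

test_that("degenerate VAR inputs are rejected", {
  x <- matrix(rnorm(400), 200, 2)
  expect_error(fit_var(x[1:5, ], order = 10), "below the series length")
  expect_error(fit_var(x[1:30, ], order = 2), "too short")
  dup <- cbind(a = x[, 1], b = x[, 1])
  expect_error(fit_var(dup, order = 1), "singular|collinear")
})

test_that("bivariate influence matches the analytic log-variance ratio", {
  # y(t) = 0.8 x(t-1) + e, x white: F(x->y) = ln(1 + 0.64 var(x)/var(e))
  set.seed(4)
  n <- 2000
  x <- rnorm(n)
  y <- 0.8 * c(0, x[-n]) + rnorm(n)
  inf <- influence_terms(cbind(x = x, y = y), order = 1)
  expect_gt(inf$F_values["x", "y"], 0.3)
  expect_lt(inf$F_values["y", "x"], 0.05)
  expect_equal(inf$F_values["x", "y"], log(1 + 0.64), tolerance = 0.1)
})

test_that("independent noise stays below the simulated small-sample null", {
  set.seed(5)
  n <- 500; M <- 4
  # simulation oracle: 99th percentile of F on independent white noise
  null_F <- replicate(40, {
    inf <- influence_terms(matrix(rnorm(n * M), n, M), order = 1)
    max(inf$F_values)
  })
  thr <- quantile(null_F, 0.99)
  inf <- influence_terms(matrix(rnorm(n * M), n, M), order = 1)
  expect_true(all(inf$F_values <= thr + 1e-12))
})

test_that("doi is an exact antisymmetric difference", {
  Fm <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("x", "y")))
  d <- doi_matrix(Fm)
  expect_equal(d["x", "y"], 2)
  expect_equal(d["y", "x"], -2)
  expect_equal(doi_matrix(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(6)
  R <- matrix(abs(rnorm(25)), 5, 5); diag(R) <- 0
  expect_equal(doi_matrix(R) + t(doi_matrix(R)), matrix(0, 5, 5))
})

test_that("surrogate doi null is centered and bookkept correctly", {
  adult <- hub_group("adult")[1:3]
  null <- surrogate_null_granger(adult, order = 1, n_surrogates = 120,
                                 seed = 8)
  expect_equal(dim(null$values)[3], 120L)
  expect_true(all(apply(null$values, c(1, 2), function(v) sum(!is.na(v)))
                  [row(diag(5)) != col(diag(5))] == 120))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      v <- null$values[i, j, ]
      expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
    }
  }
  null2 <- surrogate_null_granger(adult, order = 1, n_surrogates = 120,
                                  seed = 8)
  expect_identical(null$values, null2$values)
  expect_error(surrogate_null_granger(adult, method = "bootstrap"),
               "supported")
  expect_error(surrogate_null_granger(adult, n_surrogates = 10), ">= 100")
})

test_that("the group graph recovers the hub topology", {
  adult <- hub_group("adult")
  null <- surrogate_null_granger(adult, order = 1, n_surrogates = 199,
                                 seed = 12)
  g <- group_causal_graph(adult, order = 1, null = null, alpha = 0.05)
  for (tgt in c("rVLPFC", "ACC", "rDLPFC", "rPPC")) {
    expect_true(g$significant[tgt, "rAI"],
                label = sprintf("edge rAI->%s significant", tgt))
  }
  # the hub receives no significant inflow
  expect_true(all(!g$significant["rAI", ]))
})

test_that("group-difference statistics flip sign under label swap", {
  A <- hub_group("adult")[1:4]
  B <- hub_group("child")[1:4]
  nullA <- surrogate_null_granger(A, order = 1, n_surrogates = 100, seed = 1)
  nullB <- surrogate_null_granger(B, order = 1, n_surrogates = 100, seed = 2)
  ab <- compare_groups_doi(A, B, order = 1, nullA = nullA, nullB = nullB,
                           alpha = 0.05)
  ba <- compare_groups_doi(B, A, order = 1, nullA = nullB, nullB = nullA,
                           alpha = 0.05)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-12)
})

test_that("identical groups show no significant differences", {
  A <- hub_group("adult")[1:4]
  nullA <- surrogate_null_granger(A, order = 1, n_surrogates = 100, seed = 3)
  cmp <- compare_groups_doi(A, A, order = 1, nullA = nullA, nullB = nullA,
                            alpha = 0.05)
  expect_true(all(cmp$difference == 0))
  expect_true(all(!cmp$significant, na.rm = TRUE))
})
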
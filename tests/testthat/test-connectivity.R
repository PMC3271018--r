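test_that("identical series correlate perfectly after drift removal", {
  set.seed(1)
  x <- rnorm(200)
  fc <- functional_connectivity(cbind(a = x, b = x, c = rnorm(200)))
  expect_equal(fc["a", "b"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(fc))
  expect_equal(diag(fc), c(a = 1, b = 1, c = 1))
})

test_that("independent white noise shows near-zero correlations", {
  set.seed(2)
  fc <- functional_connectivity(matrix(rnorm(2000 * 4), 2000, 4))
  off <- fc[row(fc) != col(fc)]
  expect_true(all(abs(off) < 0.06))
})

test_that("a shared linear trend does not induce correlation", {
  set.seed(3)
  n <- 300
  a <- rnorm(n); b <- rnorm(n)
  r0 <- functional_connectivity(cbind(a = a, b = b))["a", "b"]
  trend <- 5 * seq_len(n) / n
  r1 <- functional_connectivity(cbind(a = a + trend, b = b + trend))["a", "b"]
  expect_equal(r1, r0, tolerance = 1e-10)
})

test_that("confound regression removes supplied nuisance signals", {
  set.seed(4)
  n <- 400
  conf <- rnorm(n)
  a <- rnorm(n) + 2 * conf
  b <- rnorm(n) + 2 * conf
  r_raw <- functional_connectivity(cbind(a = a, b = b))["a", "b"]
  r_cln <- functional_connectivity(cbind(a = a, b = b),
                                   confounds = conf)["a", "b"]
  expect_gt(r_raw, 0.5)
  expect_lt(abs(r_cln), 0.15)
  expect_error(functional_connectivity(cbind(a = a, b = b),
                                       confounds = conf[1:10]), "same number")
  expect_error(functional_connectivity(cbind(a = conf, b = b),
                                       confounds = conf), "constant")
})

test_that("Fisher z round-trips correlations", {
  r <- c(-0.999, -0.5, 0, 0.3, 0.999)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("group FC differences are detected with correct direction", {
  set.seed(5)
  make_fc <- function(r, n_sub, n_t = 150) {
    lapply(seq_len(n_sub), function(s) {
      z <- rnorm(n_t)
      x <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_t)
      y <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_t)
      functional_connectivity(cbind(rAI = x, rPPC = y, ACC = rnorm(n_t)))
    })
  }
  fcA <- make_fc(0.7, 12)
  fcB <- make_fc(0.1, 12)
  cmp <- compare_fc_groups(fcA, fcB, alpha = 0.01)
  row <- cmp[cmp$region_a == "rAI" & cmp$region_b == "rPPC", ]
  expect_true(row$significant)
  expect_gt(row$mean_diff_z, 0)
  # label flip reverses the sign
  cmp2 <- compare_fc_groups(fcB, fcA, alpha = 0.01)
  expect_equal(cmp2$mean_diff_z, -cmp$mean_diff_z, tolerance = 1e-12)
  # identical groups: nothing flagged
  cmp3 <- compare_fc_groups(fcA, fcA, alpha = 0.01)
  expect_true(all(!cmp3$significant))
  expect_error(compare_fc_groups(fcA[1:2], fcB), ">= 3")
})

test_that("structure-function correlation is exact on affine data", {
  sc <- data.frame(subject_id = paste0("s", 1:10),
                   region_a = "rAI", region_b = "rPPC",
                   fiber_density = seq(10, 55, by = 5), mean_FA = 0.5)
  fun <- setNames(2 + 0.1 * sc$fiber_density, sc$subject_id)
  res <- structure_function_correlation(fun, sc, "rAI->rPPC")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
})

test_that("structure-function coupling is recovered only where generated", {
  spec <- default_cohort_spec(n_subjects = c(adult = 40, child = 40),
                              n_trials = 8, embedding_lags = 6, seed = 31)
  coh <- generate_cohort(spec)
  gt <- coh$ground_truth$edge_strengths
  res <- lapply(c("adult", "child"), function(g) {
    idx <- gt$group == g
    fun <- setNames(gt[idx, "rAI->rPPC"], gt$subject_id[idx])
    structure_function_correlation(fun,
                                   coh$structure[coh$structure$group == g, ],
                                   "rAI->rPPC")
  })
  expect_gt(res[[1]]$r, 0)
  expect_lt(res[[1]]$p, 0.05)
  expect_gt(res[[2]]$p, 0.01)
  expect_lt(abs(res[[2]]$r), 0.45)
})

test_that("structure-function guards degenerate inputs", {
  sc <- data.frame(subject_id = paste0("s", 1:6), region_a = "a",
                   region_b = "b", fiber_density = 1:6, mean_FA = 0.4)
  fun <- setNames(rep(1, 6), sc$subject_id)
  expect_error(structure_function_correlation(fun, sc, "a->b"),
               "zero-variance")
  expect_error(structure_function_correlation(fun[1:3], sc, "a->b"), ">= 5")
})

test_that("structural group comparison flags generated differences", {
  mk <- function(mu_fib, mu_fa, n, g) {
    set.seed(nchar(g) + n)
    data.frame(subject_id = paste0(g, 1:n), region_a = "rAI",
               region_b = "rPPC",
               fiber_density = pmax(rnorm(n, mu_fib, 4), 0),
               mean_FA = pmin(pmax(rnorm(n, mu_fa, 0.04), 0), 1))
  }
  adult <- mk(35, 0.55, 15, "a")
  child <- mk(25, 0.45, 15, "c")
  res <- compare_structural(adult, child, "rAI->rPPC")
  expect_true(all(res$p < 0.01))
  expect_true(all(res$mean_A > res$mean_B))
  same <- compare_structural(adult, adult, "rAI->rPPC")
  expect_true(all(same$p > 0.99))
  bad <- adult; bad$mean_FA[1] <- 1.4
  expect_error(compare_structural(bad, child, "rAI->rPPC"), "FA")
})
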
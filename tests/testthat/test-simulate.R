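two_region_params <- function(c21 = 0.8, q = 0, d = c(1, 0)) {
  C <- matrix(0, 2, 2)
  C[2, 1] <- c21   # region 1 -> region 2
  mds_parameters(C, input_strengths = d, state_noise_cov = q,
                 obs_noise_var = 0, embedding_lags = 4,
                 region_names = c("A", "B"))
}

test_that("the unforced noiseless system stays at zero", {
  p <- two_region_params(q = 0, d = c(0, 0))
  u <- matrix(0, 50, 2)
  s <- simulate_latent(p, u = u, v = matrix(1, 50, 1), seed = 1)
  expect_true(all(s$values == 0))
})

test_that("an impulse echoes one step later scaled by the coupling", {
  p <- two_region_params(c21 = 0.8, q = 0, d = c(1, 0))
  u <- matrix(0, 20, 2); u[1, 1] <- 1
  s <- simulate_latent(p, u = u, v = matrix(1, 20, 1), seed = 1)
  expect_equal(s$values[1, ], c(A = 1, B = 0))
  expect_equal(s$values[2, ], c(A = 0, B = 0.8))
  expect_true(all(abs(s$values[3:20, ]) < 1e-12))
})

test_that("hub targets lag the hub in cross-correlation", {
  spec <- hub_spec()
  par <- spec$base_params
  u <- matrix(1, 3000, 5)
  s <- simulate_latent(par, u = u, v = matrix(1, 3000, 1), seed = 5)
  for (tgt in c("rVLPFC", "ACC", "rDLPFC", "rPPC")) {
    cc <- ccf(s$values[, "rAI"], s$values[, tgt], lag.max = 3, plot = FALSE)
    # ccf(x, y) peaks at negative lag when x leads y
    expect_equal(cc$lag[which.max(abs(cc$acf))], -1)
  }
})

test_that("the impulse response is linear in the input strength", {
  p1 <- two_region_params(c21 = 0.5, d = c(1, 0))
  p2 <- two_region_params(c21 = 0.5, d = c(2, 0))
  u <- matrix(0, 30, 2); u[1, 1] <- 1
  s1 <- simulate_latent(p1, u = u, v = matrix(1, 30, 1), seed = 1)
  s2 <- simulate_latent(p2, u = u, v = matrix(1, 30, 1), seed = 1)
  expect_equal(s2$values, 2 * s1$values, tolerance = 1e-12)
})

test_that("a stable noisy latent process has stationary variance", {
  p <- two_region_params(c21 = 0.6, q = 1, d = c(0, 0))
  u <- matrix(0, 4000, 2)
  s <- simulate_latent(p, u = u, v = matrix(1, 4000, 1), seed = 9)
  v1 <- apply(s$values[1:2000, ], 2, var)
  v2 <- apply(s$values[2001:4000, ], 2, var)
  expect_true(all(v1 / v2 > 0.5 & v1 / v2 < 2))
})

test_that("unstable coupling matrices are refused", {
  C <- matrix(0, 2, 2); C[2, 1] <- 0.5; diag(C) <- 1.05
  expect_error(mds_parameters(C, input_strengths = 1),
               "spectral radius")
})

test_that("latent simulation is deterministic under a fixed seed", {
  p <- two_region_params(q = 1)
  u <- matrix(rbinom(100, 1, 0.5), 50, 2)
  s1 <- simulate_latent(p, u = u, v = matrix(1, 50, 1), seed = 4)
  s2 <- simulate_latent(p, u = u, v = matrix(1, 50, 1), seed = 4)
  expect_identical(s1$values, s2$values)
})

test_that("a noiseless impulse reproduces the canonical HRF", {
  L <- 16
  p <- mds_parameters(matrix(0, 2, 2), input_strengths = c(0, 0),
                      state_noise_cov = 0, obs_noise_var = 0,
                      embedding_lags = L, region_names = c("A", "B"))
  basis <- build_hrf_basis(TR = 2, n_lags = L)
  sv <- matrix(0, 40, 2); sv[1, 1] <- 1
  lat <- structure(list(values = sv, TR = 2), class = "latent_series")
  y <- simulate_bold(lat, p, basis, seed = 1)
  expect_equal(y$values[1:L, "A"], unname(basis$basis_matrix["canonical", ]),
               tolerance = 1e-12)
  expect_true(all(y$values[, "B"] == 0))
})

test_that("the derivative basis response matches its finite-difference oracle", {
  L <- 32
  basis <- build_hrf_basis(TR = 1, n_lags = L)
  p_can <- mds_parameters(matrix(0, 2, 2), input_strengths = c(0, 0),
                          state_noise_cov = 0, obs_noise_var = 0,
                          embedding_lags = L,
                          hrf_basis_weights = rbind(c(1, 0), c(1, 0)))
  p_der <- mds_parameters(matrix(0, 2, 2), input_strengths = c(0, 0),
                          state_noise_cov = 0, obs_noise_var = 0,
                          embedding_lags = L,
                          hrf_basis_weights = rbind(c(0, 1), c(0, 1)))
  sv <- matrix(0, 60, 2); sv[1, ] <- 1
  lat <- structure(list(values = sv, TR = 1), class = "latent_series")
  y_can <- simulate_bold(lat, p_can, basis, seed = 1)$values[, 1]
  y_der <- simulate_bold(lat, p_der, basis, seed = 1)$values[, 1]
  # derivative basis = 1 s backward difference of the canonical response
  oracle <- y_can - c(0, y_can[-60])
  expect_equal(y_der[2:32], oracle[2:32], tolerance = 1e-10)
})

test_that("BOLD simulation is deterministic and validates dimensions", {
  p <- two_region_params(q = 1)
  basis <- build_hrf_basis(TR = 2, n_lags = 4)
  u <- matrix(rbinom(80, 1, 0.4), 40, 2)
  lat <- simulate_latent(p, u = u, v = matrix(1, 40, 1), seed = 2)
  p$obs_noise_var <- c(0.5, 0.5)
  y1 <- simulate_bold(lat, p, basis, seed = 3)
  y2 <- simulate_bold(lat, p, basis, seed = 3)
  expect_identical(y1$values, y2$values)
  p_bad <- p; p_bad$embedding_lags <- 10L
  expect_error(simulate_bold(lat, p_bad, basis), "basis")
})
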
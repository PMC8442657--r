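test_that("gaussian one-time estimates equal the closed-form partial solves", {
  set.seed(21)
  n <- 80; p <- 25
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(1, 4)] %*% c(1.5, -1) + rnorm(n))
  rec <- one_split_estimate(X, y, "gaussian", seed = 3)
  idx1 <- which(rec$J == 1)
  S <- rec$selected$selected
  for (j in seq_len(p)) {
    Sj <- sort(union(j, S))
    bj <- oracle_ols(X[idx1, Sj, drop = FALSE], y[idx1])[1 + match(j, Sj)]
    expect_equal(rec$beta_tilde[j + 1], bj, tolerance = 1e-8)
  }
  # intercept comes from the S-only fit
  b0 <- oracle_ols(X[idx1, S, drop = FALSE], y[idx1])[1]
  expect_equal(rec$beta_tilde[1], b0, tolerance = 1e-8)
})

test_that("coefficients in S match a redundant refit of the same model", {
  set.seed(22)
  n <- 100; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(drop(X[, 2] * 1.2)))
  rec <- one_split_estimate(X, y, "binomial", seed = 8)
  idx1 <- which(rec$J == 1)
  S <- rec$selected$selected
  refit <- fit_glm("binomial", X[idx1, S, drop = FALSE], y[idx1])
  for (j in S)
    expect_equal(rec$beta_tilde[j + 1],
                 unname(refit$coefficients[1 + match(j, S)]),
                 tolerance = 1e-12)
})

test_that("a forced-empty selection reduces to the simple GLM per predictor", {
  set.seed(23)
  X <- matrix(rnorm(50), 50, 1)
  y <- rpois(50, exp(0.4 + 0.5 * X[, 1]))
  rec <- one_split_estimate(X, y, "poisson",
                            selector = function(X, y, family, max_size)
                              integer(0), seed = 2)
  idx1 <- which(rec$J == 1)
  simple <- fit_glm("poisson", X[idx1, , drop = FALSE], y[idx1])
  expect_equal(rec$beta_tilde[2], unname(simple$coefficients[2]),
               tolerance = 1e-10)
})

test_that("smoothing is the exact per-coordinate mean and B = 1 is identity", {
  set.seed(24)
  X <- matrix(rnorm(90 * 20), 90, 20)
  y <- drop(X[, 3] + rnorm(90))
  fit <- ssglm_fit(X, y, "gaussian", B = 7, seed = 5)
  expect_equal(fit$beta_hat, colMeans(fit$beta_tilde, na.rm = TRUE))
  expect_equal(rowSums(fit$J), rep(45, 7))
  one <- ssglm_fit(X, y, "gaussian", B = 1, seed = 5)
  expect_equal(one$beta_hat, drop(one$beta_tilde[1, ]))
})

test_that("splits are order-invariant: recomputing any split reproduces it", {
  set.seed(25)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- rbinom(80, 1, plogis(X[, 1]))
  fit <- ssglm_fit(X, y, "binomial", B = 6, seed = 42)
  for (b in sample(6)) {   # shuffled order, as a parallel scheduler would
    rec <- one_split_estimate(X, y, "binomial",
                              seed = ssglm:::derive_seed(42, b))
    expect_identical(rec$beta_tilde, fit$beta_tilde[b, ])
    expect_identical(rec$J, fit$J[b, ])
  }
  # and the whole fit is bit-reproducible
  expect_identical(fit$beta_hat, ssglm_fit(X, y, "binomial", B = 6,
                                           seed = 42)$beta_hat)
})

test_that("subvector fits match the coordinate path and the plain S1 fit", {
  set.seed(26)
  n <- 90; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(2, 5)] %*% c(1, -1) + rnorm(n))
  # S1 containing every selector output reduces to the plain S1-model fit
  sv <- subvector_fit(X, y, S1 = 1:12, "gaussian", B = 3, seed = 9,
                      selector = function(X, y, family, max_size) c(2L, 5L))
  rec1 <- which(sv$J[1, ] == 1)
  expect_equal(unname(sv$beta_tilde1[1, ]),
               oracle_ols(X[rec1, ], y[rec1])[-1], tolerance = 1e-8)
  # single-coordinate subvector equals the full sweep's coordinate under
  # shared seeds
  fit <- ssglm_fit(X, y, "gaussian", B = 4, seed = 33)
  sv2 <- subvector_fit(X, y, S1 = 5, "gaussian", B = 4, seed = 33)
  expect_equal(unname(sv2$beta1_hat), fit$beta_hat[6], tolerance = 1e-10)
})

test_that("failing splits abort loudly when too frequent", {
  set.seed(27)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rbinom(40, 1, 0.5)
  expect_error(
    ssglm_fit(X, y, "binomial", B = 5, seed = 1,
              selector = function(X, y, family, max_size)
                stop("selector down")),
    "splits failed")
})

test_that("equal splitting beats a lopsided split on average error", {
  set.seed(28)
  d <- simulation_design(n = 150, p = 60, s0 = 4, family = "gaussian",
                         corr = "ar1", rho = 0.5, coef_band = c(0.5, 1.5))
  g <- split_proportion_study(d, q_grid = c(0.1, 0.5), K = 6, B = 25,
                              seed = 3)
  expect_lt(g$mse_avg[g$q == 0.5], g$mse_avg[g$q == 0.1])
})
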
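test_that("variance estimators match the brute-force nested sums", {
  set.seed(31)
  for (rep in 1:5) {
    B <- sample(3:5, 1); n <- sample(6:8, 1); n1 <- n %/% 2
    J <- random_J(B, n, n1)
    bt <- matrix(rnorm(B * 3), B, 3)
    orc <- oracle_ij(J, bt)
    expect_equal(as.numeric(ij_variance(J, bt)), orc$V, tolerance = 1e-12)
    VB <- suppressMessages(bias_corrected_variance(J, bt))
    keep <- orc$VB >= 0
    expect_equal(as.numeric(VB)[keep], orc$VB[keep], tolerance = 1e-12)
    # negative corrected values fall back to the uncorrected variance
    expect_equal(as.numeric(VB)[!keep], orc$V[!keep], tolerance = 1e-12)
  }
})

test_that("constant one-time estimates give zero variance", {
  J <- random_J(4, 8, 4)
  bt <- matrix(2.5, 4, 2)
  expect_equal(as.numeric(ij_variance(J, bt)), c(0, 0))
  expect_equal(as.numeric(suppressMessages(bias_corrected_variance(J, bt))),
               c(0, 0))
})

test_that("bias correction never exceeds the raw variance, missing handled", {
  set.seed(32)
  J <- random_J(10, 12, 6)
  bt <- matrix(rnorm(10 * 4), 10, 4)
  bt[c(2, 7), 3] <- NA          # per-coordinate missingness
  V <- ij_variance(J, bt)
  VB <- suppressMessages(bias_corrected_variance(J, bt))
  expect_true(all(as.numeric(VB) <= as.numeric(V) + 1e-15))
  expect_identical(attr(V, "B_used"), c(10L, 10L, 8L, 10L))
  # the incomplete coordinate agrees with a direct computation on its rows
  ok <- which(is.finite(bt[, 3]))
  expect_equal(V[[3]], oracle_ij(J[ok, ], bt[ok, 3, drop = FALSE])$V,
               tolerance = 1e-12)
  bt[1:9, 2] <- NA
  expect_error(ij_variance(J, bt), "fewer than 2")
})

test_that("confidence intervals and p-values follow the normal formulas", {
  set.seed(33)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- drop(X[, 1] + rnorm(100))
  fit <- ssglm_fit(X, y, "gaussian", B = 12, seed = 2)
  tab <- inference_table(fit, alpha = 0.05)
  VB <- suppressMessages(bias_corrected_variance(fit))
  z <- qnorm(0.975)
  expect_equal(tab$ci_lo, fit$beta_hat - z * sqrt(as.numeric(VB)))
  expect_equal(tab$ci_hi, fit$beta_hat + z * sqrt(as.numeric(VB)))
  expect_equal(tab$pvalue,
               2 * (1 - pnorm(abs(fit$beta_hat) / sqrt(as.numeric(VB)))))
  expect_equal(tab$pvalue_adj[-1],
               pmin(1, tab$pvalue[-1] * fit$p))
  # borderline z: estimate = 1.959964 SE gives p ~ 0.05
  se1 <- tab$se[2]
  expect_equal(2 * (1 - pnorm(1.959964)), 0.05, tolerance = 1e-6)
  # a zero estimate must give p exactly 1
  fit0 <- fit
  fit0$beta_hat[3] <- 0
  expect_equal(inference_table(fit0)$pvalue[3], 1)
})

test_that("subvector covariance is consistent with the scalar estimators", {
  set.seed(34)
  X <- matrix(rnorm(90 * 10), 90, 10)
  y <- drop(X[, c(1, 2)] %*% c(1, -1) + rnorm(90))
  sv <- subvector_fit(X, y, S1 = c(1, 2, 6), "gaussian", B = 10, seed = 4)
  # uncorrected diagonal == scalar IJ variance of each coordinate
  Sig_raw <- subvector_covariance(sv$J, sv$beta_tilde1, bias_correct = FALSE)
  expect_equal(diag(Sig_raw), as.numeric(ij_variance(sv$J, sv$beta_tilde1)),
               tolerance = 1e-12)
  # before PSD repair, the corrected diagonal is exactly the scalar
  # bias-corrected value
  B <- nrow(sv$J); n <- ncol(sv$J); n1 <- sum(sv$J[1, ])
  Bc <- sweep(sv$beta_tilde1, 2, colMeans(sv$beta_tilde1))
  Sig_manual <- Sig_raw - (n / B^2) * (n1 / (n - n1)) * crossprod(Bc)
  VB <- suppressMessages(bias_corrected_variance(sv$J, sv$beta_tilde1))
  keep <- setdiff(seq_along(VB), attr(VB, "fallback"))
  expect_equal(diag(Sig_manual)[keep], as.numeric(VB)[keep],
               tolerance = 1e-12)
  # the returned matrix is the PSD projection of that correction
  Sig <- subvector_covariance(sv)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12))
  expect_equal(Sig, t(Sig))
  # constant estimates give the zero matrix
  Sig0 <- subvector_covariance(random_J(5, 10, 5), matrix(1, 5, 2),
                               bias_correct = FALSE)
  expect_equal(Sig0, matrix(0, 2, 2))
})

test_that("Wald contrasts reduce to squared z-tests and detect null truth", {
  set.seed(35)
  b <- c(0.8, -0.4, 1.1)
  Sig <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
  # r = 1 with a coordinate selector equals the squared z-test
  w <- wald_contrast_test(b, Sig, Q = c(0, 1, 0), R = 0)
  z2 <- (b[2] / sqrt(Sig[2, 2]))^2
  expect_equal(w$T, z2, tolerance = 1e-12)
  expect_equal(w$p_value, pchisq(z2, 1, lower.tail = FALSE))
  # R = Q b gives T = 0, p = 1
  Q <- rbind(c(1, 1, 0), c(0, 0, 1))
  w0 <- wald_contrast_test(b, Sig, Q, R = drop(Q %*% b))
  expect_equal(w0$T, 0)
  expect_equal(w0$p_value, 1)
  # row-scaling the contrast leaves the statistic invariant
  w1 <- wald_contrast_test(b, Sig, Q = c(2, 2, 0), R = 2 * sum(b[1:2]) - 1)
  w2 <- wald_contrast_test(b, Sig, Q = c(1, 1, 0), R = sum(b[1:2]) - 0.5)
  expect_equal(w1$T, w2$T, tolerance = 1e-10)
  expect_error(wald_contrast_test(b, Sig, Q = rbind(c(1, 0, 0), c(1, 0, 0))),
               "full row rank")
  expect_error(wald_contrast_test(b, matrix(0, 3, 3), Q = c(1, 0, 0)),
               "singular")
})
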
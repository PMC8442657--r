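# Independent oracles and shared fixtures for the test suite.

# brute-force nested-loop evaluation of the infinitesimal-jackknife variance
# and its bias-corrected form, straight from the defining sums
oracle_ij <- function(J, bt) {
  B <- nrow(J); n <- ncol(J); n1 <- sum(J[1, ])
  m <- ncol(bt)
  V <- VB <- numeric(m)
  for (j in seq_len(m)) {
    bh <- mean(bt[, j])
    s <- 0
    for (i in seq_len(n)) {
      cij <- 0
      for (b in seq_len(B))
        cij <- cij + (J[b, i] - mean(J[, i])) * (bt[b, j] - bh)
      s <- s + (cij / B)^2
    }
    V[j] <- n * (n - 1) / (n - n1)^2 * s
    VB[j] <- V[j] - (n / B^2) * (n1 / (n - n1)) * sum((bt[, j] - bh)^2)
  }
  list(V = V, VB = VB)
}

# closed-form least-squares coefficients (intercept prepended)
oracle_ols <- function(X, y) {
  Xb <- cbind(1, X)
  drop(solve(crossprod(Xb), crossprod(Xb, y)))
}

# random membership matrix with exactly n1 ones per row
random_J <- function(B, n, n1) {
  t(replicate(B, { v <- integer(n); v[sample.int(n, n1)] <- 1L; v }))
}

# memoised heavy study results shared between acceptance criteria blocks
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(key, expr) {
  if (!exists(key, envir = .study_cache))
    assign(key, force(expr), envir = .study_cache)
  get(key, envir = .study_cache)
}
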
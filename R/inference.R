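# Infinitesimal-jackknife variance estimation for the smoothed estimator,
# per-coefficient confidence intervals / p-values, and Wald contrast tests on
# subvectors.

# per-coordinate IJ machinery shared by the scalar and the bias-corrected
# estimators; honours per-coordinate missingness (a coordinate whose partial
# fit failed in a split uses only its own successful splits, with its own
# split count and mean)
ij_terms <- function(J, beta_tilde) {
  J <- as.matrix(J)
  beta_tilde <- as.matrix(beta_tilde)
  if (nrow(J) != nrow(beta_tilde))
    stop("J and beta_tilde must have one row per split")
  n <- ncol(J)
  n1 <- sum(J[1L, ])
  B <- nrow(J)
  m <- ncol(beta_tilde)
  corr <- n * (n - 1) / (n - n1)^2
  V <- numeric(m)
  upsilon_sum <- numeric(m)   # sum_b (btilde - bhat)^2
  B_used <- integer(m)
  complete <- !colSums(is.na(beta_tilde))
  if (any(complete)) {
    Jc <- sweep(J, 2, colMeans(J))
    Bc <- sweep(beta_tilde[, complete, drop = FALSE], 2,
                colMeans(beta_tilde[, complete, drop = FALSE]))
    covm <- crossprod(Jc, Bc) / B                    # n x m_complete
    V[complete] <- corr * colSums(covm^2)
    upsilon_sum[complete] <- colSums(Bc^2)
    B_used[complete] <- B
  }
  for (j in which(!complete)) {
    ok <- which(is.finite(beta_tilde[, j]))
    if (length(ok) < 2L)
      stop("variance undefined: coefficient ", j - 1L,
           " has fewer than 2 usable splits")
    Jj <- J[ok, , drop = FALSE]
    bj <- beta_tilde[ok, j]
    cj <- drop(crossprod(sweep(Jj, 2, colMeans(Jj)), bj - mean(bj))) /
      length(ok)
    V[j] <- corr * sum(cj^2)
    upsilon_sum[j] <- sum((bj - mean(bj))^2)
    B_used[j] <- length(ok)
  }
  list(V = V, upsilon_sum = upsilon_sum, B_used = B_used, n = n, n1 = n1)
}

#' Infinitesimal-jackknife variance of smoothed coefficients
#'
#' For each coefficient, computes the per-sample covariances between the
#' split-membership indicators and the one-time estimates,
#' \eqn{\widehat{cov}_{ij} = B^{-1}\sum_b (J_{bi} - \bar J_{.i})
#' (\tilde\beta_j^b - \hat\beta_j)}, and returns
#' \eqn{\hat V_j = n(n-1)/(n-n_1)^2 \sum_i \widehat{cov}_{ij}^2}, the
#' subsampling-corrected infinitesimal-jackknife variance.
#'
#' @param J `B x n` 0/1 split-membership matrix (1 = estimation half), or an
#'   `ssglm` fit (in which case `beta_tilde` is taken from it).
#' @param beta_tilde `B x m` matrix of one-time estimates (columns =
#'   coefficients), possibly containing `NA` for failed per-split fits.
#' @return numeric vector of variances, with attributes `B_used` (per-column
#'   split counts) and `n`, `n1`.
#' @export
ij_variance <- function(J, beta_tilde = NULL) {
  if (inherits(J, "ssglm")) { beta_tilde <- J$beta_tilde; J <- J$J }
  t <- ij_terms(J, beta_tilde)
  structure(t$V, B_used = t$B_used, n = t$n, n1 = t$n1)
}

#' Bias-corrected infinitesimal-jackknife variance
#'
#' Subtracts from [ij_variance()] the Monte-Carlo noise term
#' \eqn{(n/B^2)\,(n_1/(n-n_1))\sum_b (\tilde\beta_j^b - \hat\beta_j)^2}
#' caused by using a finite number of splits.  When Monte-Carlo error drives
#' the corrected value below zero the correction is evidently unreliable for
#' that coordinate, and the uncorrected \eqn{\hat V_j} is returned for it
#' instead (reported via a message): \eqn{\hat V_j} is biased upward, so the
#' fallback is conservative, whereas a near-zero variance would manufacture
#' false rejections.
#'
#' @inheritParams ij_variance
#' @return numeric vector of bias-corrected variances (same attributes as
#'   [ij_variance()], plus `V_raw` carrying the uncorrected values and
#'   `fallback` marking coordinates where the uncorrected value was used).
#' @export
bias_corrected_variance <- function(J, beta_tilde = NULL) {
  if (inherits(J, "ssglm")) { beta_tilde <- J$beta_tilde; J <- J$J }
  t <- ij_terms(J, beta_tilde)
  correction <- (t$n / t$B_used^2) * (t$n1 / (t$n - t$n1)) * t$upsilon_sum
  VB <- t$V - correction
  neg <- VB < 0
  if (any(neg)) {
    VB[neg] <- t$V[neg]
    message(sum(neg), " bias-corrected variance(s) fell below zero; ",
            "using the uncorrected variance for those coordinates")
  }
  structure(VB, B_used = t$B_used, n = t$n, n1 = t$n1, V_raw = t$V,
            fallback = which(neg))
}

#' Per-coefficient confidence intervals and p-values
#'
#' Applies the normal-approximation formulas to a smoothed fit: the
#' 100(1 - alpha)% interval is \eqn{\hat\beta_j \pm \Phi^{-1}(1-\alpha/2)
#' \sqrt{\hat V_j^B}} and the two-sided p-value for \eqn{H_0: \beta_j = 0}
#' is \eqn{2\{1 - \Phi(|\hat\beta_j| / \sqrt{\hat V_j^B})\}}, with
#' \eqn{\hat V_j^B} the bias-corrected variance.  Adjusted p-values
#' (Bonferroni over the p non-intercept coefficients) are included when
#' requested.
#'
#' @param fit an `ssglm` object from [ssglm_fit()].
#' @param alpha two-sided level for the confidence intervals.
#' @param adjust multiplicity adjustment for the p-values: `"bonferroni"` or
#'   `"none"`.
#' @return a `data.frame` with one row per coefficient (intercept first):
#'   `index` (0 = intercept), `name`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `pvalue`, `pvalue_adj`, `sel_freq` (selection frequency across splits;
#'   `NA` for the intercept), and `flagged` (coefficient missing in > 20% of
#'   splits).
#' @export
inference_table <- function(fit, alpha = 0.05,
                            adjust = c("bonferroni", "none")) {
  stopifnot(inherits(fit, "ssglm"))
  adjust <- match.arg(adjust)
  VB <- as.numeric(bias_corrected_variance(fit))
  se <- sqrt(pmax(VB, 0))
  z <- qnorm(1 - alpha / 2)
  est <- fit$beta_hat
  pv <- ifelse(se > 0, 2 * (1 - pnorm(abs(est) / se)),
               as.numeric(est == 0))
  padj <- pv
  padj[-1L] <- p.adjust(pv[-1L], method = if (adjust == "bonferroni")
    "bonferroni" else "none")
  padj[1L] <- NA_real_
  nm <- c("(Intercept)",
          if (!is.null(fit$xnames)) fit$xnames else paste0("X", seq_len(fit$p)))
  out <- data.frame(
    index = 0:fit$p, name = nm, estimate = est, se = se,
    ci_lo = est - z * se, ci_hi = est + z * se,
    pvalue = pv, pvalue_adj = padj,
    sel_freq = c(NA_real_, fit$sel_freq),
    flagged = (0:fit$p) %in% fit$flagged,
    row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' Covariance of a smoothed subvector estimate
#'
#' Builds the `n x |S1|` matrix of per-sample covariances between the
#' membership indicators and the per-split subvector estimates and returns
#' its Gram product, scaled by the same \eqn{n(n-1)/(n-n_1)^2} subsampling
#' correction as the scalar estimator, so the diagonal of the uncorrected
#' matrix coincides with [ij_variance()] of each coordinate.  By default the
#' matrix analogue of the finite-B bias correction is subtracted
#' (\eqn{(n/B^2)(n_1/(n-n_1)) \sum_b (\tilde\beta^b - \hat\beta)
#' (\tilde\beta^b - \hat\beta)^T}), after which the matrix is projected back
#' onto the PSD cone by flooring its eigenvalues; the diagonal then matches
#' [bias_corrected_variance()].
#'
#' @param J `B x n` membership matrix or an `ssglm_subvector` fit.
#' @param beta_tilde1 `B x p1` matrix of per-split subvector estimates.
#' @param bias_correct subtract the finite-B Monte-Carlo term (recommended
#'   whenever `B` is not much larger than `n`).
#' @return a symmetric PSD `p1 x p1` covariance matrix.
#' @export
subvector_covariance <- function(J, beta_tilde1 = NULL, bias_correct = TRUE) {
  if (inherits(J, "ssglm_subvector")) {
    beta_tilde1 <- J$beta_tilde1; J <- J$J
  }
  J <- as.matrix(J); beta_tilde1 <- as.matrix(beta_tilde1)
  if (nrow(J) < 2L) stop("need at least 2 splits")
  if (any(is.na(beta_tilde1)))
    stop("subvector estimates contain failed splits; drop them first")
  B <- nrow(J); n <- ncol(J); n1 <- sum(J[1L, ])
  Jc <- sweep(J, 2, colMeans(J))
  Bc <- sweep(beta_tilde1, 2, colMeans(beta_tilde1))
  COV <- crossprod(Jc, Bc) / B                     # n x p1
  Sigma <- n * (n - 1) / (n - n1)^2 * crossprod(COV)
  if (bias_correct) {
    Sigma <- Sigma - (n / B^2) * (n1 / (n - n1)) * crossprod(Bc)
    e <- eigen(Sigma, symmetric = TRUE)
    floor_ev <- max(1e-12, 1e-10 * max(abs(e$values)))
    if (any(e$values < floor_ev)) {
      ev <- pmax(e$values, floor_ev)
      Sigma <- e$vectors %*% (ev * t(e$vectors))
    }
  }
  (Sigma + t(Sigma)) / 2
}

#' Wald test of linear contrasts on a subvector
#'
#' Tests \eqn{H_0: Q\beta^{(1)} = R} with the statistic
#' \eqn{T = (Q\hat\beta^{(1)} - R)^T [Q \hat\Sigma^{(1)} Q^T]^{-1}
#' (Q\hat\beta^{(1)} - R)}, referred to the chi-square distribution with
#' `r = nrow(Q)` degrees of freedom.
#'
#' @param beta1_hat subvector estimate (length `p1`), or an
#'   `ssglm_subvector` fit (in which case `Sigma1` defaults to
#'   [subvector_covariance()] of the fit).
#' @param Sigma1 `p1 x p1` covariance of the estimate.
#' @param Q `r x p1` contrast matrix (full row rank); a vector is treated as
#'   a single row.
#' @param R length-`r` right-hand side (default zeros).
#' @return an object of class `ssglm_contrast`: `T` (statistic), `df`,
#'   `p_value`, plus the inputs.
#' @export
wald_contrast_test <- function(beta1_hat, Sigma1 = NULL, Q, R = NULL) {
  if (inherits(beta1_hat, "ssglm_subvector")) {
    fit <- beta1_hat
    if (is.null(Sigma1)) Sigma1 <- subvector_covariance(fit)
    beta1_hat <- fit$beta1_hat
  }
  if (is.vector(Q)) Q <- matrix(Q, nrow = 1)
  Q <- as.matrix(Q)
  p1 <- length(beta1_hat)
  r <- nrow(Q)
  if (ncol(Q) != p1) stop("Q must have ", p1, " columns")
  if (qr(Q)$rank < r) stop("Q must have full row rank")
  if (is.null(R)) R <- numeric(r)
  if (length(R) != r) stop("R must have length nrow(Q)")
  delta <- drop(Q %*% beta1_hat) - R
  M <- Q %*% Sigma1 %*% t(Q)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("Q Sigma1 Q^T is singular; reduce or reparameterize the contrast"))
  T_stat <- drop(t(delta) %*% Minv %*% delta)
  structure(list(T = T_stat, df = r,
                 p_value = pchisq(T_stat, df = r, lower.tail = FALSE),
                 Q = Q, R = R, beta1_hat = beta1_hat, Sigma1 = Sigma1),
            class = "ssglm_contrast")
}

#' @export
print.ssglm_contrast <- function(x, ...) {
  cat("Wald contrast test: T =", format(x$T, digits = 4),
      "on", x$df, "df, p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
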
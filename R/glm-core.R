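#' Average negative log-likelihood of a canonical-link GLM
#'
#' Computes \eqn{(1/n)\sum_i \{A(\bar x_i \beta) - y_i \bar x_i \beta\}},
#' the per-observation negative log-likelihood with the response-only term
#' \eqn{c(y)} dropped (it does not depend on \eqn{\beta}).
#'
#' @param family an [ssglm_family()] object or family name.
#' @param beta coefficient vector, same length as `ncol(X)`.
#' @param X design matrix *including* its intercept column.
#' @param y response vector.
#' @return a scalar.
#' @export
negative_loglik <- function(family, beta, X, y) {
  family <- as_ssglm_family(family)
  X <- as.matrix(X)
  if (length(beta) != ncol(X))
    stop("length(beta) = ", length(beta), " but ncol(X) = ", ncol(X))
  if (length(y) != nrow(X))
    stop("length(y) = ", length(y), " but nrow(X) = ", nrow(X))
  family$check_response(y)
  theta <- drop(X %*% beta)
  mean(family$A(theta) - y * theta)
}

#' Maximum-likelihood fit of a low-dimensional GLM
#'
#' Newton-Raphson (iteratively reweighted least squares with the observed
#' information) for a canonical-link GLM of `y` on `X_S` plus an intercept.
#' Initialization puts all coefficients at zero except the intercept, which
#' starts at the link of the response mean (clamped into the mean space).
#' Each iteration halves the step (up to 10 times) if the objective fails to
#' decrease; convergence is declared when the maximum absolute coefficient
#' change drops below `tol`.
#'
#' @param family an [ssglm_family()] object or family name.
#' @param X_S an `n x |S|` predictor matrix *without* the intercept column
#'   (use `NULL` or a zero-column matrix for an intercept-only model).
#' @param y response vector.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the coefficient change.
#' @param start optional starting coefficient vector of length `1 + ncol(X_S)`.
#' @return an object of class `ssglm_glm`: `coefficients` (intercept first,
#'   then the columns of `X_S` in their given order), `converged`,
#'   `iterations`, `neg_loglik`, and `observed_information`
#'   (\eqn{(1/n)\bar X^T W \bar X} at the solution, symmetric PSD).
#'   Non-convergence (e.g. logistic separation) is reported through
#'   `converged = FALSE`, never silently.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' y <- rbinom(20, 1, plogis(X[, 1]))
#' fit_glm("binomial", X, y)$coefficients
#' @export
fit_glm <- function(family, X_S, y, max_iter = 100L, tol = 1e-8,
                    start = NULL) {
  family <- as_ssglm_family(family)
  family$check_response(y)
  n <- length(y)
  if (is.null(X_S)) X_S <- matrix(numeric(0), n, 0)
  X_S <- as.matrix(X_S)
  if (nrow(X_S) != n) stop("nrow(X_S) must equal length(y)")
  if (ncol(X_S) + 1L >= n)
    stop("model dimension ", ncol(X_S) + 1L, " must be < n = ", n)
  Xb <- cbind(1, X_S)
  sds <- apply(Xb[, -1, drop = FALSE], 2, sd)
  if (any(sds == 0))
    stop("rank deficiency: constant predictor column(s) ",
         paste(which(sds == 0), collapse = ", "))
  if (qr(Xb)$rank < ncol(Xb))
    stop("rank deficiency: design matrix with intercept is not full rank")
  r <- cpp_fit_glm(Xb, y, family$code, as.integer(max_iter), tol,
                   if (!is.null(start)) as.numeric(start) else NULL)
  if (!r$ok) stop("rank deficiency or numerical failure in Newton solve")
  structure(
    list(coefficients = drop(r$coefficients),
         converged = r$converged,
         iterations = r$iterations,
         neg_loglik = r$neg_loglik,
         observed_information = r$observed_information,
         family = family$name),
    class = "ssglm_glm")
}

#' @export
print.ssglm_glm <- function(x, ...) {
  cat("low-dimensional ", x$family, " GLM fit (",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations)\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
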
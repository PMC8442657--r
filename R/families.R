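#' Exponential-family descriptions for canonical-link GLMs
#'
#' Returns the building blocks of a linear exponential family with density
#' \eqn{f(y \mid \theta) = \exp\{y\theta - A(\theta) + c(y)\}} under the
#' canonical link, i.e. the natural parameter equals the linear predictor.
#' The cumulant \eqn{A}, its derivative (the inverse link), the variance
#' function \eqn{\nu(\mu)} and the canonical link \eqn{g} are exposed as
#' closures; \eqn{A''(\theta) > 0} throughout the admissible range.
#'
#' For the binomial and poisson families the natural parameter is clamped to
#' \eqn{[-30, 30]} inside \eqn{A} and \eqn{A'} to avoid overflow; clamping at
#' that magnitude is far outside any linear predictor a converged fit visits.
#'
#' @param name one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @return an object of class `ssglm_family`: a list with elements `name`,
#'   `code` (integer code used by the compiled fitter), `A`, `mean`
#'   (\eqn{A'}, the inverse link), `variance`, `link`, and
#'   `check_response(y)` which errors (naming the first offending index) on
#'   inadmissible response values.
#' @examples
#' fam <- ssglm_family("binomial")
#' fam$A(0)            # log(2)
#' fam$mean(fam$link(0.3))  # round trip: 0.3
#' @export
ssglm_family <- function(name = c("gaussian", "binomial", "poisson")) {
  name <- match.arg(name)
  clamp <- function(theta) pmin(pmax(theta, -30), 30)
  fam <- switch(name,
    gaussian = list(
      code = 0L,
      A = function(theta) theta^2 / 2,
      mean = function(theta) theta,
      variance = function(mu) rep_len(1, length(mu)),
      link = function(mu) mu,
      check_response = function(y) {
        bad <- which(!is.finite(y))
        if (length(bad)) stop("non-finite response at index ", bad[1L])
        invisible(TRUE)
      }),
    binomial = list(
      code = 1L,
      A = function(theta) {
        theta <- clamp(theta)
        ifelse(theta > 0, theta + log1p(exp(-theta)), log1p(exp(theta)))
      },
      mean = function(theta) plogis(clamp(theta)),
      variance = function(mu) mu * (1 - mu),
      link = function(mu) log(mu / (1 - mu)),
      check_response = function(y) {
        bad <- which(!(y %in% c(0, 1)))
        if (length(bad))
          stop("binomial response must be 0/1; offending index ", bad[1L])
        invisible(TRUE)
      }),
    poisson = list(
      code = 2L,
      A = function(theta) exp(clamp(theta)),
      mean = function(theta) exp(clamp(theta)),
      variance = function(mu) mu,
      link = function(mu) log(mu),
      check_response = function(y) {
        bad <- which(!is.finite(y) | y < 0 | y != round(y))
        if (length(bad))
          stop("poisson response must be a nonnegative integer; ",
               "offending index ", bad[1L])
        invisible(TRUE)
      }))
  fam$name <- name
  class(fam) <- "ssglm_family"
  fam
}

as_ssglm_family <- function(family) {
  if (inherits(family, "ssglm_family")) return(family)
  ssglm_family(family)
}

#' @export
print.ssglm_family <- function(x, ...) {
  cat("ssglm family:", x$name, "(canonical link)\n")
  invisible(x)
}
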
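# Synthetic designs: multivariate-normal predictors with identity / AR(1) /
# compound-symmetry correlation, sparse coefficient vectors, and gaussian /
# logistic / poisson outcomes.  Presets encode the bundled simulation-study
# designs so every stage of the method is testable without external data.

#' Predictor covariance matrix
#'
#' `identity` gives the identity; `ar1` gives \eqn{\Sigma_{ij} =
#' \rho^{|i-j|}}; `cs` (compound symmetry) gives \eqn{\Sigma_{ij} = \rho}
#' for \eqn{i \ne j} and 1 on the diagonal.
#'
#' @param corr one of `"identity"`, `"ar1"`, `"cs"`.
#' @param p dimension.
#' @param rho correlation parameter; must lie in (-1, 1) for `ar1` and in
#'   (-1/(p-1), 1) for `cs` (positive definiteness).
#' @return a `p x p` covariance matrix.
#' @export
make_covariance <- function(corr = c("identity", "ar1", "cs"), p, rho = 0) {
  corr <- match.arg(corr)
  if (corr == "identity") return(diag(p))
  if (corr == "ar1") {
    if (abs(rho) >= 1) stop("ar1 requires rho in (-1, 1)")
    return(rho^abs(outer(seq_len(p), seq_len(p), "-")))
  }
  if (rho >= 1 || rho <= -1 / (p - 1))
    stop("cs requires rho in (-1/(p-1), 1)")
  m <- matrix(rho, p, p); diag(m) <- 1
  m
}

#' Specify a simulation design
#'
#' Bundles the generative truth for one synthetic study: dimensions, family,
#' predictor correlation, and the rule producing the sparse coefficient
#' vector.  Nonzero coefficients are either drawn with magnitudes uniform on
#' `coef_band` and independent random signs (`signs = "random"`), all
#' positive (`signs = "positive"`), or fixed at `coef_values`; the active set
#' is either drawn uniformly at random or fixed at `active_set`.
#'
#' @param n,p sample size and number of predictors.
#' @param s0 number of nonzero coefficients (ignored when `coef_values` and
#'   `active_set` are given).
#' @param family `"gaussian"`, `"binomial"`, or `"poisson"`.
#' @param corr,rho predictor correlation structure, see [make_covariance()].
#' @param coef_band length-2 magnitude band for random coefficients.
#' @param signs `"random"` or `"positive"` signs for random coefficients.
#' @param coef_values optional fixed coefficient values (implies fixed s0).
#' @param active_set optional fixed active indices (same length as
#'   `coef_values` when both given).
#' @param intercept true intercept.
#' @param truncate truncate predictor entries at +/- 3 SD; defaults to on
#'   for the poisson family (keeps \eqn{e^{x\beta}} bounded) and off
#'   otherwise.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n, p, s0 = NULL, family = "gaussian",
                              corr = "identity", rho = 0,
                              coef_band = c(0.5, 1.5), signs = "random",
                              coef_values = NULL, active_set = NULL,
                              intercept = 0, truncate = NULL) {
  family <- as_ssglm_family(family)$name
  if (!is.null(coef_values)) s0 <- length(coef_values)
  if (!is.null(active_set)) {
    active_set <- sort(as.integer(active_set))
    if (!is.null(coef_values) && length(active_set) != length(coef_values))
      stop("active_set and coef_values must have equal length")
    s0 <- length(active_set)
  }
  if (is.null(s0)) stop("supply s0, coef_values, or active_set")
  if (s0 >= n) stop("s0 must be < n")
  if (is.null(truncate)) truncate <- (family == "poisson")
  make_covariance(corr, min(p, 3L), rho)  # validates rho early
  structure(list(n = n, p = p, s0 = s0, family = family, corr = corr,
                 rho = rho, coef_band = coef_band, signs = signs,
                 coef_values = coef_values, active_set = active_set,
                 intercept = intercept, truncate = truncate),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation design: ", x$family, ", n = ", x$n, ", p = ", x$p,
      ", s0 = ", x$s0, ", corr = ", x$corr,
      if (x$corr != "identity") paste0(" (rho = ", x$rho, ")"), "\n", sep = "")
  invisible(x)
}

#' Bundled simulation-study presets
#'
#' The five designs exercised throughout the package:
#' \describe{
#'   \item{example1}{gaussian, n = 500, p = 1000, s0 = 10, AR(1) rho = 0.5,
#'     coefficient magnitudes Unif(0.5, 1.5) with random signs.}
#'   \item{example2}{poisson, n = 300, p = 400, coefficients
#'     (0.4, 0.6, 0.8, 1.0, 1.2) at random indices, identity correlation,
#'     intercept 1.}
#'   \item{example3}{poisson, n = 400, p = 500, s0 = 6, magnitudes
#'     Unif(0.5, 1) all positive, intercept 1; `corr` selectable.}
#'   \item{example4}{logistic, n = 400, p = 500, active set
#'     {218, 242, 269, 417} with coefficients (-2, -1, 1, 2); `corr`
#'     selectable.}
#'   \item{example5}{logistic, n = 200, p = 300, active set {10, 20, 30}
#'     with coefficients (2, -2, 2), AR(1) with selectable `rho`.}
#' }
#'
#' @param preset preset name.
#' @param corr,rho correlation structure override where the design leaves it
#'   free (`example3` / `example4` default to identity; `example5` is AR(1)
#'   with `rho` defaulting to 0.25).
#' @return a [simulation_design()] object.
#' @export
example_design <- function(preset = c("example1", "example2", "example3",
                                      "example4", "example5"),
                           corr = NULL, rho = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    example1 = simulation_design(500, 1000, s0 = 10, family = "gaussian",
                                 corr = "ar1", rho = 0.5,
                                 coef_band = c(0.5, 1.5), signs = "random"),
    example2 = simulation_design(300, 400, family = "poisson",
                                 coef_values = c(0.4, 0.6, 0.8, 1.0, 1.2),
                                 corr = "identity", intercept = 1),
    example3 = simulation_design(400, 500, s0 = 6, family = "poisson",
                                 corr = if (is.null(corr)) "identity" else corr,
                                 rho = if (is.null(rho)) 0.5 else rho,
                                 coef_band = c(0.5, 1), signs = "positive",
                                 intercept = 1),
    example4 = simulation_design(400, 500, family = "binomial",
                                 corr = if (is.null(corr)) "identity" else corr,
                                 rho = if (is.null(rho)) 0.5 else rho,
                                 coef_values = c(-2, -1, 1, 2),
                                 active_set = c(218, 242, 269, 417)),
    example5 = simulation_design(200, 300, family = "binomial",
                                 corr = "ar1",
                                 rho = if (is.null(rho)) 0.25 else rho,
                                 coef_values = c(2, -2, 2),
                                 active_set = c(10, 20, 30)))
}

#' Draw one dataset from a simulation design
#'
#' Predictor rows are zero-mean multivariate normal with the design
#' covariance (drawn via the Cholesky factor, optionally truncated at
#' +/- 3 SD entrywise); the coefficient vector is drawn per the design's
#' rule; the outcome is generated from the canonical-link GLM of the
#' design's family.  The generative truth is returned alongside the data so
#' parameter-recovery checks need no extra bookkeeping.
#'
#' @param design a [simulation_design()] object.
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return a list: `X` (`n x p`), `y`, `beta_star` (length `p`, zeros off
#'   the active set), `active` (active indices), `intercept`, `design`.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n; p <- design$p; s0 <- design$s0
  active <- if (!is.null(design$active_set)) design$active_set
            else sort(sample.int(p, s0))
  bvals <- if (!is.null(design$coef_values)) design$coef_values
  else {
    mag <- runif(s0, design$coef_band[1], design$coef_band[2])
    if (design$signs == "random") mag * sample(c(-1, 1), s0, replace = TRUE)
    else mag
  }
  beta_star <- numeric(p)
  beta_star[active] <- bvals
  Z <- matrix(rnorm(n * p), n, p)
  if (design$corr != "identity") {
    R <- chol(make_covariance(design$corr, p, design$rho))
    X <- Z %*% R
  } else X <- Z
  if (design$truncate) X <- pmin(pmax(X, -3), 3)
  eta <- design$intercept + drop(X[, active, drop = FALSE] %*% bvals)
  y <- switch(design$family,
    gaussian = eta + rnorm(n),
    binomial = rbinom(n, 1, plogis(eta)),
    poisson = {
      mu <- exp(pmin(eta, 30))
      if (any(mu > 1e10))
        stop("poisson mean overflow after clamping; use smaller coefficients")
      rpois(n, mu)
    })
  list(X = X, y = y, beta_star = beta_star, active = active,
       intercept = design$intercept, design = design)
}
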
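# Variable-selection procedures applied to the screening half of each split.
# All selectors return a SelectionResult: ascending 1-based predictor indices
# (never the intercept), capped in size so the downstream partial fits stay
# well-posed.

new_selection_result <- function(selected, selector_name, tuning = list()) {
  selected <- sort(unique(as.integer(selected)))
  structure(list(selected = selected, selector_name = selector_name,
                 tuning = tuning),
            class = "ssglm_selection")
}

#' @export
print.ssglm_selection <- function(x, ...) {
  cat("selection (", x$selector_name, "): ", length(x$selected),
      " predictors\n", sep = "")
  print(x$selected)
  invisible(x)
}

default_size_cap <- function(n) max(1L, floor(n / 3))

# standardize columns on the selection half only; selection is index-based so
# downstream fits always use raw columns
standardize_cols <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  s[s == 0] <- 1
  sweep(Xc, 2, s, "/")
}

#' Sure independence screening
#'
#' Ranks predictors by marginal association with the response and keeps the
#' top `d`.  Columns are centred and scaled on this half-sample first.  For
#' the gaussian family the utility is the absolute standardized marginal
#' score statistic \eqn{|X_j^T (y - \bar y)| / (\|X_j\| \, \hat{sd}(y))},
#' which for standardized predictors ranks identically to the magnitude of
#' the single-covariate least-squares slope.  For the binomial family the
#' utility is the absolute slope of the per-predictor single-covariate
#' logistic fit.  For the poisson family the utility is the absolute
#' correlation of each column with `log(1 + y)`: the log transform
#' linearizes the exponential mean, whereas both the raw-scale correlation
#' and the marginal poisson MLE are dominated by the most extreme counts and
#' can rank true signals arbitrarily low under heavy marginal
#' overdispersion.  Ties are broken by ascending predictor index.
#'
#' @param X predictor matrix of the screening half-sample (`n2 x p`).
#' @param y response vector of the screening half-sample.
#' @param family family name or [ssglm_family()] object; picks the marginal
#'   utility as described above.
#' @param d number of predictors to keep; defaults to the conventional
#'   screening size `floor(n2 / log(n2))`, except for the binomial family
#'   where it is `floor(n2 / (4 log(n2)))`.  A binary response carries at
#'   most 1/4 unit of Fisher information per observation, and downstream
#'   partial logistic fits on a half-sample of comparable size degrade
#'   visibly (inflated estimates, separation-driven non-convergence) when
#'   the model dimension approaches `n/5`; the reduced binomial default —
#'   the same one used by standard screening software — keeps them
#'   well-posed at realistic sample sizes.
#' @param max_size hard cap on the returned set size (defaults to
#'   `floor(n2/3)`).
#' @return an `ssglm_selection` object.
#' @export
sis_screen <- function(X, y, family = "gaussian", d = NULL, max_size = NULL) {
  X <- as.matrix(X)
  n2 <- nrow(X); p <- ncol(X)
  fam <- as_ssglm_family(family)
  if (is.null(d))
    d <- max(1L, if (fam$name == "binomial") floor(n2 / (4 * log(n2)))
             else floor(n2 / log(n2)))
  if (d >= n2) stop("screening size d = ", d, " must be < n2 = ", n2)
  if (is.null(max_size)) max_size <- default_size_cap(n2)
  d <- min(d, p, max_size)
  Xs <- standardize_cols(X)
  if (fam$name == "binomial") {
    util <- drop(cpp_marginal_coefs(Xs, y, fam$code, 50L, 1e-6))
  } else {
    yy <- if (fam$name == "poisson") log1p(y) else y
    yc <- yy - mean(yy)
    sdy <- sqrt(mean(yc^2))
    if (sdy == 0) sdy <- 1
    util <- abs(drop(crossprod(Xs, yc))) / (n2 * sdy)
  }
  keep <- order(-util, seq_len(p))[seq_len(d)]
  new_selection_result(keep, "sis", list(d = d))
}

# shared core of the penalized selectors (via glmnet); `penalty_weights`
# implements the one-step local-linear-approximation reweighting for SCAD/MCP
penalized_select <- function(X, y, family, alpha, n_folds, max_size,
                             selector_name, penalty = c("none", "scad", "mcp"),
                             nlambda = 50L) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  n2 <- nrow(X); p <- ncol(X)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (is.null(max_size)) max_size <- default_size_cap(n2)
  fam <- as_ssglm_family(family)$name
  foldid <- sample(rep(seq_len(n_folds), length.out = n2))
  cv <- glmnet::cv.glmnet(X, y, family = fam, alpha = alpha, foldid = foldid,
                          nlambda = nlambda, standardize = TRUE)
  lam <- cv$lambda.min
  b <- drop(coef(cv, s = "lambda.min"))[-1L]
  if (penalty != "none") {
    # one-step LLA: reweighted L1 with the penalty derivative at the lasso
    # solution (SCAD a = 3.7, MCP gamma = 3)
    ab <- abs(b)
    w <- if (penalty == "scad") {
      a <- 3.7
      ifelse(ab <= lam, 1, pmax(a * lam - ab, 0) / ((a - 1) * lam))
    } else {
      gam <- 3
      pmax(1 - ab / (gam * lam), 0)
    }
    fit2 <- glmnet::glmnet(X, y, family = fam, alpha = 1,
                           penalty.factor = w, lambda = lam * pmax(mean(w), 1e-3),
                           standardize = TRUE)
    b <- drop(coef(fit2))[-1L]
  }
  supp <- which(b != 0)
  if (length(supp) == 0) {
    # empty support at the chosen lambda: fall back to the strongest
    # coefficient anywhere along the path
    path <- as.matrix(cv$glmnet.fit$beta)
    j <- which.max(apply(abs(path), 1, max))
    warning("empty support at chosen lambda; falling back to predictor ", j)
    supp <- j
  }
  if (length(supp) > max_size)
    supp <- supp[order(-abs(b[supp]), supp)][seq_len(max_size)]
  new_selection_result(supp, selector_name,
                       list(lambda = lam, n_folds = n_folds, alpha = alpha))
}

#' Cross-validated LASSO selection
#'
#' Fits an L1-penalized GLM path with [glmnet::cv.glmnet()], picks the
#' deviance-minimizing penalty, and returns the support of that fit
#' (truncated to `max_size` by largest absolute coefficient if needed).
#' Fold assignment is drawn from the current RNG state, so selection is a
#' deterministic function of the half-sample and the seed in force.
#'
#' @inheritParams sis_screen
#' @param n_folds number of cross-validation folds.
#' @param max_size hard cap on the selected-set size (default `floor(n2/3)`).
#' @return an `ssglm_selection` object.
#' @export
lasso_select <- function(X, y, family, n_folds = 10L, max_size = NULL) {
  penalized_select(X, y, family, alpha = 1, n_folds = n_folds,
                   max_size = max_size, selector_name = "lasso")
}

#' Elastic-net selection
#'
#' As [lasso_select()] with an L1/L2 mixing weight; `mixing = 1` reduces
#' exactly to the lasso on identical folds.
#'
#' @inheritParams lasso_select
#' @param mixing elastic-net mixing parameter in (0, 1].
#' @export
elastic_net_select <- function(X, y, family, n_folds = 10L, mixing = 0.5,
                               max_size = NULL) {
  penalized_select(X, y, family, alpha = mixing, n_folds = n_folds,
                   max_size = max_size, selector_name = "elasticnet")
}

#' SCAD selection via one-step local linear approximation
#'
#' Reweighted L1 fit with weights given by the SCAD penalty derivative
#' (a = 3.7) at the cross-validated lasso solution.
#' @inheritParams lasso_select
#' @export
scad_select <- function(X, y, family, n_folds = 10L, max_size = NULL) {
  penalized_select(X, y, family, alpha = 1, n_folds = n_folds,
                   max_size = max_size, selector_name = "scad",
                   penalty = "scad")
}

#' MCP selection via one-step local linear approximation
#'
#' Reweighted L1 fit with weights given by the MCP penalty derivative
#' (gamma = 3) at the cross-validated lasso solution.
#' @inheritParams lasso_select
#' @export
mcp_select <- function(X, y, family, n_folds = 10L, max_size = NULL) {
  penalized_select(X, y, family, alpha = 1, n_folds = n_folds,
                   max_size = max_size, selector_name = "mcp",
                   penalty = "mcp")
}

# resolve a selector by name into a function(X, y, family, max_size)
make_selector <- function(selector = c("sis", "lasso", "elasticnet", "scad",
                                       "mcp"),
                          args = list()) {
  if (is.function(selector)) return(selector)
  selector <- match.arg(selector)
  fn <- switch(selector,
    sis = sis_screen, lasso = lasso_select, elasticnet = elastic_net_select,
    scad = scad_select, mcp = mcp_select)
  function(X, y, family, max_size) {
    # user-supplied options (e.g. an explicit max_size or d) take precedence
    arglist <- utils::modifyList(
      list(X = X, y = y, family = family, max_size = max_size), args)
    do.call(fn, arglist)
  }
}
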
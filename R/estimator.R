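# Smoothed (split-and-average) estimators: the full-coefficient sweep and the
# subvector variant.  Every split draws its own RNG stream from the master
# seed and a counter, so results are invariant to the order in which splits
# are computed (and hence to any parallel execution layout).

derive_seed <- function(seed, counter, salt = 0L) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(counter) +
                7919 * as.numeric(salt)) %% 2147483647)
}

check_xy <- function(X, y, family) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  family <- as_ssglm_family(family)
  family$check_response(y)
  list(X = X, y = y, family = family)
}

# draw a split of size n1; for binomial responses redraw (up to 100 times)
# until both halves contain both classes, since a single-class half makes the
# selector or the partial fits degenerate
draw_split <- function(n, n1, y, family) {
  for (attempt in seq_len(100L)) {
    idx1 <- sample.int(n, n1)
    if (family$name != "binomial") return(idx1)
    y1 <- y[idx1]; y2 <- y[-idx1]
    if (length(unique(y1)) == 2L && length(unique(y2)) == 2L) return(idx1)
  }
  stop("could not draw a split with both response classes in both halves")
}

#' One-time estimator from a single random split
#'
#' Draws a random half `D1` of size `n1 = round(q * n)`, runs the selector on
#' the complementary half `D2` to get a selected set `S`, then for the
#' intercept and every predictor `j = 1..p` fits the partial GLM of `y` on
#' the `D1` columns of `{j} union S`, keeping the coefficient of predictor
#' `j`.  For `j` in `S` (and the intercept) the convention
#' `S_{+j} = S` means a single fit on `S` supplies all those entries; the
#' fit for `j` outside `S` is warm-started from it and converges to the same
#' optimum as a cold separate fit.
#'
#' @param X `n x p` design matrix (no intercept column).
#' @param y response vector.
#' @param family family name or [ssglm_family()] object.
#' @param q split proportion in (0, 1); `n1 = round(q * n)` samples go to the
#'   estimation half.
#' @param selector selector name (`"sis"`, `"lasso"`, `"elasticnet"`,
#'   `"scad"`, `"mcp"`) or a function `(X, y, family, max_size)`.
#' @param selector_args list of extra arguments for the selector.
#' @param seed integer seed for this split (membership draw and any selector
#'   randomness).
#' @param max_iter,tol Newton control for the partial fits.
#' @return a `SplitRecord` list: `J` (0/1 membership vector of length `n`,
#'   1 = estimation half), `selected` (the `ssglm_selection`), `beta_tilde`
#'   (length `p + 1`, intercept first, `NA` where a partial fit failed), and
#'   `converged` (per-coefficient flags).
#' @export
one_split_estimate <- function(X, y, family, q = 0.5, selector = "sis",
                               selector_args = list(), seed = NULL,
                               max_iter = 100L, tol = 1e-8) {
  d <- check_xy(X, y, family)
  X <- d$X; y <- d$y; family <- d$family
  n <- nrow(X); p <- ncol(X)
  n1 <- round(q * n)
  if (n1 < 3 || n1 > n - 3) stop("split proportion q = ", q,
                                 " leaves a degenerate half-sample")
  if (!is.null(seed)) set.seed(seed)
  idx1 <- draw_split(n, n1, y, family)
  J <- integer(n); J[idx1] <- 1L
  max_size <- max(1L, min(floor(n1 / 3), floor((n - n1) / 3)))
  sel_fn <- make_selector(selector, selector_args)
  sel <- sel_fn(X[-idx1, , drop = FALSE], y[-idx1], family, max_size)
  if (!inherits(sel, "ssglm_selection"))
    sel <- new_selection_result(sel, "custom")
  S <- sel$selected
  if (n1 < length(S) + 2L)
    stop("estimation half (n1 = ", n1, ") too small for |S| = ", length(S))
  sweep <- cpp_partial_sweep(X[idx1, , drop = FALSE], y[idx1],
                             as.integer(S), family$code,
                             as.integer(max_iter), tol)
  beta_tilde <- drop(sweep$beta_tilde)
  beta_tilde[!sweep$converged] <- NA_real_
  list(J = J, selected = sel, beta_tilde = beta_tilde,
       converged = as.logical(sweep$converged), n1 = n1)
}

#' Smoothed estimator over B random splits
#'
#' Runs [one_split_estimate()] on `B` independent random splits (each with
#' its own seed derived from `seed` and the split counter, so any execution
#' order gives bit-identical results) and averages the one-time estimates per
#' coordinate.  A coordinate whose partial fit failed in some split (rank
#' deficiency, separation) is averaged over its own successful splits; a
#' coordinate missing in more than 20% of splits is flagged.
#'
#' @inheritParams one_split_estimate
#' @param B number of random splits.
#' @param seed master seed; split `b` uses a stream derived from
#'   `(seed, b)`.
#' @return an object of class `ssglm`: `beta_hat` (length `p + 1`, intercept
#'   first), `beta_tilde` (`B x (p+1)` matrix of one-time estimates),
#'   `J` (`B x n` 0/1 membership matrix), `sel_freq` (per-predictor selection
#'   frequency across splits), `selected` (list of index vectors),
#'   `flagged` (coordinates missing in > 20% of splits), dimensions and the
#'   configuration.
#' @examples
#' sim <- simulate_dataset(simulation_design(n = 120, p = 30, s0 = 2,
#'                                           family = "gaussian"), seed = 1)
#' fit <- ssglm_fit(sim$X, sim$y, "gaussian", B = 5, seed = 1)
#' head(fit$beta_hat)
#' @export
ssglm_fit <- function(X, y, family, B = 500L, q = 0.5, selector = "sis",
                      selector_args = list(), seed = 1L,
                      max_iter = 100L, tol = 1e-8) {
  d <- check_xy(X, y, family)
  X <- d$X; y <- d$y; family <- d$family
  n <- nrow(X); p <- ncol(X)
  if (B < 1) stop("B must be >= 1")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  beta_tilde <- matrix(NA_real_, B, p + 1L)
  J <- matrix(0L, B, n)
  selected <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    rec <- tryCatch(
      one_split_estimate(X, y, family, q = q, selector = selector,
                         selector_args = selector_args,
                         seed = derive_seed(seed, b),
                         max_iter = max_iter, tol = tol),
      error = function(e) e)
    if (inherits(rec, "error")) { failed <- failed + 1L; next }
    beta_tilde[b, ] <- rec$beta_tilde
    J[b, ] <- rec$J
    selected[[b]] <- rec$selected$selected
  }
  if (failed > 0.1 * B)
    stop(failed, " of ", B, " splits failed entirely; ",
         "check the design (class balance, rank) before proceeding")
  okb <- rowSums(J) > 0
  beta_tilde <- beta_tilde[okb, , drop = FALSE]
  J <- J[okb, , drop = FALSE]
  selected <- selected[okb]
  beta_hat <- colMeans(beta_tilde, na.rm = TRUE)
  miss <- colMeans(is.na(beta_tilde))
  sel_freq <- tabulate(unlist(selected), nbins = p) / nrow(J)
  structure(
    list(beta_hat = beta_hat, beta_tilde = beta_tilde, J = J,
         selected = selected, sel_freq = sel_freq, xnames = colnames(X),
         flagged = which(miss > 0.2) - 1L,
         n = n, p = p, n1 = round(q * n), B = nrow(J), failed_splits = failed,
         config = list(B = B, q = q, selector = if (is.function(selector))
           "custom" else selector, selector_args = selector_args,
           family = family$name, seed = seed, max_iter = max_iter, tol = tol)),
    class = "ssglm")
}

#' @export
print.ssglm <- function(x, ...) {
  cat("ssglm fit: n =", x$n, ", p =", x$p, ", B =", x$B, "splits (q =",
      x$config$q, ", selector =", x$config$selector, ")\n")
  cat("intercept + first coefficients:\n")
  print(head(x$beta_hat, 6))
  if (length(x$flagged))
    cat("flagged coordinates (missing in > 20% of splits):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Smoothed subvector estimator for a fixed coefficient set
#'
#' For a fixed small index set `S1`, each split fits a single GLM of the
#' estimation half on the columns `S1 union S` (`S` from the selector on the
#' other half) and keeps the `S1` coordinates; estimates are averaged over
#' splits.  This supports joint covariance estimation and Wald contrast
#' tests via [subvector_covariance()] and [wald_contrast_test()].
#'
#' @inheritParams ssglm_fit
#' @param S1 integer vector of 1-based predictor indices of interest.
#' @return an object of class `ssglm_subvector`: `beta1_hat` (length
#'   `|S1|`, named by index), `beta_tilde1` (`B x |S1|`), `J` (`B x n`),
#'   `S1`, dimensions and configuration.
#' @export
subvector_fit <- function(X, y, S1, family, B = 500L, q = 0.5,
                          selector = "sis", selector_args = list(),
                          seed = 1L, max_iter = 100L, tol = 1e-8) {
  d <- check_xy(X, y, family)
  X <- d$X; y <- d$y; family <- d$family
  n <- nrow(X); p <- ncol(X)
  S1 <- sort(unique(as.integer(S1)))
  if (length(S1) < 1 || any(S1 < 1 | S1 > p))
    stop("S1 must be nonempty with indices in 1..p")
  n1 <- round(q * n)
  p1 <- length(S1)
  beta1 <- matrix(NA_real_, B, p1)
  J <- matrix(0L, B, n)
  failed <- 0L
  sel_fn <- make_selector(selector, selector_args)
  for (b in seq_len(B)) {
    rec <- tryCatch({
      set.seed(derive_seed(seed, b))
      idx1 <- draw_split(n, n1, y, family)
      max_size <- max(1L, min(floor(n1 / 3), floor((n - n1) / 3)))
      sel <- sel_fn(X[-idx1, , drop = FALSE], y[-idx1], family, max_size)
      if (!inherits(sel, "ssglm_selection"))
        sel <- new_selection_result(sel, "custom")
      Su <- sort(union(S1, sel$selected))
      if (n1 < length(Su) + 2L) stop("estimation half too small")
      r <- cpp_fit_glm(cbind(1, X[idx1, Su, drop = FALSE]), y[idx1],
                       family$code, as.integer(max_iter), tol, NULL)
      if (!r$ok || !r$converged) stop("subvector fit did not converge")
      list(idx1 = idx1, est = drop(r$coefficients)[1L + match(S1, Su)])
    }, error = function(e) e)
    if (inherits(rec, "error")) { failed <- failed + 1L; next }
    J[b, rec$idx1] <- 1L
    beta1[b, ] <- rec$est
  }
  if (failed > 0.1 * B)
    stop(failed, " of ", B, " subvector splits failed; check the design")
  okb <- rowSums(J) > 0
  beta1 <- beta1[okb, , drop = FALSE]
  J <- J[okb, , drop = FALSE]
  beta1_hat <- colMeans(beta1)
  names(beta1_hat) <- S1
  structure(
    list(beta1_hat = beta1_hat, beta_tilde1 = beta1, J = J, S1 = S1,
         n = n, p = p, n1 = n1, B = nrow(J), failed_splits = failed,
         config = list(B = B, q = q, selector = if (is.function(selector))
           "custom" else selector, family = family$name, seed = seed)),
    class = "ssglm_subvector")
}

#' @export
print.ssglm_subvector <- function(x, ...) {
  cat("ssglm subvector fit over", x$B, "splits; S1 = {",
      paste(x$S1, collapse = ", "), "}\n")
  print(x$beta1_hat)
  invisible(x)
}
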
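# Replicated simulation studies: estimation metrics, split-proportion and
# variance-convergence explorations, power / type-I and contrast rejection
# studies.  Replicate k draws its seed from the master seed and the replicate
# counter (a stream independent of the per-split derivation), so studies are
# bit-reproducible and order-invariant.

#' Fix the generative truth of a design
#'
#' Draws the active set and the nonzero coefficients once (under `seed`) and
#' returns the design with both fixed, so that replicated studies share one
#' truth while redrawing predictors and outcomes.  Designs that are already
#' fully fixed are returned unchanged.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed for the truth draw.
#' @return a [simulation_design()] with `active_set` and `coef_values` set.
#' @export
realize_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(design$active_set) && !is.null(design$coef_values))
    return(design)
  set.seed(derive_seed(seed, 0L, salt = 11L))
  if (is.null(design$active_set))
    design$active_set <- sort(sample.int(design$p, design$s0))
  if (is.null(design$coef_values)) {
    mag <- runif(design$s0, design$coef_band[1], design$coef_band[2])
    design$coef_values <- if (design$signs == "random")
      mag * sample(c(-1, 1), design$s0, replace = TRUE) else mag
  }
  design
}

#' Replicated estimation and inference study
#'
#' Draws `K` independent datasets from the (realized) design, runs the full
#' smoothed fit plus inference on each, and aggregates per-coefficient bias,
#' mean standard error, empirical standard deviation, coverage of the
#' 100(1-alpha)% intervals, selection frequency (mean over replicates of the
#' per-split rate) and mean squared error, alongside study-level averages.
#' Monte-Carlo standard errors (binomial) accompany every estimated
#' probability.
#'
#' @param design a [simulation_design()]; its truth is fixed once via
#'   [realize_design()] under `seed`.
#' @param K number of replicates.
#' @param B,q,selector,selector_args passed to [ssglm_fit()].
#' @param alpha level for the intervals and rejections.
#' @param seed master seed; replicate k uses a derived stream.
#' @return an object of class `ssglm_metrics`: `per_coef` (data frame over
#'   coefficients 0..p), `summary` (study-level averages), and the raw
#'   `estimates`, `ses`, `pvalues` matrices (`K x (p+1)`) for downstream
#'   studies.  Failed replicates are dropped and counted.
#' @export
run_replicates <- function(design, K = 50L, B = 100L, q = 0.5,
                           selector = "sis", selector_args = list(),
                           alpha = 0.05, seed = 1L) {
  if (K < 2) stop("K must be >= 2")
  design <- realize_design(design, seed)
  p <- design$p
  truth <- c(design$intercept, {
    b <- numeric(p); b[design$active_set] <- design$coef_values; b
  })
  est <- se <- pv <- matrix(NA_real_, K, p + 1L)
  sf <- matrix(NA_real_, K, p)
  msize <- numeric(K)
  failed <- 0L
  for (k in seq_len(K)) {
    res <- tryCatch({
      sim <- simulate_dataset(design, seed = derive_seed(seed, k, salt = 1L))
      fit <- ssglm_fit(sim$X, sim$y, design$family, B = B, q = q,
                       selector = selector, selector_args = selector_args,
                       seed = derive_seed(seed, k, salt = 2L))
      tab <- inference_table(fit, alpha = alpha, adjust = "none")
      list(est = tab$estimate, se = tab$se, pv = tab$pvalue,
           sf = fit$sel_freq,
           msize = mean(lengths(fit$selected)))
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- failed + 1L; next }
    est[k, ] <- res$est; se[k, ] <- res$se; pv[k, ] <- res$pv
    sf[k, ] <- res$sf; msize[k] <- res$msize
  }
  ok <- which(!is.na(est[, 1]))
  Ku <- length(ok)
  if (Ku < 2) stop("fewer than 2 replicates succeeded")
  est <- est[ok, , drop = FALSE]; se <- se[ok, , drop = FALSE]
  pv <- pv[ok, , drop = FALSE]; sf <- sf[ok, , drop = FALSE]
  z <- qnorm(1 - alpha / 2)
  cover <- abs(sweep(est, 2, truth)) <= z * se
  coverage <- colMeans(cover)
  per_coef <- data.frame(
    index = 0:p,
    truth = truth,
    bias = colMeans(est) - truth,
    mean_se = colMeans(se),
    emp_sd = apply(est, 2, sd),
    coverage = coverage,
    coverage_mc_se = sqrt(coverage * (1 - coverage) / Ku),
    sel_freq = c(NA_real_, colMeans(sf)),
    mse = colMeans(sweep(est, 2, truth)^2),
    row.names = NULL)
  noise <- setdiff(seq_len(p), design$active_set) + 1L  # rows of per_coef
  structure(list(
    per_coef = per_coef,
    summary = list(
      K = Ku, failed = failed, alpha = alpha,
      mse_avg = mean(per_coef$mse[-1L]),
      avg_coverage = mean(coverage[-1L]),
      noise_coverage = mean(coverage[noise]),
      avg_model_size = mean(msize[ok]),
      avg_type1 = mean(pv[, noise] < alpha)),
    estimates = est, ses = se, pvalues = pv,
    design = design, truth = truth,
    config = list(K = K, B = B, q = q, selector = if (is.function(selector))
      "custom" else selector, alpha = alpha, seed = seed)),
    class = "ssglm_metrics")
}

#' @export
print.ssglm_metrics <- function(x, ...) {
  s <- x$summary
  cat("replicated study: K =", s$K, "(", s$failed, "failed ), family =",
      x$design$family, "\n")
  cat("  MSE_avg =", format(s$mse_avg, digits = 4),
      "; avg coverage =", format(s$avg_coverage, digits = 4),
      "; noise coverage =", format(s$noise_coverage, digits = 4), "\n")
  cat("  avg model size =", format(s$avg_model_size, digits = 4),
      "; avg type-I at alpha =", s$alpha, ":",
      format(s$avg_type1, digits = 3), "\n")
  act <- x$design$active_set
  print(x$per_coef[c(1L, act + 1L), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Split-proportion study
#'
#' Runs [run_replicates()] at each split proportion in `q_grid` and reports
#' the average mean squared error over all coefficients.
#'
#' @inheritParams run_replicates
#' @param q_grid vector of split proportions in (0, 1).
#' @return data frame with columns `q` and `mse_avg`.
#' @export
split_proportion_study <- function(design, q_grid = seq(0.1, 0.9, by = 0.1),
                                   K = 50L, B = 100L, selector = "sis",
                                   selector_args = list(), seed = 1L) {
  design <- realize_design(design, seed)
  mse <- vapply(q_grid, function(qq) {
    run_replicates(design, K = K, B = B, q = qq, selector = selector,
                   selector_args = selector_args,
                   seed = seed)$summary$mse_avg
  }, numeric(1))
  data.frame(q = q_grid, mse_avg = mse)
}

#' Variance-estimator convergence in the number of splits
#'
#' For each replicate, fits once with `max(B_grid)` splits and evaluates the
#' raw and bias-corrected infinitesimal-jackknife variances using the first
#' `B` splits for every `B` in the grid.  The across-replicate empirical
#' variance of the smoothed estimate (at the same `B`) is the reference.
#' Values are averaged over the signal coefficients.
#'
#' @inheritParams run_replicates
#' @param B_grid increasing vector of split counts.
#' @return data frame with columns `B`, `mean_V`, `mean_VB`, `empirical`.
#' @export
variance_convergence_study <- function(design, B_grid = c(100L, 200L),
                                       K = 50L, q = 0.5, selector = "sis",
                                       selector_args = list(), seed = 1L) {
  design <- realize_design(design, seed)
  Bmax <- max(B_grid)
  act <- design$active_set + 1L  # coefficient columns (intercept first)
  V <- VB <- array(NA_real_, c(K, length(B_grid)))
  bh <- array(NA_real_, c(K, length(B_grid), length(act)))
  for (k in seq_len(K)) {
    sim <- simulate_dataset(design, seed = derive_seed(seed, k, salt = 1L))
    fit <- ssglm_fit(sim$X, sim$y, design$family, B = Bmax, q = q,
                     selector = selector, selector_args = selector_args,
                     seed = derive_seed(seed, k, salt = 2L))
    for (g in seq_along(B_grid)) {
      rows <- seq_len(B_grid[g])
      bt <- fit$beta_tilde[rows, act, drop = FALSE]
      Jg <- fit$J[rows, , drop = FALSE]
      V[k, g] <- mean(ij_variance(Jg, bt))
      VB[k, g] <- mean(suppressMessages(bias_corrected_variance(Jg, bt)))
      bh[k, g, ] <- colMeans(bt, na.rm = TRUE)
    }
  }
  data.frame(
    B = B_grid,
    mean_V = colMeans(V),
    mean_VB = colMeans(VB),
    empirical = vapply(seq_along(B_grid), function(g)
      mean(apply(bh[, g, , drop = FALSE], 3, stats::var)), numeric(1)))
}

#' Power and type-I error study
#'
#' Per-signal power (fraction of replicates whose p-value falls below
#' `alpha`) and average type-I error over all noise coefficients and
#' replicates, from a [run_replicates()] study.
#'
#' @inheritParams run_replicates
#' @param metrics optionally, a precomputed `ssglm_metrics` object (the other
#'   run arguments are then ignored).
#' @return list with `power` (data frame over signals: index, truth, power,
#'   mc_se), `type1_avg`, `type1_mc_se`, and the underlying `metrics`.
#' @export
power_type1_study <- function(design, K = 50L, B = 100L, q = 0.5,
                              selector = "sis", selector_args = list(),
                              alpha = 0.05, seed = 1L, metrics = NULL) {
  if (is.null(metrics))
    metrics <- run_replicates(design, K = K, B = B, q = q,
                              selector = selector,
                              selector_args = selector_args,
                              alpha = alpha, seed = seed)
  design <- metrics$design
  alpha <- metrics$summary$alpha
  Ku <- metrics$summary$K
  act_cols <- design$active_set + 1L
  noise_cols <- setdiff(2:(design$p + 1L), act_cols)
  pw <- colMeans(metrics$pvalues[, act_cols, drop = FALSE] < alpha)
  t1 <- metrics$pvalues[, noise_cols, drop = FALSE] < alpha
  list(power = data.frame(index = design$active_set,
                          truth = design$coef_values,
                          power = pw,
                          mc_se = sqrt(pw * (1 - pw) / Ku)),
       type1_avg = mean(t1),
       type1_mc_se = sd(rowMeans(t1)) / sqrt(Ku),
       type1_per_coef = colMeans(t1),
       metrics = metrics)
}

#' Contrast rejection study
#'
#' Replicated Wald tests of linear contrasts on a fixed subvector: each
#' replicate runs [subvector_fit()] with `S1`, forms the bias-corrected
#' subvector covariance, and tests every contrast; rejection fractions at
#' `alpha` are reported with Monte-Carlo standard errors, together with the
#' across-replicate mean subvector estimate and covariance diagnostics.
#'
#' @inheritParams run_replicates
#' @param S1 predictor indices of the subvector (defaults to the design's
#'   active set).
#' @param contrasts list of contrasts, each a list with elements `Q`
#'   (vector or `r x |S1|` matrix) and `R` (right-hand side, default 0).
#' @return list with `rejection` (data frame: contrast label, rate, mc_se),
#'   `beta1_mean`, `beta1` (`K x |S1|` estimates), `Sigma1_mean`, `K`.
#' @export
contrast_study <- function(design, contrasts, S1 = NULL, K = 50L, B = 100L,
                           q = 0.5, selector = "sis", selector_args = list(),
                           alpha = 0.05, seed = 1L) {
  design <- realize_design(design, seed)
  if (is.null(S1)) S1 <- design$active_set
  S1 <- sort(unique(as.integer(S1)))
  p1 <- length(S1)
  nc <- length(contrasts)
  rej <- matrix(NA_real_, K, nc)
  beta1 <- matrix(NA_real_, K, p1)
  Sig_sum <- matrix(0, p1, p1)
  failed <- 0L
  for (k in seq_len(K)) {
    res <- tryCatch({
      sim <- simulate_dataset(design, seed = derive_seed(seed, k, salt = 1L))
      sv <- subvector_fit(sim$X, sim$y, S1, design$family, B = B, q = q,
                          selector = selector, selector_args = selector_args,
                          seed = derive_seed(seed, k, salt = 2L))
      Sig <- subvector_covariance(sv)
      list(b = sv$beta1_hat, Sig = Sig,
           rej = vapply(contrasts, function(ct) {
             R <- if (is.null(ct$R)) NULL else ct$R
             as.numeric(wald_contrast_test(sv$beta1_hat, Sig, ct$Q,
                                           R)$p_value < alpha)
           }, numeric(1)))
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- failed + 1L; next }
    beta1[k, ] <- res$b
    rej[k, ] <- res$rej
    Sig_sum <- Sig_sum + res$Sig
  }
  ok <- which(!is.na(beta1[, 1]))
  Ku <- length(ok)
  if (Ku < 2) stop("fewer than 2 replicates succeeded")
  rates <- colMeans(rej[ok, , drop = FALSE])
  labels <- vapply(seq_len(nc), function(i) {
    lb <- contrasts[[i]]$label
    if (is.null(lb)) paste0("contrast", i) else lb
  }, character(1))
  list(rejection = data.frame(contrast = labels, rate = rates,
                              mc_se = sqrt(rates * (1 - rates) / Ku)),
       beta1_mean = colMeans(beta1[ok, , drop = FALSE]),
       beta1 = beta1[ok, , drop = FALSE],
       Sigma1_mean = Sig_sum / Ku,
       S1 = S1, K = Ku, failed = failed, alpha = alpha,
       design = design)
}
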
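---
title: "Splitting-and-smoothing inference for high-dimensional GLMs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting-and-smoothing inference for high-dimensional GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and the procedure

We observe $n$ i.i.d. pairs $(Y_i, x_i)$ with $x_i \in \mathbb{R}^p$ and
possibly $p \gg n$.  The response follows a linear exponential family with
density $f(y \mid \theta) = \exp\{y\theta - A(\theta) + c(y)\}$ under the
canonical link, so the natural parameter is the linear predictor
$\theta_i = \beta_0 + x_i^T \beta$.  The package supports the gaussian
($A(\theta) = \theta^2/2$), binomial ($A(\theta) = \log(1 + e^\theta)$) and
poisson ($A(\theta) = e^\theta$) members.  The inferential target is the full
coefficient vector $\beta^* = (\beta_0^*, \beta_1^*, \dots, \beta_p^*)$ under
a sparsity assumption: only $s_0 \ll n$ entries are nonzero.

Classical p-dimensional fitting is impossible when $p > n$, and penalized
point estimates do not come with usable standard errors.  The procedure
implemented here turns the problem into many low-dimensional GLM fits:

1. **Split.** Draw a random half $D_1$ of size $n_1 = qn$ (without
   replacement); the complement $D_2$ has $n_2 = n - n_1$.
2. **Screen.** Run a variable selector on $D_2$ only, producing a small set
   $S \subset \{1, \dots, p\}$.
3. **Partial regressions.** On $D_1$, for every $j = 0, 1, \dots, p$, fit
   the GLM of $Y$ on the columns $S_{+j} = \{j\} \cup S$ (with the
   convention $S_{+0} = S$) and record the $j$-th coordinate
   $\tilde\beta_j$.  Because $S_{+j} = S$ for every $j \in S$, a single fit
   on $S$ supplies the intercept and all selected coordinates; the package
   fits the remaining $p - |S|$ models warm-started from that base fit,
   which converges to the same optimum as cold separate fits (this identity
   is tested).
4. **Smooth.** Repeat steps 1–3 for $b = 1, \dots, B$ independent splits
   and average coordinate-wise:
   $\hat\beta_j = B^{-1} \sum_b \tilde\beta_j^b$.

The one-time estimate $\tilde\beta_j$ is consistent whenever $S \supseteq
S^*$ (the selected set only needs to *contain* the truth — the
sure-screening property — not equal it), but it is highly variable because
it uses half the data and one arbitrary selection.  Averaging over splits
removes most of that variability, in the same way bagging stabilizes a
single tree.

## Variance estimation

Each $\tilde\beta_j^b$ is a function of which samples landed in $D_1^b$,
recorded by indicators $J_{bi} \in \{0, 1\}$.  The infinitesimal-jackknife
variance estimate for the smoothed coefficient is

$$\hat V_j = \frac{n(n-1)}{(n-n_1)^2} \sum_{i=1}^n \widehat{\mathrm{cov}}_{ij}^2,
\qquad
\widehat{\mathrm{cov}}_{ij} = \frac{1}{B} \sum_{b=1}^B
  (J_{bi} - \bar J_{\cdot i})(\tilde\beta_j^b - \hat\beta_j),$$

where the leading factor is the finite-sample correction appropriate for
subsampling without replacement.  With a finite $B$, $\hat V_j$ carries an
upward Monte-Carlo bias of order $n\hat\upsilon_j/B$, where $\hat\upsilon_j$
is the across-split variance of $\tilde\beta_j^b$; the bias-corrected form

$$\hat V_j^B = \hat V_j - \frac{n}{B^2}\,\frac{n_1}{n-n_1}
  \sum_{b=1}^B (\tilde\beta_j^b - \hat\beta_j)^2$$

removes it and is the default for all confidence intervals
($\hat\beta_j \pm \Phi^{-1}(1-\alpha/2)\sqrt{\smash[b]{\hat V_j^B}}$) and
p-values ($2\{1 - \Phi(|\hat\beta_j|/\sqrt{\smash[b]{\hat V_j^B}})\}$).
Both formulas are verified against brute-force nested summation in the test
suite.

**Negative corrected values.** At moderate $B$ the correction is itself a
noisy estimate, and $\hat V_j - \text{correction}$ can fall below zero.  A
hard floor near zero would make the standard error vanish and manufacture a
false rejection at exactly the coordinates where the correction is least
reliable, so the package falls back to the (upward-biased, hence
conservative) uncorrected $\hat V_j$ for those coordinates and reports how
many were affected.  With the package defaults the fallback touches a
handful of coordinates per fit at $B = 100$ and none at $B \gtrsim 500$.

## Subvectors and contrasts

For a fixed small set $S^{(1)}$, each split fits a single GLM on
$S^{(1)} \cup S$ and keeps the $S^{(1)}$ coordinates; averaging gives
$\hat\beta^{(1)}$.  The joint covariance applies the same per-sample
covariance construction,
$\hat\Sigma^{(1)} = \frac{n(n-1)}{(n-n_1)^2}\,\widehat{\mathrm{COV}}^T
\widehat{\mathrm{COV}}$ with $\widehat{\mathrm{COV}}$ the $n \times p_1$
matrix of rows $\widehat{\mathrm{cov}}_{i\cdot}$, so its diagonal coincides
with the scalar $\hat V_j$.  Two numerical choices were genuinely open:

* the scalar formula's subsampling correction factor is applied to the
  matrix as well (internal consistency between the scalar and matrix paths
  demands it, and the diagonal identity is tested);
* the matrix analogue of the finite-$B$ bias correction,
  $\frac{n}{B^2}\frac{n_1}{n-n_1}\sum_b (\tilde\beta^b - \hat\beta)
  (\tilde\beta^b - \hat\beta)^T$, is subtracted by default
  (`bias_correct = TRUE`), because at $B \sim 100$ the uncorrected matrix is
  inflated by the same order-$n\hat\upsilon/B$ term as the scalar case and
  Wald tests built on it lose most of their power.  The corrected matrix is
  projected back onto the PSD cone by flooring its eigenvalues.

Linear hypotheses $H_0: Q\beta^{(1)} = R$ ($Q$ of full row rank $r$) use the
Wald statistic
$T = (Q\hat\beta^{(1)} - R)^T [Q\hat\Sigma^{(1)}Q^T]^{-1}
(Q\hat\beta^{(1)} - R)$, referred to $\chi^2_r$.

## Tunable parameters

* **Split proportion `q` (default 0.5).**  Larger $n_1$ sharpens the partial
  fits, but $n_2$ must stay large enough for reliable screening.  Across the
  bundled gaussian design the coordinate-averaged MSE is minimized at or
  near $q = 0.5$ (see `split_proportion_study()`), so equal splitting is the
  default.
* **Number of splits `B` (default 500; the bundled studies use 100).**
  Estimation stabilizes quickly in $B$; variance estimation is the binding
  constraint, and the bias-corrected $\hat V_j^B$ is reliable from roughly
  $B \sim 100$ while the raw $\hat V_j$ needs an order of magnitude more
  (see `variance_convergence_study()`).
* **Selector (default SIS).**  Any procedure with the sure-screening
  property works; cross-validated lasso, elastic net, and one-step-LLA SCAD
  and MCP are provided via glmnet.  Estimates and coverage are empirically
  insensitive to this choice; model sizes differ (concave penalties select
  fewer variables than the lasso).
* **Screening size `d`.**  `floor(n2/log n2)` for gaussian and poisson —
  the conventional screening size — and `floor(n2/(4 log n2))` for
  binomial, matching standard screening software.  A binary response
  carries at most $1/4$ unit of Fisher information per observation, and
  partial logistic fits whose dimension approaches $n_1/5$ become unstable
  (inflated coefficients, separation); the reduced binomial default keeps
  them well-posed.  All selectors are additionally capped at
  $|S| \le \min(\lfloor n_1/3 \rfloor, \lfloor n_2/3 \rfloor)$.
* **Screening utility.**  Gaussian: standardized marginal score (identical
  ranking to per-predictor least-squares slopes).  Binomial: absolute
  marginal logistic slope.  Poisson: absolute correlation with
  $\log(1+y)$ — the log transform linearizes the exponential mean, whereas
  both the raw-scale correlation and the marginal poisson MLE are dominated
  by the largest counts under the heavy marginal overdispersion that a
  multi-signal log-linear model induces, and can rank true signals
  arbitrarily low.

## Numerical choices

Partial GLMs are fitted by Newton–Raphson on the average negative
log-likelihood with the observed information, initialized at zero apart
from the intercept (started at the link of the response mean), with up to
ten step-halvings per iteration when the objective fails to decrease, and
convergence declared when the maximum absolute coefficient change drops
below `1e-8`.  Linear predictors are clamped to $[-30, 30]$ inside the
binomial and poisson cumulant evaluations to prevent overflow.  Separation
and rank deficiency are flagged per coefficient, never silently: a
coefficient whose fit fails in a split is averaged over its own successful
splits (with its own split count in the variance formulas), and flagged in
the output when missing from more than 20% of splits.  For binomial
responses a split is redrawn (up to 100 times) if either half lacks a
response class.  Screening ties break by ascending predictor index.

Every split derives its own RNG stream from the master seed and the split
counter, so the $B$ splits can be computed in any order — or in parallel —
with bit-identical results; replicate-level streams in the study drivers
are derived independently of the split streams.

## The synthetic designs

`simulate_dataset()` draws predictor rows from a zero-mean multivariate
normal with identity, AR(1) ($\Sigma_{ij} = \rho^{|i-j|}$) or
compound-symmetry ($\Sigma_{ij} = \rho,\ i \ne j$) covariance; sparse
coefficient vectors use either fixed values or magnitudes uniform on a band
with random (or all-positive) signs; outcomes follow the canonical-link
model of the chosen family.  For the poisson family predictor entries are
truncated at $\pm 3$ standard deviations (on by default) so that
$e^{x^T\beta}$ stays finite at realistic signal strengths.  The five
bundled presets (`example_design()`) cover a gaussian AR(1) design
($n = 500$, $p = 1000$, $s_0 = 10$), two poisson designs ($n = 300$,
$p = 400$ with coefficients $0.4$–$1.2$; $n = 400$, $p = 500$, $s_0 = 6$
with coefficients in $[0.5, 1]$ and intercept 1), and two logistic designs
($n = 400$, $p = 500$ with active set $\{218, 242, 269, 417\}$ and
coefficients $(-2, -1, 1, 2)$; $n = 200$, $p = 300$ with active set
$\{10, 20, 30\}$, coefficients $(2, -2, 2)$ and AR(1) correlation).

What the generator does **not** emulate: bounded or discrete predictors
(SNP dosages, standardized clinical covariates), linkage-type block
correlation, model misspecification, and overdispersion beyond the family
variance.  Passing tests on these designs therefore demonstrate the
correctness and calibration of the machinery under clean multivariate
normal designs, not robustness on real genomic data.  One consequence worth
stating explicitly: with standard normal predictors a logistic design with
coefficients $\pm 2$ is highly informative (the oracle GLM at $n = 400$ has
coefficient variances near $0.03$–$0.06$), so Wald tests of moderate
contrasts are close to saturation and their rejection rates exceed what the
same design would show under a lower-information predictor law, and
reported standard errors under the poisson designs scale inversely with
the (large) realized counts.

## Problem sizes used by the bundled studies

The replicated studies in `scripts/acceptance.R` and the test suite run at
$K = 10$–$40$ replicates with $B = 100$ splits, sizes chosen so the full
set completes on a single CPU in tens of minutes while keeping binomial
Monte-Carlo standard errors of estimated probabilities near $0.05$ or
below.  Every estimated probability is reported with its Monte-Carlo
standard error, and each study fixes one generative truth (active set and
coefficients) per master seed via `realize_design()`, then redraws
predictors and outcomes per replicate.

## Known limitations

* Sure screening is an assumption, not a guarantee: with the weakest
  admissible signals (e.g. poisson coefficients right at $0.5$) the default
  screening misses the full active set in a few percent of half-samples.
  The smoothing step absorbs occasional misses gracefully, but coverage at
  the weakest signals can dip a point or two below nominal.
* Partial logistic fits inherit the finite-sample inflation of the MLE at
  moderate dimension-to-sample ratios, so smoothed logistic estimates of
  large coefficients are a few percent larger in magnitude than the truth
  at $n_1 = 200$; the effect shrinks with $n$ and with smaller screening
  sizes.
* The bias-corrected variance needs $B$ of order $n$; at much smaller $B$
  the conservative fallback engages more often and intervals widen.
* Families are restricted to the three canonical-link members above;
  dispersion parameters and non-canonical links are out of scope.
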
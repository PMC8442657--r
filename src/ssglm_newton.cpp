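// Newton-Raphson fitting of low-dimensional canonical-link GLMs and the
// per-split partial-regression sweep (one fit per predictor, warm-started
// from the selected-set fit). Family codes: 0 gaussian, 1 binomial, 2 poisson.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double THETA_CLAMP = 30.0;

// cumulant A(theta), elementwise, with clamping for binomial/poisson
static inline double cumulant(double th, int fam) {
  if (fam == 0) return 0.5 * th * th;
  if (th > THETA_CLAMP) th = THETA_CLAMP; else if (th < -THETA_CLAMP) th = -THETA_CLAMP;
  if (fam == 1) return (th > 0.0) ? th + std::log1p(std::exp(-th)) : std::log1p(std::exp(th));
  return std::exp(th); // poisson
}

static inline double meanfun(double th, int fam) {
  if (fam == 0) return th;
  if (th > THETA_CLAMP) th = THETA_CLAMP; else if (th < -THETA_CLAMP) th = -THETA_CLAMP;
  if (fam == 1) return 1.0 / (1.0 + std::exp(-th));
  return std::exp(th);
}

static inline double varfun(double mu, int fam) {
  if (fam == 0) return 1.0;
  if (fam == 1) { double v = mu * (1.0 - mu); return (v < 1e-10) ? 1e-10 : v; }
  return (mu < 1e-10) ? 1e-10 : mu;
}

static double neg_loglik_eta(const vec& eta, const vec& y, int fam) {
  double s = 0.0;
  const int n = eta.n_elem;
  for (int i = 0; i < n; ++i) s += cumulant(eta[i], fam) - y[i] * eta[i];
  return s / n;
}

struct NewtonResult {
  vec beta;
  bool converged;
  int iterations;
  double nll;
  bool ok;          // false on rank deficiency / numerical failure
};

// Newton-Raphson with step-halving; X includes the intercept column.
static NewtonResult newton_glm(const mat& X, const vec& y, int fam,
                               vec beta, int max_iter, double tol) {
  NewtonResult res;
  const int n = X.n_rows, k = X.n_cols;
  vec eta = X * beta;
  double nll = neg_loglik_eta(eta, y, fam);
  bool converged = false, ok = true;
  int it = 0;
  vec mu(n), w(n);
  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      mu[i] = meanfun(eta[i], fam);
      w[i] = varfun(mu[i], fam);
    }
    vec g = X.t() * (mu - y) / n;
    mat Xw = X.each_col() % sqrt(w);
    mat H = (Xw.t() * Xw) / n;
    vec step;
    bool solved = solve(step, H, g, solve_opts::no_approx + solve_opts::likely_sympd);
    if (!solved || !step.is_finite()) { ok = false; break; }
    // step-halving if the objective does not decrease
    double lambda = 1.0;
    vec beta_new, eta_new;
    double nll_new = datum::inf;
    int h;
    for (h = 0; h <= 10; ++h) {
      beta_new = beta - lambda * step;
      eta_new = X * beta_new;
      nll_new = neg_loglik_eta(eta_new, y, fam);
      if (std::isfinite(nll_new) && nll_new <= nll + 1e-12) break;
      lambda *= 0.5;
    }
    if (h > 10) { // no decrease found: treat current point as final
      converged = false; break;
    }
    double delta = max(abs(beta_new - beta));
    beta = beta_new; eta = eta_new; nll = nll_new;
    if (delta < tol) { converged = true; break; }
  }
  res.beta = beta; res.converged = converged && ok;
  res.iterations = it; res.nll = nll; res.ok = ok;
  return res;
}

static vec init_beta(const vec& y, int fam, int k) {
  vec b(k, fill::zeros);
  double ybar = mean(y);
  if (fam == 0) b[0] = ybar;
  else if (fam == 1) {
    double p = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    b[0] = std::log(p / (1.0 - p));
  } else b[0] = std::log(std::max(ybar, 1e-6));
  return b;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_glm(const arma::mat& X, const arma::vec& y, int fam,
                       int max_iter, double tol,
                       Rcpp::Nullable<Rcpp::NumericVector> start = R_NilValue) {
  vec b0;
  if (start.isNotNull()) b0 = Rcpp::as<vec>(start.get());
  else b0 = init_beta(y, fam, X.n_cols);
  NewtonResult r = newton_glm(X, y, fam, b0, max_iter, tol);
  // observed information (1/n) X^T W X at the solution
  const int n = X.n_rows;
  vec eta = X * r.beta, w(n);
  for (int i = 0; i < n; ++i) w[i] = varfun(meanfun(eta[i], fam), fam);
  mat Xw = X.each_col() % sqrt(w);
  mat info = (Xw.t() * Xw) / n;
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = r.beta,
    Rcpp::Named("converged") = r.converged,
    Rcpp::Named("iterations") = r.iterations,
    Rcpp::Named("neg_loglik") = r.nll,
    Rcpp::Named("observed_information") = info,
    Rcpp::Named("ok") = r.ok);
}

// Marginal screening utilities: absolute slope of the single-covariate GLM
// of y on each (already standardized) column of X.  Columns whose marginal
// fit fails get utility 0.
// [[Rcpp::export]]
arma::vec cpp_marginal_coefs(const arma::mat& X, const arma::vec& y, int fam,
                             int max_iter, double tol) {
  const int n = X.n_rows, p = X.n_cols;
  vec out(p, fill::zeros);
  mat Xj(n, 2);
  Xj.col(0).ones();
  vec b0 = init_beta(y, fam, 2);
  for (int j = 0; j < p; ++j) {
    Xj.col(1) = X.col(j);
    NewtonResult r = newton_glm(Xj, y, fam, b0, max_iter, tol);
    if (r.ok && r.converged) out[j] = std::abs(r.beta[1]);
  }
  return out;
}

// One split's sweep: fit the selected-set model once (supplying the intercept
// and all j in S), then one warm-started fit per j not in S. S is 1-based.
// Returns beta_tilde of length p+1 (index 1 = intercept) with NA where a fit
// failed, plus per-entry convergence flags.
// [[Rcpp::export]]
Rcpp::List cpp_partial_sweep(const arma::mat& X1, const arma::vec& y1,
                             const arma::uvec& S, int fam,
                             int max_iter, double tol) {
  const int n1 = X1.n_rows, p = X1.n_cols, k = S.n_elem;
  vec beta_tilde(p + 1); beta_tilde.fill(datum::nan);
  Rcpp::LogicalVector conv(p + 1, false);

  mat Xs(n1, k + 1);
  Xs.col(0).ones();
  for (int a = 0; a < k; ++a) Xs.col(a + 1) = X1.col(S[a] - 1);

  NewtonResult base = newton_glm(Xs, y1, fam, init_beta(y1, fam, k + 1),
                                 max_iter, tol);
  if (base.ok) {
    beta_tilde[0] = base.beta[0];
    conv[0] = base.converged;
    for (int a = 0; a < k; ++a) {
      beta_tilde[S[a]] = base.beta[a + 1];
      conv[S[a]] = base.converged;
    }
  }

  std::vector<bool> inS(p + 1, false);
  for (int a = 0; a < k; ++a) inS[S[a]] = true;

  mat Xa(n1, k + 2);
  Xa.cols(0, k) = Xs;
  vec warm(k + 2, fill::zeros);
  if (base.ok) warm.subvec(0, k) = base.beta;
  else warm = init_beta(y1, fam, k + 2);

  for (int j = 1; j <= p; ++j) {
    if (inS[j]) continue;
    Xa.col(k + 1) = X1.col(j - 1);
    vec b0 = warm;
    NewtonResult r = newton_glm(Xa, y1, fam, b0, max_iter, tol);
    if (r.ok) {
      beta_tilde[j] = r.beta[k + 1];
      conv[j] = r.converged;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta_tilde") = beta_tilde,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("base_converged") = base.ok && base.converged);
}
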
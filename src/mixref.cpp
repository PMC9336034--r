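// Numerical core: mixture-density-network loss/gradient and the weighted
// Gaussian location-scale fit used inside the EM M-step. Kept in compiled
// code because the simulation harness evaluates these objectives many
// thousands of times at n = 5000..10000.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Softplus with a numerically safe large-argument branch.
static inline double softplus(double a) {
  if (a > 30.0) return a;
  return std::log1p(std::exp(a));
}
static inline double sigmoid(double a) {
  if (a >= 0.0) return 1.0 / (1.0 + std::exp(-a));
  double e = std::exp(a);
  return e / (1.0 + e);
}

// Unpack the flat parameter vector. Layout (column-major matrices):
//   W1 (1 x H), b1 (H), [Wa (H x M) if alpha_connected], ba (M),
//   Wm (H x M), bm (M), Ws (H x M), bs (M)
struct MdnPars {
  rowvec W1; rowvec b1; mat Wa; rowvec ba; mat Wm; rowvec bm; mat Ws; rowvec bs;
};

static MdnPars unpack(const vec& par, int H, int M, bool alpha_connected) {
  MdnPars p;
  int k = 0;
  p.W1 = par.subvec(k, k + H - 1).t(); k += H;
  p.b1 = par.subvec(k, k + H - 1).t(); k += H;
  if (alpha_connected) {
    p.Wa = reshape(par.subvec(k, k + H * M - 1), H, M); k += H * M;
  } else {
    p.Wa = zeros<mat>(H, M);
  }
  p.ba = par.subvec(k, k + M - 1).t(); k += M;
  p.Wm = reshape(par.subvec(k, k + H * M - 1), H, M); k += H * M;
  p.bm = par.subvec(k, k + M - 1).t(); k += M;
  p.Ws = reshape(par.subvec(k, k + H * M - 1), H, M); k += H * M;
  p.bs = par.subvec(k, k + M - 1).t(); k += M;
  return p;
}

// Shared forward pass. Produces the mixture parameters together with the
// log-scale quantities the likelihood needs, avoiding redundant log/exp.
struct Forward {
  mat Z;        // n x H hidden activations
  mat alpha;    // n x M mixture weights
  mat logalpha; // log mixture weights
  mat mu;       // n x M means
  mat sigma;    // n x M scales (floored)
  mat logsigma; // log of the floored scales
  mat As;       // scale pre-activations
};

static void mdn_forward_core(const MdnPars& p, const vec& x, bool softplus_scale,
                             double sigma_floor, Forward& f) {
  f.Z = x * p.W1;
  f.Z.each_row() += p.b1;
  f.Z = tanh(f.Z);

  mat Aa = f.Z * p.Wa;
  Aa.each_row() += p.ba;
  vec amax = max(Aa, 1);
  Aa.each_col() -= amax;
  mat ea = exp(Aa);
  vec rs = sum(ea, 1);
  f.alpha = ea.each_col() / rs;
  f.logalpha = Aa.each_col() - log(rs);

  f.mu = f.Z * p.Wm;
  f.mu.each_row() += p.bm;

  f.As = f.Z * p.Ws;
  f.As.each_row() += p.bs;
  f.sigma.set_size(size(f.As));
  f.logsigma.set_size(size(f.As));
  const double log_floor = std::log(sigma_floor);
  if (softplus_scale) {
    for (uword j = 0; j < f.As.n_elem; ++j) {
      double s = softplus(f.As(j));
      if (s < sigma_floor) s = sigma_floor;
      f.sigma(j) = s;
      f.logsigma(j) = std::log(s);
    }
  } else {
    for (uword j = 0; j < f.As.n_elem; ++j) {
      double a = f.As(j);
      if (a < log_floor) {
        f.sigma(j) = sigma_floor;
        f.logsigma(j) = log_floor;
      } else {
        f.sigma(j) = std::exp(a);
        f.logsigma(j) = a;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mdn_forward(const arma::vec& par, const arma::vec& x, int H, int M,
                           bool alpha_connected, bool softplus_scale,
                           double sigma_floor) {
  MdnPars p = unpack(par, H, M, alpha_connected);
  Forward f;
  mdn_forward_core(p, x, softplus_scale, sigma_floor, f);
  return Rcpp::List::create(Rcpp::Named("weights") = f.alpha,
                            Rcpp::Named("means") = f.mu,
                            Rcpp::Named("scales") = f.sigma);
}

// [[Rcpp::export]]
Rcpp::List cpp_mdn_nll_grad(const arma::vec& par, const arma::vec& x,
                            const arma::vec& y, int H, int M,
                            bool alpha_connected, bool softplus_scale,
                            double sigma_floor, bool want_grad) {
  MdnPars p = unpack(par, H, M, alpha_connected);
  Forward f;
  mdn_forward_core(p, x, softplus_scale, sigma_floor, f);

  // log alpha_m + log N(y; mu_m, sigma_m), then a row-wise log-sum-exp
  mat resid = f.mu;
  resid.each_col() -= y;           // mu - y
  mat zs = resid / f.sigma;        // (mu - y) / sigma
  mat logcomp = f.logalpha - f.logsigma - 0.5 * LOG2PI - 0.5 * square(zs);
  vec rowmax = max(logcomp, 1);
  mat eshift = exp(logcomp.each_col() - rowmax);
  vec rs = sum(eshift, 1);
  double nll = -accu(rowmax + log(rs));

  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("nll") = nll);
  }

  // posterior responsibilities pi_im (reuses the shifted exponentials)
  mat pi = eshift.each_col() / rs;

  // pre-activation gradients of the summed NLL
  mat d_alpha = f.alpha - pi;
  mat d_mu = pi % zs / f.sigma;
  mat d_s = pi % (1.0 - square(zs));  // exponential parameterization
  if (softplus_scale) {
    // dE/da = dE/dsigma * sigmoid(a); dE/dsigma = (pi/sigma)(1 - z^2)
    for (uword j = 0; j < d_s.n_elem; ++j)
      d_s(j) = d_s(j) / f.sigma(j) * sigmoid(f.As(j));
  }

  mat gWm = f.Z.t() * d_mu;
  rowvec gbm = sum(d_mu, 0);
  mat gWs = f.Z.t() * d_s;
  rowvec gbs = sum(d_s, 0);
  rowvec gba = sum(d_alpha, 0);

  mat D = d_mu * p.Wm.t() + d_s * p.Ws.t();
  mat gWa;
  if (alpha_connected) {
    gWa = f.Z.t() * d_alpha;
    D += d_alpha * p.Wa.t();
  }
  D %= (1.0 - square(f.Z));
  rowvec gW1 = x.t() * D;
  rowvec gb1 = sum(D, 0);

  int npar = 2 * H + 3 * M + (alpha_connected ? 3 : 2) * H * M;
  vec g(npar);
  int k = 0;
  g.subvec(k, k + H - 1) = gW1.t(); k += H;
  g.subvec(k, k + H - 1) = gb1.t(); k += H;
  if (alpha_connected) { g.subvec(k, k + H * M - 1) = vectorise(gWa); k += H * M; }
  g.subvec(k, k + M - 1) = gba.t(); k += M;
  g.subvec(k, k + H * M - 1) = vectorise(gWm); k += H * M;
  g.subvec(k, k + M - 1) = gbm.t(); k += M;
  g.subvec(k, k + H * M - 1) = vectorise(gWs); k += H * M;
  g.subvec(k, k + M - 1) = gbs.t(); k += M;

  return Rcpp::List::create(Rcpp::Named("nll") = nll, Rcpp::Named("grad") = g);
}

// Weighted Gaussian location-scale objective for one mixture component:
// par = c(beta, gamma), mu = Z beta, sigma = exp(Z gamma).
// Returns sum_i w_i * (-log N(y_i; mu_i, sigma_i)) and its gradient.
// [[Rcpp::export]]
Rcpp::List cpp_wls_nll_grad(const arma::vec& par, const arma::mat& Z,
                            const arma::vec& y, const arma::vec& w,
                            double sigma_floor, bool want_grad) {
  int pdim = Z.n_cols;
  vec beta = par.subvec(0, pdim - 1);
  vec gamma = par.subvec(pdim, 2 * pdim - 1);
  vec mu = Z * beta;
  vec lsig = Z * gamma;
  vec sigma = exp(lsig);
  sigma.transform([sigma_floor](double s) { return s < sigma_floor ? sigma_floor : s; });
  vec r = y - mu;
  vec z2 = square(r / sigma);
  double nll = accu(w % (0.5 * LOG2PI + log(sigma) + 0.5 * z2));
  if (!want_grad) return Rcpp::List::create(Rcpp::Named("nll") = nll);
  vec dbeta_vec = w % (-r) / square(sigma);
  vec dgamma_vec = w % (1.0 - z2);
  vec g(2 * pdim);
  g.subvec(0, pdim - 1) = Z.t() * dbeta_vec;
  g.subvec(pdim, 2 * pdim - 1) = Z.t() * dgamma_vec;
  return Rcpp::List::create(Rcpp::Named("nll") = nll, Rcpp::Named("grad") = g);
}

static double wls_nll(const mat& Z, const vec& y, const vec& w,
                      const vec& beta, const vec& gamma, double sigma_floor) {
  vec mu = Z * beta;
  vec lsig = Z * gamma;
  lsig.transform([sigma_floor](double a) {
    double lf = std::log(sigma_floor);
    return a < lf ? lf : a;
  });
  vec sigma = exp(lsig);
  return accu(w % (0.5 * LOG2PI + lsig + 0.5 * square((y - mu) / sigma)));
}

// Weighted maximum-likelihood fit of one Gaussian location-scale component,
// mu = Z beta, log sigma = Z gamma, by alternating exact weighted least
// squares for beta (the global optimum given sigma) and Fisher-scoring
// steps with step-halving for gamma. Each sub-step never increases the
// weighted NLL, so using it inside EM keeps the observed-data likelihood
// monotone (a generalized EM update).
// [[Rcpp::export]]
Rcpp::List cpp_fit_component(const arma::mat& Z, const arma::vec& y,
                             const arma::vec& w, const arma::vec& beta0,
                             const arma::vec& gamma0, int max_sweeps,
                             double tol, double sigma_floor) {
  vec beta = beta0, gamma = gamma0;
  double f = wls_nll(Z, y, w, beta, gamma, sigma_floor);
  bool ok = true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // beta: weighted least squares with weights w / sigma^2
    vec sigma = exp(Z * gamma);
    sigma.transform([sigma_floor](double s) { return s < sigma_floor ? sigma_floor : s; });
    vec wls_w = w / square(sigma);
    mat Zw = Z.each_col() % wls_w;
    vec beta_new;
    bool solved = solve(beta_new, Z.t() * Zw, Zw.t() * y, solve_opts::no_approx);
    if (solved) {
      double f_try = wls_nll(Z, y, w, beta_new, gamma, sigma_floor);
      if (f_try <= f) { beta = beta_new; f = f_try; }
    } else {
      ok = false;
    }

    // gamma: Fisher scoring (information 2 Z' W Z) with step-halving
    vec mu = Z * beta;
    sigma = exp(Z * gamma);
    sigma.transform([sigma_floor](double s) { return s < sigma_floor ? sigma_floor : s; });
    vec z2 = square((y - mu) / sigma);
    vec grad = Z.t() * (w % (1.0 - z2));
    mat info = 2.0 * (Z.t() * (Z.each_col() % w));
    vec step;
    if (solve(step, info, grad, solve_opts::no_approx)) {
      double scale = 1.0;
      for (int h = 0; h < 30; ++h) {
        vec gamma_try = gamma - scale * step;
        double f_try = wls_nll(Z, y, w, beta, gamma_try, sigma_floor);
        if (f_try <= f) { gamma = gamma_try; f = f_try; break; }
        scale *= 0.5;
      }
    } else {
      ok = false;
    }

    double f_new = wls_nll(Z, y, w, beta, gamma, sigma_floor);
    if (sweep > 0 && std::abs(f_new - f) < tol) { f = f_new; break; }
    f = f_new;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("nll") = f,
                            Rcpp::Named("ok") = ok);
}
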
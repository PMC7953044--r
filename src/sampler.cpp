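// Marginal-likelihood CFA: log posterior evaluation and adaptive
// Metropolis-within-Gibbs sampling on the unconstrained parameter scale.
//
// Unconstrained layout (length d):
//   [0, p)                     nu (item intercepts)
//   [p, p + nfree)             free loadings (items that are not reference
//                              items, in item order; reference loadings == 1)
//   [.., + p)                  log residual SDs      (theta_j = exp(2 t_j))
//   [.., + m)                  log factor SDs
//   [.., + m(m-1)/2)           atanh factor correlations, lower triangle
//                              column-major: (2,1),(3,1),(3,2)
// m == 0 encodes the independence model (nu and residual SDs only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Spec {
  int p, m, nfree, ncorr, d;
  arma::ivec factor_of;  // 1-based factor index per item (unused when m == 0)
  arma::uvec is_ref;     // 1 if loading fixed to 1
};

struct Priors {
  double loading_sd, nu_sd;
  double resid_shape, resid_rate;
  double fsd_shape, fsd_rate;
};

struct Pars {
  arma::vec nu, lambda, theta, fsd;
  arma::mat corr;
};

Spec make_spec(int p, int m, const IntegerVector& factor_of,
               const LogicalVector& is_ref) {
  Spec sp;
  sp.p = p;
  sp.m = m;
  sp.factor_of.set_size(p);
  sp.is_ref.set_size(p);
  int nref = 0;
  for (int j = 0; j < p; ++j) {
    sp.factor_of[j] = (m > 0) ? factor_of[j] : 0;
    sp.is_ref[j] = (m > 0 && is_ref[j]) ? 1u : 0u;
    if (sp.is_ref[j]) ++nref;
  }
  sp.nfree = (m > 0) ? (p - nref) : 0;
  sp.ncorr = (m > 1) ? m * (m - 1) / 2 : 0;
  sp.d = p + sp.nfree + p + m + sp.ncorr;
  return sp;
}

Priors make_priors(const List& prior) {
  Priors pr;
  pr.loading_sd = as<double>(prior["loading_sd"]);
  pr.nu_sd = as<double>(prior["nu_sd"]);
  pr.resid_shape = as<double>(prior["resid_shape"]);
  pr.resid_rate = as<double>(prior["resid_rate"]);
  pr.fsd_shape = as<double>(prior["fsd_shape"]);
  pr.fsd_rate = as<double>(prior["fsd_rate"]);
  return pr;
}

Pars unpack(const arma::vec& u, const Spec& sp) {
  Pars P;
  int off = 0;
  P.nu = u.subvec(0, sp.p - 1);
  off = sp.p;
  P.lambda.set_size(sp.p);
  if (sp.m > 0) {
    int k = 0;
    for (int j = 0; j < sp.p; ++j)
      P.lambda[j] = sp.is_ref[j] ? 1.0 : u[off + k++];
    off += sp.nfree;
  } else {
    P.lambda.zeros();
  }
  P.theta = arma::exp(2.0 * u.subvec(off, off + sp.p - 1));
  off += sp.p;
  if (sp.m > 0) {
    P.fsd = arma::exp(u.subvec(off, off + sp.m - 1));
    off += sp.m;
    P.corr.eye(sp.m, sp.m);
    int k = 0;
    for (int c = 0; c < sp.m; ++c)
      for (int r = c + 1; r < sp.m; ++r) {
        double rho = std::tanh(u[off + k++]);
        P.corr(r, c) = P.corr(c, r) = rho;
      }
  }
  return P;
}

// -(N/2) [ p log 2pi + log|Sig| + tr(S Sig^-1) + (ybar-nu)' Sig^-1 (ybar-nu) ]
double loglik(const Pars& P, const Spec& sp, const arma::mat& S,
              const arma::vec& ybar, double N) {
  arma::mat Sigma;
  if (sp.m > 0) {
    arma::mat L(sp.p, sp.m, arma::fill::zeros);
    for (int j = 0; j < sp.p; ++j) L(j, sp.factor_of[j] - 1) = P.lambda[j];
    arma::mat D = arma::diagmat(P.fsd);
    Sigma = L * (D * P.corr * D) * L.t();
    Sigma.diag() += P.theta;
  } else {
    Sigma = arma::diagmat(P.theta);
  }
  arma::mat R;
  if (!arma::chol(R, Sigma)) return -arma::datum::inf;  // Sigma = R'R
  // reject numerically singular implied covariances before solving
  if (R.diag().min() < 1e-12 * R.diag().max()) return -arma::datum::inf;
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  arma::mat W = arma::solve(arma::trimatl(R.t()), S,
                            arma::solve_opts::fast);
  arma::mat SigInvS = arma::solve(arma::trimatu(R), W,
                                  arma::solve_opts::fast);
  double tr = arma::trace(SigInvS);
  arma::vec w = arma::solve(arma::trimatl(R.t()), ybar - P.nu,
                            arma::solve_opts::fast);
  double quad = arma::dot(w, w);
  return -0.5 * N * (sp.p * std::log(2.0 * M_PI) + logdet + tr + quad);
}

// Log prior density on the unconstrained scale (Jacobians included):
//   nu_j        ~ N(0, nu_sd^2)
//   lambda_j    ~ N(0, loading_sd^2)          (free loadings only)
//   resid sd    ~ Gamma(shape, rate)          (+ log-scale Jacobian)
//   factor sd   ~ Gamma(shape, rate)          (+ log-scale Jacobian)
//   correlations uniform per off-diagonal, jointly truncated to the positive
//   definite region, with the exact normalizing constant for m <= 3
//   (vol = 2 per correlation for m == 2; elliptope volume pi^2/2 for m == 3);
//   atanh-scale Jacobian log(1 - rho^2) added per correlation.
double logprior(const arma::vec& u, const Pars& P, const Spec& sp,
                const Priors& pr) {
  double lp = 0.0;
  for (int j = 0; j < sp.p; ++j)
    lp += R::dnorm(P.nu[j], 0.0, pr.nu_sd, 1);
  if (sp.m > 0) {
    for (int j = 0; j < sp.p; ++j)
      if (!sp.is_ref[j]) lp += R::dnorm(P.lambda[j], 0.0, pr.loading_sd, 1);
  }
  int off = sp.p + sp.nfree;
  for (int j = 0; j < sp.p; ++j) {
    double t = u[off + j];
    lp += R::dgamma(std::exp(t), pr.resid_shape, 1.0 / pr.resid_rate, 1) + t;
  }
  off += sp.p;
  if (sp.m > 0) {
    for (int k = 0; k < sp.m; ++k) {
      double t = u[off + k];
      lp += R::dgamma(std::exp(t), pr.fsd_shape, 1.0 / pr.fsd_rate, 1) + t;
    }
    off += sp.m;
    if (sp.ncorr > 0) {
      arma::mat Rc;
      if (!arma::chol(Rc, P.corr)) return -arma::datum::inf;
      for (int k = 0; k < sp.ncorr; ++k) {
        double rho = std::tanh(u[off + k]);
        lp += std::log1p(-rho * rho);
      }
      double vol = (sp.m == 2) ? 2.0
                 : (sp.m == 3) ? (M_PI * M_PI / 2.0)
                               : std::pow(2.0, sp.ncorr);  // untruncated fallback
      lp -= std::log(vol);
    }
  }
  return lp;
}

double logpost(const arma::vec& u, const Spec& sp, const Priors& pr,
               const arma::mat& S, const arma::vec& ybar, double N,
               double lik_weight) {
  Pars P = unpack(u, sp);
  double lp = logprior(u, P, sp, pr);
  if (!std::isfinite(lp)) return -arma::datum::inf;
  if (lik_weight != 0.0) {
    double ll = loglik(P, sp, S, ybar, N);
    if (!std::isfinite(ll)) return -arma::datum::inf;
    lp += lik_weight * ll;
  }
  return lp;
}

// Exact conjugate draw of the intercept block: given the current implied
// covariance, nu | rest ~ N((w N Sig^-1 + I/s0^2)^-1 w N Sig^-1 ybar, same^-1)
// with s0 the prior intercept SD and w the likelihood weight (w = 0 gives a
// prior draw).  Returns false if the implied covariance is not PD.
bool gibbs_nu(arma::vec& u, const Spec& sp, const Priors& pr,
              const arma::mat& S, const arma::vec& ybar, double N,
              double lik_weight) {
  Pars P = unpack(u, sp);
  arma::mat Prec(sp.p, sp.p, arma::fill::zeros);
  arma::vec b(sp.p, arma::fill::zeros);
  if (lik_weight != 0.0) {
    arma::mat Sigma;
    if (sp.m > 0) {
      arma::mat L(sp.p, sp.m, arma::fill::zeros);
      for (int j = 0; j < sp.p; ++j) L(j, sp.factor_of[j] - 1) = P.lambda[j];
      arma::mat D = arma::diagmat(P.fsd);
      Sigma = L * (D * P.corr * D) * L.t();
      Sigma.diag() += P.theta;
    } else {
      Sigma = arma::diagmat(P.theta);
    }
    arma::mat SigInv;
    if (!arma::inv_sympd(SigInv, Sigma)) return false;
    Prec = lik_weight * N * SigInv;
    b = Prec * ybar;
  }
  Prec.diag() += 1.0 / (pr.nu_sd * pr.nu_sd);
  arma::mat R;
  if (!arma::chol(R, Prec)) return false;
  arma::vec mean = arma::solve(Prec, b);
  arma::vec z(sp.p);
  for (int j = 0; j < sp.p; ++j) z[j] = R::norm_rand();
  u.subvec(0, sp.p - 1) = mean + arma::solve(arma::trimatu(R), z);
  return true;
}

}  // namespace

// [[Rcpp::export]]
double cpp_log_posterior(const arma::vec& u, const arma::mat& S,
                         const arma::vec& ybar, double N, int p, int m,
                         IntegerVector factor_of, LogicalVector is_ref,
                         List prior, double lik_weight) {
  Spec sp = make_spec(p, m, factor_of, is_ref);
  Priors pr = make_priors(prior);
  return logpost(u, sp, pr, S, ybar, N, lik_weight);
}

// Adaptive random-walk Metropolis-within-Gibbs.  One recorded iteration is
// `sweeps` full scans over all coordinates.  Proposal scales adapt during
// warmup (Robbins-Monro towards 0.44 acceptance) and are frozen afterwards.
// [[Rcpp::export]]
List cpp_mwg_sampler(const arma::mat& S, const arma::vec& ybar, double N,
                     int p, int m, IntegerVector factor_of,
                     LogicalVector is_ref, List prior, const arma::vec& u0,
                     int n_warmup, int n_kept, int sweeps, double lik_weight,
                     const arma::vec& step0) {
  Spec sp = make_spec(p, m, factor_of, is_ref);
  Priors pr = make_priors(prior);
  const int d = sp.d;
  if ((int)u0.n_elem != d) stop("starting vector has wrong length");

  arma::vec u = u0;
  double lp_cur = logpost(u, sp, pr, S, ybar, N, lik_weight);
  if (!std::isfinite(lp_cur)) stop("invalid starting values (log posterior not finite)");

  arma::vec ls = arma::log(step0);
  arma::mat kept(n_kept, d);
  arma::vec acc_kept(d, arma::fill::zeros);
  const double target = 0.44;
  long scan = 0;

  for (int iter = 0; iter < n_warmup + n_kept; ++iter) {
    for (int sw = 0; sw < sweeps; ++sw) {
      ++scan;
      double gam = std::min(0.25, 2.0 / std::sqrt((double)scan));
      // intercept block: exact conjugate (Gibbs) draw
      if (gibbs_nu(u, sp, pr, S, ybar, N, lik_weight))
        lp_cur = logpost(u, sp, pr, S, ybar, N, lik_weight);
      // remaining coordinates: adaptive random-walk Metropolis
      for (int j = p; j < d; ++j) {
        double old = u[j];
        u[j] = old + std::exp(ls[j]) * R::norm_rand();
        double lp_new = logpost(u, sp, pr, S, ybar, N, lik_weight);
        double alpha = std::isfinite(lp_new)
                           ? std::exp(std::min(0.0, lp_new - lp_cur))
                           : 0.0;
        if (alpha > 0.0 && R::unif_rand() < alpha) {
          lp_cur = lp_new;
          if (iter >= n_warmup) acc_kept[j] += 1.0;
        } else {
          u[j] = old;
        }
        if (iter < n_warmup) ls[j] += gam * (alpha - target);
      }
    }
    if (iter >= n_warmup) kept.row(iter - n_warmup) = u.t();
  }
  acc_kept /= (double)(n_kept * sweeps);
  acc_kept.subvec(0, p - 1).fill(1.0);  // intercepts are Gibbs-updated
  return List::create(_["draws"] = kept, _["accept"] = acc_kept,
                      _["step"] = arma::exp(ls), _["logpost_last"] = lp_cur);
}

// Sample moments (divisor-N covariance) of a replicate dataset of size N
// drawn from N(mu, Sigma).  Used by posterior predictive checking.
// [[Rcpp::export]]
List cpp_sim_moments(const arma::vec& mu, const arma::mat& Sigma, int N) {
  int p = mu.n_elem;
  arma::mat R;
  if (!arma::chol(R, Sigma)) stop("Sigma is not positive definite");
  arma::mat Z(N, p);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < p; ++j) Z(i, j) = R::norm_rand();
  arma::mat Y = Z * R;  // rows ~ N(0, R'R = Sigma)
  Y.each_row() += mu.t();
  arma::rowvec yb = arma::mean(Y, 0);
  Y.each_row() -= yb;
  arma::mat Sm = (Y.t() * Y) / (double)N;
  return List::create(_["ybar"] = arma::vec(yb.t()), _["S"] = Sm);
}
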
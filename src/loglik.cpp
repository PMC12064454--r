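// Structured two-level Gaussian log-likelihood for clustered diary data.
//
// For dyad j with n_j observed days of p daily indicators and a vector of
// q between-only variables z_j, the covariance of the stacked data is
// I_{n_j} (x) Sigma_W + J_{n_j} (x) Sigma_B plus the between-only blocks.
// The likelihood is evaluated through the eigenstructure of J: n_j - 1
// deviation components with covariance Sigma_W, and the cluster mean jointly
// with z_j with covariance [[Sigma_B^yy + Sigma_W / n_j, Sigma_B^yz],
// [Sigma_B^zy, Sigma_B^zz]]. The dense n_j * p covariance is never formed.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct FreeMap {
  arma::imat map; // columns: level(0 W,1 B,2 mu), mat(0 A,1 S,2 L), i, j, trans
};

struct ModelCtx {
  int kind; // 0 = RAM, 1 = Cholesky (saturated / baseline)
  arma::mat AW0, SW0, AB0, SB0, LW0, LB0;
  arma::uvec obsW, obsB;
  arma::vec mu0;
  arma::imat fmap;
  int p, m;
};

static ModelCtx parse_ctx(const List& ctx) {
  ModelCtx mc;
  mc.kind = as<int>(ctx["kind"]);
  mc.p = as<int>(ctx["p"]);
  mc.m = as<int>(ctx["m"]);
  if (mc.kind == 0) {
    mc.AW0 = as<arma::mat>(ctx["AW0"]);
    mc.SW0 = as<arma::mat>(ctx["SW0"]);
    mc.AB0 = as<arma::mat>(ctx["AB0"]);
    mc.SB0 = as<arma::mat>(ctx["SB0"]);
    mc.obsW = as<arma::uvec>(ctx["obsW"]);
    mc.obsB = as<arma::uvec>(ctx["obsB"]);
  } else {
    mc.LW0 = as<arma::mat>(ctx["LW0"]);
    mc.LB0 = as<arma::mat>(ctx["LB0"]);
  }
  mc.mu0 = as<arma::vec>(ctx["mu0"]);
  mc.fmap = as<arma::imat>(ctx["fmap"]);
  return mc;
}

// returns false if implied covariance is not positive definite
static bool implied(const ModelCtx& mc, const arma::vec& theta, bool raw,
                    arma::mat& SigW, arma::mat& SigB, arma::vec& mu) {
  arma::mat AW, SW, AB, SB, LW, LB;
  if (mc.kind == 0) {
    AW = mc.AW0; SW = mc.SW0; AB = mc.AB0; SB = mc.SB0;
  } else {
    LW = mc.LW0; LB = mc.LB0;
  }
  mu = mc.mu0;
  const arma::imat& f = mc.fmap;
  for (arma::uword k = 0; k < f.n_rows; ++k) {
    double v = theta(k);
    if (!raw && f(k, 4) == 1) v = std::exp(v);
    int lev = f(k, 0), mat = f(k, 1), i = f(k, 2), j = f(k, 3);
    if (lev == 2) { mu(i) = v; continue; }
    if (mat == 0) {
      if (lev == 0) AW(i, j) = v; else AB(i, j) = v;
    } else if (mat == 1) {
      if (lev == 0) { SW(i, j) = v; SW(j, i) = v; }
      else          { SB(i, j) = v; SB(j, i) = v; }
    } else {
      if (lev == 0) LW(i, j) = v; else LB(i, j) = v;
    }
  }
  if (mc.kind == 0) {
    arma::mat IW = arma::eye(AW.n_rows, AW.n_rows) - AW;
    arma::mat IB = arma::eye(AB.n_rows, AB.n_rows) - AB;
    if (arma::rcond(IW) < 1e-12 || arma::rcond(IB) < 1e-12) return false;
    arma::mat MW, MB;
    if (!arma::inv(MW, IW) || !arma::inv(MB, IB)) return false;
    arma::mat CW = MW * SW * MW.t();
    arma::mat CB = MB * SB * MB.t();
    SigW = CW.submat(mc.obsW, mc.obsW);
    SigB = CB.submat(mc.obsB, mc.obsB);
  } else {
    SigW = LW * LW.t();
    SigB = LB * LB.t();
  }
  return SigW.is_finite() && SigB.is_finite();
}

static double ll_eval(const ModelCtx& mc, const List& stats,
                      const arma::vec& theta, bool raw) {
  arma::mat SigW, SigB;
  arma::vec mu;
  if (!implied(mc, theta, raw, SigW, SigB, mu)) return NA_REAL;

  double NmJ = as<double>(stats["NmJ"]);
  arma::mat Sdev = as<arma::mat>(stats["Sdev"]);
  arma::ivec nj = as<arma::ivec>(stats["nj"]);
  List U = stats["U"];
  int p = mc.p, m = mc.m;

  arma::mat LW;
  if (!arma::chol(LW, SigW, "lower") || LW.diag().min() < 1e-12) {
    return NA_REAL;
  }
  double ldW = 2.0 * arma::accu(arma::log(LW.diag()));
  // trace(SigW^-1 Sdev) via triangular solves
  arma::mat X = arma::solve(arma::trimatl(LW), Sdev);
  arma::mat Y = arma::solve(arma::trimatl(LW), X.t());
  double tr = arma::trace(Y);
  double ll = -0.5 * (NmJ * (p * LOG2PI + ldW) + tr);

  for (int g = 0; g < (int)nj.n_elem; ++g) {
    arma::mat Ug = as<arma::mat>(U[g]);
    int ng = Ug.n_rows;
    arma::mat V = SigB;
    V.submat(0, 0, p - 1, p - 1) += SigW / (double)nj(g);
    arma::mat LV;
    if (!arma::chol(LV, V, "lower") || LV.diag().min() < 1e-12) {
      return NA_REAL;
    }
    double ldV = 2.0 * arma::accu(arma::log(LV.diag()));
    arma::mat R = Ug.each_row() - mu.t();
    arma::mat Z = arma::solve(arma::trimatl(LV), R.t());
    double quad = arma::accu(Z % Z);
    // Jacobian of expressing the mean component through ybar rather than
    // the orthonormal Helmert coordinate sqrt(n_j) * ybar
    ll += -0.5 * (ng * (m * LOG2PI + ldV + p * std::log((double)nj(g))) + quad);
  }
  return ll;
}

// [[Rcpp::export]]
double cfm_ll_cpp(const arma::vec& theta, const List& ctx, const List& stats,
                  bool raw = false) {
  ModelCtx mc = parse_ctx(ctx);
  return ll_eval(mc, stats, theta, raw);
}

// [[Rcpp::export]]
arma::vec cfm_grad_cpp(const arma::vec& theta, const List& ctx,
                       const List& stats, bool raw = false) {
  ModelCtx mc = parse_ctx(ctx);
  int K = theta.n_elem;
  arma::vec g(K);
  arma::vec th = theta;
  for (int k = 0; k < K; ++k) {
    double h = 1e-6 * std::max(1.0, std::fabs(theta(k)));
    th(k) = theta(k) + h;
    double fp = ll_eval(mc, stats, th, raw);
    th(k) = theta(k) - h;
    double fm = ll_eval(mc, stats, th, raw);
    th(k) = theta(k);
    g(k) = (fp - fm) / (2.0 * h);
  }
  return g;
}

// [[Rcpp::export]]
arma::mat cfm_hess_cpp(const arma::vec& theta, const List& ctx,
                       const List& stats, bool raw = false) {
  ModelCtx mc = parse_ctx(ctx);
  int K = theta.n_elem;
  arma::vec h(K);
  for (int k = 0; k < K; ++k) {
    h(k) = 5e-4 * std::max(1.0, std::fabs(theta(k)));
  }
  double f0 = ll_eval(mc, stats, theta, raw);
  arma::mat H(K, K);
  arma::vec th = theta;
  for (int k = 0; k < K; ++k) {
    th(k) = theta(k) + h(k);
    double fp = ll_eval(mc, stats, th, raw);
    th(k) = theta(k) - h(k);
    double fm = ll_eval(mc, stats, th, raw);
    th(k) = theta(k);
    H(k, k) = (fp - 2.0 * f0 + fm) / (h(k) * h(k));
    for (int l = k + 1; l < K; ++l) {
      th(k) = theta(k) + h(k); th(l) = theta(l) + h(l);
      double fpp = ll_eval(mc, stats, th, raw);
      th(l) = theta(l) - h(l);
      double fpm = ll_eval(mc, stats, th, raw);
      th(k) = theta(k) - h(k); th(l) = theta(l) + h(l);
      double fmp = ll_eval(mc, stats, th, raw);
      th(l) = theta(l) - h(l);
      double fmm = ll_eval(mc, stats, th, raw);
      th(k) = theta(k); th(l) = theta(l);
      H(k, l) = H(l, k) = (fpp - fpm - fmp + fmm) / (4.0 * h(k) * h(l));
    }
  }
  return H;
}
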
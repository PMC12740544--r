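// Compiled core of the NLMEM engine: per-subject joint -2*log-likelihood for
// the six-parameter sum-of-exponentials kinetics model with log-normal random
// effects, its analytic gradient in the random effects eta, and a damped
// Newton inner optimizer producing the Laplace-approximate marginal -2LL.
//
// Parameter order everywhere: (A1, A2, A3, lambda1, lambda2, lambda3).
// Individual parameters are p_j = theta_j * exp(eta_j).

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// f(t) and the n x 6 Jacobian df/dp of the sum-of-exponentials curve.
// f = A1 e^{-(l1+lp)t} + A2 e^{-(l2+lp)t} - A3 e^{-(l3+lp)t}
//     - (A1+A2-A3) e^{-(lbc+lp)t}
static void soef_fjac(const arma::vec& p, double lp, double lbc,
                      const arma::vec& t, arma::vec& f, arma::mat* J) {
  const double A1 = p(0), A2 = p(1), A3 = p(2);
  const double l1 = p(3), l2 = p(4), l3 = p(5);
  arma::vec e1 = arma::exp(-(l1 + lp) * t);
  arma::vec e2 = arma::exp(-(l2 + lp) * t);
  arma::vec e3 = arma::exp(-(l3 + lp) * t);
  arma::vec e4 = arma::exp(-(lbc + lp) * t);
  f = A1 * e1 + A2 * e2 - A3 * e3 - (A1 + A2 - A3) * e4;
  if (J) {
    J->col(0) = e1 - e4;
    J->col(1) = e2 - e4;
    J->col(2) = e4 - e3;
    J->col(3) = -A1 * (t % e1);
    J->col(4) = -A2 * (t % e2);
    J->col(5) =  A3 * (t % e3);
  }
}

// [[Rcpp::export]]
arma::vec cpp_soef_eval(const arma::vec& p, double lp, double lbc,
                        const arma::vec& t) {
  arma::vec f;
  soef_fjac(p, lp, lbc, t, f, nullptr);
  return f;
}

// Joint -2LL of one subject at eta: residual part with variance
// v_i = s2a + s2p * max(f_i, floor)^2, plus the Gaussian prior on the
// components with omega_j > 0.  omega_j == 0 is a point mass at eta_j = 0
// (no prior normalization term; eta_j is expected to be 0 there).
static double joint_impl(const arma::vec& theta, const arma::vec& omega,
                         double s2a, double s2p, double floor_f,
                         const arma::vec& t, const arma::vec& y,
                         const arma::vec& eta, double lp, double lbc,
                         arma::vec* grad) {
  arma::vec p = theta % arma::exp(eta);
  arma::vec f;
  arma::mat J;
  if (grad) J.set_size(t.n_elem, 6);
  soef_fjac(p, lp, lbc, t, f, grad ? &J : nullptr);

  double val = 0.0;
  arma::vec dvdf;
  if (grad) { grad->zeros(6); dvdf.set_size(t.n_elem); }
  for (arma::uword i = 0; i < t.n_elem; ++i) {
    double fv = std::max(f(i), floor_f);
    double v  = s2a + s2p * fv * fv;
    double r  = y(i) - f(i);
    val += std::log(v) + LOG2PI + r * r / v;
    if (grad) {
      double dv = (f(i) > floor_f) ? 2.0 * s2p * fv : 0.0;
      // d/df [log v + r^2/v] = dv/v + 2r/v (dr/df = -1) - r^2 dv / v^2
      dvdf(i) = dv / v - 2.0 * r / v - r * r * dv / (v * v);
    }
  }
  if (grad) {
    arma::vec g = J.t() * dvdf;       // d residual / d p
    *grad = g % p;                    // chain rule dp_j/deta_j = p_j
  }
  for (arma::uword j = 0; j < 6; ++j) {
    if (omega(j) > 0.0) {
      val += std::log(omega(j)) + LOG2PI + eta(j) * eta(j) / omega(j);
      if (grad) (*grad)(j) += 2.0 * eta(j) / omega(j);
    }
  }
  return val;
}

// [[Rcpp::export]]
List cpp_joint_neg2ll(const arma::vec& theta, const arma::vec& omega,
                      double s2a, double s2p, double floor_f,
                      const arma::vec& t, const arma::vec& y,
                      const arma::vec& eta, double lp, double lbc,
                      bool want_grad) {
  arma::vec g(6, arma::fill::zeros);
  double v = joint_impl(theta, omega, s2a, s2p, floor_f, t, y, eta, lp, lbc,
                        want_grad ? &g : nullptr);
  return List::create(_["value"] = v, _["grad"] = g);
}

// Central finite differences of the analytic gradient -> Hessian of the
// joint -2LL, restricted to the free components.
static arma::mat fd_hessian(const arma::vec& theta, const arma::vec& omega,
                            double s2a, double s2p, double floor_f,
                            const arma::vec& t, const arma::vec& y,
                            const arma::vec& eta, double lp, double lbc,
                            const arma::uvec& free, double h) {
  const arma::uword k = free.n_elem;
  arma::mat H(k, k);
  arma::vec gp(6), gm(6), e(eta);
  for (arma::uword a = 0; a < k; ++a) {
    e(free(a)) = eta(free(a)) + h;
    joint_impl(theta, omega, s2a, s2p, floor_f, t, y, e, lp, lbc, &gp);
    e(free(a)) = eta(free(a)) - h;
    joint_impl(theta, omega, s2a, s2p, floor_f, t, y, e, lp, lbc, &gm);
    e(free(a)) = eta(free(a));
    for (arma::uword b = 0; b < k; ++b)
      H(a, b) = (gp(free(b)) - gm(free(b))) / (2.0 * h);
  }
  return 0.5 * (H + H.t());
}

static arma::mat expected_info_half_impl(const arma::vec& theta,
                                          const arma::vec& omega,
                                          double s2a, double s2p,
                                          double floor_f, const arma::vec& t,
                                          const arma::vec& eta, double lp,
                                          double lbc);

// Inner MAP step: damped Newton on the joint -2LL over the free eta
// components, then the curvature correction  log det( C / (2*pi) )  with C
// the curvature of the negative log posterior at the mode:
// corr_type = 0 -> observed Hessian of joint/2 (strict Laplacian),
// corr_type = 1 -> expected (Fisher) information (FOCE-style; smooth and
//                  positive definite everywhere).
// [[Rcpp::export]]
List cpp_inner_laplace(const arma::vec& theta, const arma::vec& omega,
                       double s2a, double s2p, double floor_f,
                       const arma::vec& t, const arma::vec& y,
                       const arma::vec& eta0, double lp, double lbc,
                       double grad_tol, int max_iter, int corr_type = 0) {
  arma::uvec free = arma::find(omega > 0.0);
  arma::vec eta(6, arma::fill::zeros);
  for (arma::uword a = 0; a < free.n_elem; ++a) eta(free(a)) = eta0(free(a));

  arma::vec g(6);
  double val = joint_impl(theta, omega, s2a, s2p, floor_f, t, y, eta, lp, lbc, &g);
  bool converged = free.n_elem == 0;
  const double h = 1e-5;

  if (free.n_elem > 0) {
    for (int it = 0; it < max_iter; ++it) {
      arma::vec gf = g.elem(free);
      if (arma::abs(gf).max() < grad_tol) { converged = true; break; }
      arma::mat H = fd_hessian(theta, omega, s2a, s2p, floor_f, t, y, eta,
                               lp, lbc, free, h);
      // ridge until the Newton system is solvable and descent succeeds
      double ridge = 0.0;
      arma::vec step;
      bool ok = false;
      for (int r = 0; r < 12 && !ok; ++r) {
        arma::mat Hr = H + ridge * arma::eye(free.n_elem, free.n_elem);
        ok = arma::solve(step, Hr, -gf, arma::solve_opts::no_approx);
        if (ok && arma::dot(step, gf) >= 0.0) ok = false;  // not a descent dir
        if (!ok) ridge = (ridge == 0.0) ? 1e-4 * arma::abs(H.diag()).max() + 1e-8
                                        : ridge * 10.0;
      }
      if (!ok) { step = -gf; }  // last resort: steepest descent
      // backtracking line search
      double alpha = 1.0;
      bool improved = false;
      arma::vec eta_try(eta);
      for (int ls = 0; ls < 30; ++ls) {
        for (arma::uword a = 0; a < free.n_elem; ++a)
          eta_try(free(a)) = eta(free(a)) + alpha * step(a);
        arma::vec gt(6);
        double vt = joint_impl(theta, omega, s2a, s2p, floor_f, t, y, eta_try,
                               lp, lbc, &gt);
        if (std::isfinite(vt) && vt <= val) {
          double dec = val - vt;
          eta = eta_try; val = vt; g = gt;
          improved = true;
          if (dec < 1e-13 * (std::abs(val) + 1.0)) {
            // stagnation at (numerical) optimum
            if (arma::abs(g.elem(free)).max() < 1e-4) converged = true;
            it = max_iter;
          }
          break;
        }
        alpha *= 0.5;
      }
      if (!improved) {
        if (arma::abs(g.elem(free)).max() < 1e-4) converged = true;
        break;
      }
    }
  }

  // Laplace correction at the mode
  double logdet_term = 0.0;
  arma::mat Hmode;
  bool hess_pd = true;
  if (free.n_elem > 0) {
    Hmode = fd_hessian(theta, omega, s2a, s2p, floor_f, t, y, eta, lp, lbc,
                       free, h);
    if (!Hmode.is_finite() || !std::isfinite(val)) {
      // degenerate region (e.g. absurd multi-start draw): report a large
      // finite value so the outer optimizer moves away
      return List::create(_["value"] = 1e10, _["joint"] = val,
                          _["eta"] = eta,
                          _["hessian"] = arma::mat(6, 6, arma::fill::zeros),
                          _["converged"] = false, _["hess_pd"] = false);
    }
    arma::mat Hhalf;
    if (corr_type == 1) {
      arma::mat I6 = expected_info_half_impl(theta, omega, s2a, s2p, floor_f,
                                             t, eta, lp, lbc);
      Hhalf = I6.submat(free, free);
    } else {
      Hhalf = 0.5 * Hmode;
    }
    arma::mat R;
    if (!arma::chol(R, Hhalf)) {
      hess_pd = false;
      double bump = 1e-8 * arma::abs(Hhalf.diag()).max() + 1e-12;
      while (!arma::chol(R, Hhalf + bump * arma::eye(free.n_elem, free.n_elem)))
        bump *= 10.0;
    }
    logdet_term = 2.0 * arma::accu(arma::log(R.diag()))
                  - double(free.n_elem) * LOG2PI;
  }

  arma::mat Hfull(6, 6, arma::fill::zeros);
  if (free.n_elem > 0)
    for (arma::uword a = 0; a < free.n_elem; ++a)
      for (arma::uword b = 0; b < free.n_elem; ++b)
        Hfull(free(a), free(b)) = Hmode(a, b);

  return List::create(_["value"] = val + logdet_term,
                      _["joint"] = val,
                      _["eta"] = eta,
                      _["hessian"] = Hfull,       // Hessian of joint -2LL
                      _["converged"] = converged,
                      _["hess_pd"] = hess_pd);
}

// Expected (Fisher) information of the joint -2LL in eta at a given point,
// on the half scale (curvature of the negative log posterior): for
// y ~ N(f, v(f)),  I_half = sum_i f'_a f'_b (1/v + (dv/df)^2/(2 v^2))
// + diag(1/omega).  PSD by construction; used for the reported EBE
// covariance where the observed Hessian can lose definiteness.
static arma::mat expected_info_half_impl(const arma::vec& theta,
                                          const arma::vec& omega,
                                          double s2a, double s2p,
                                          double floor_f, const arma::vec& t,
                                          const arma::vec& eta, double lp,
                                          double lbc) {
  arma::vec p = theta % arma::exp(eta);
  arma::vec f;
  arma::mat J(t.n_elem, 6);
  soef_fjac(p, lp, lbc, t, f, &J);
  arma::mat H(6, 6, arma::fill::zeros);
  for (arma::uword i = 0; i < t.n_elem; ++i) {
    double fv = std::max(f(i), floor_f);
    double v  = s2a + s2p * fv * fv;
    double dv = (f(i) > floor_f) ? 2.0 * s2p * fv : 0.0;
    double w  = 1.0 / v + dv * dv / (2.0 * v * v);
    arma::vec fp = (J.row(i).t() % p);
    H += w * (fp * fp.t());
  }
  for (arma::uword j = 0; j < 6; ++j)
    if (omega(j) > 0.0) H(j, j) += 1.0 / omega(j);
  return H;
}

// [[Rcpp::export]]
arma::mat cpp_expected_info_half(const arma::vec& theta, const arma::vec& omega,
                                 double s2a, double s2p, double floor_f,
                                 const arma::vec& t, const arma::vec& y,
                                 const arma::vec& eta, double lp, double lbc) {
  (void)y;
  return expected_info_half_impl(theta, omega, s2a, s2p, floor_f, t, eta,
                                 lp, lbc);
}

// Sum of Laplace contributions over subjects; warm starts in/out.
// [[Rcpp::export]]
List cpp_marginal_neg2ll(const arma::vec& theta, const arma::vec& omega,
                         double s2a, double s2p, double floor_f,
                         const List& t_list, const List& y_list,
                         const arma::mat& eta_warm, double lp, double lbc,
                         double grad_tol, int max_iter, int corr_type = 0) {
  const int n = t_list.size();
  arma::mat eta_out(6, n);
  arma::vec per(n);
  bool all_conv = true;
  for (int s = 0; s < n; ++s) {
    arma::vec t = as<arma::vec>(t_list[s]);
    arma::vec y = as<arma::vec>(y_list[s]);
    List r = cpp_inner_laplace(theta, omega, s2a, s2p, floor_f, t, y,
                               eta_warm.col(s), lp, lbc, grad_tol, max_iter,
                               corr_type);
    per(s) = as<double>(r["value"]);
    eta_out.col(s) = as<arma::vec>(r["eta"]);
    if (!as<bool>(r["converged"])) all_conv = false;
  }
  return List::create(_["value"] = arma::accu(per),
                      _["per_subject"] = per,
                      _["eta"] = eta_out,
                      _["all_converged"] = all_conv);
}
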
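// Cox partial-likelihood machinery shared by the marginal scan, the
// multi-covariate Newton fitter and the group-lasso ADMM solver.
//
// All routines expect each study pre-sorted by DECREASING observed time and
// take the TRANSPOSED design Xt (d features x n subjects) so subject vectors
// are contiguous columns. `risk_end[i]` (0-based) is the last sorted
// position whose time equals time[i]; the Breslow risk set of subject i is
// then positions 0..risk_end[i] (every subject with Y_j >= Y_i, tied event
// times sharing one risk set). Because times decrease, risk_end is
// non-decreasing and a single forward pass accumulates the risk-set sums.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Each event term eta_i - log S_i is <= 0 (the subject sits in its own risk
// set), but S can underflow to 0 for extreme trial coefficients during
// step-halving; clamping keeps the objective finite and correctly signed so
// bad steps are rejected rather than accepted through NaN/Inf comparisons.
static const double TINY = std::numeric_limits<double>::min();

// loglik and (optionally) gradient. The gradient collapses to one GEMV:
//   grad = Xt (delta - w . G),  w_j = e^{eta_j - shift},
//   G_j = sum over events i whose risk set contains j of 1/S_i,
// with G built by a difference-array prefix sum. eta is shifted by its max
// before exponentiation so large coefficients cannot overflow; the shift
// cancels everywhere.
// G_j = sum of 1/S_i over events whose risk set contains position j. The
// risk set of event i is 0..risk_end[i] and risk_end is non-decreasing, so
// those events form a suffix of the event list; G is read off an
// all-positive suffix sum (a difference-array prefix sum would cancel
// catastrophically when the S_i span many orders of magnitude).
static void risk_weight_G(const vec& delta, const ivec& risk_end,
                          const vec& cw, vec& G) {
  const int n = cw.n_elem;
  std::vector<int> evpos;
  evpos.reserve(n);
  for (int i = 0; i < n; ++i) if (delta[i] > 0.5) evpos.push_back(i);
  const int m = (int) evpos.size();
  std::vector<double> suf(m + 1, 0.0);
  for (int e = m - 1; e >= 0; --e)
    suf[e] = suf[e + 1] + 1.0 / std::max(cw[risk_end[evpos[e]]], TINY);
  G.set_size(n);
  int e0 = 0;
  for (int j = 0; j < n; ++j) {
    while (e0 < m && risk_end[evpos[e0]] < j) ++e0;
    G[j] = suf[e0];
  }
}

static double cox_ll_grad(const mat& Xt, const vec& delta,
                          const ivec& risk_end, const vec& beta,
                          bool want_grad, vec& grad) {
  const int n = Xt.n_cols;
  vec eta = (beta.t() * Xt).t();
  double shift = eta.max();
  vec w = exp(eta - shift);
  vec cw = cumsum(w);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (delta[i] > 0.5) {
      double S = std::max(cw[risk_end[i]], TINY);
      ll += std::min((eta[i] - shift) - std::log(S), 0.0);
    }
  }
  if (want_grad) {
    vec G;
    risk_weight_G(delta, risk_end, cw, G);
    grad = Xt * (delta - w % G);
  }
  return ll;
}

// loglik, gradient and negative Hessian. The Hessian
//   -H = sum_events [ M2_i/S_i - mu_i mu_i' ],  M2 = sum x x' e^eta,
// is assembled in BLAS-3 form: the first term is Xw Xw' with column j of Xw
// scaled by sqrt(e^{eta_j} * G_j), G_j the sum of 1/S_i over events whose
// risk set contains j (a difference-array prefix sum); the second stacks
// the event-specific means mu_i into a d x m matrix.
static double cox_ll_grad_hess(const mat& Xt, const vec& delta,
                               const ivec& risk_end, const vec& beta,
                               vec& grad, mat& neg_hess) {
  const int n = Xt.n_cols, d = Xt.n_rows;
  vec eta = (beta.t() * Xt).t();
  double shift = eta.max();
  vec w = exp(eta - shift);
  grad.zeros(d);
  vec M1(d, fill::zeros);
  const int m = (int) accu(delta > 0.5);
  mat Mu(d, std::max(m, 1));
  double S = 0.0, ll = 0.0;
  int a = -1, e = 0;
  for (int i = 0; i < n; ++i) {
    while (a < risk_end[i]) { ++a; S += w[a]; M1 += w[a] * Xt.unsafe_col(a); }
    if (delta[i] > 0.5) {
      double Sm = std::max(S, TINY);
      ll += std::min((eta[i] - shift) - std::log(Sm), 0.0);
      vec mu = M1 / Sm;
      grad += Xt.unsafe_col(i); grad -= mu;
      Mu.col(e++) = mu;
    }
  }
  vec cw = cumsum(w);
  vec G;
  risk_weight_G(delta, risk_end, cw, G);
  mat Xw = Xt;
  Xw.each_row() %= sqrt(w % G).t();
  neg_hess = Xw * Xw.t();
  if (m > 0) neg_hess -= Mu.head_cols(m) * Mu.head_cols(m).t();
  neg_hess = 0.5 * (neg_hess + neg_hess.t());   // exact symmetry for chol
  return ll;
}

// [[Rcpp::export(name = ".cox_loglik_cpp")]]
double cox_loglik_cpp(const arma::mat& Xt, const arma::vec& delta,
                      const arma::ivec& risk_end, const arma::vec& beta) {
  vec g;
  return cox_ll_grad(Xt, delta, risk_end, beta, false, g);
}

// [[Rcpp::export(name = ".cox_grad_cpp")]]
arma::vec cox_grad_cpp(const arma::mat& Xt, const arma::vec& delta,
                       const arma::ivec& risk_end, const arma::vec& beta) {
  vec g;
  cox_ll_grad(Xt, delta, risk_end, beta, true, g);
  return g;
}

// [[Rcpp::export(name = ".cox_score_hess_cpp")]]
List cox_score_hess_cpp(const arma::mat& Xt, const arma::vec& delta,
                        const arma::ivec& risk_end, const arma::vec& beta) {
  vec g; mat nH;
  double ll = cox_ll_grad_hess(Xt, delta, risk_end, beta, g, nH);
  return List::create(_["loglik"] = ll, _["score"] = g, _["neg_hessian"] = nH);
}

// Scalar (single-covariate) evaluation used by the marginal scan.
static double cox_eval1(const double* x, int n, const vec& delta,
                        const ivec& risk_end, double beta, double xmax,
                        double xmin, double& score, double& info) {
  double shift = beta >= 0 ? beta * xmax : beta * xmin;
  double S = 0.0, m1 = 0.0, m2 = 0.0, ll = 0.0;
  score = 0.0; info = 0.0;
  int a = -1;
  for (int i = 0; i < n; ++i) {
    while (a < risk_end[i]) {
      ++a;
      double w = std::exp(beta * x[a] - shift);
      S += w; m1 += w * x[a]; m2 += w * x[a] * x[a];
    }
    if (delta[i] > 0.5) {
      double Sm = std::max(S, TINY);
      ll += std::min((beta * x[i] - shift) - std::log(Sm), 0.0);
      double mu = m1 / Sm;
      score += x[i] - mu;
      info += m2 / Sm - mu * mu;
    }
  }
  return ll;
}

// Marginal Cox Newton fit for every column of X (here passed n x p).
// flags: 0 = ok, 1 = degenerate covariate, 2 = separation (|beta| > bcap).
// [[Rcpp::export(name = ".marginal_scan_cpp")]]
List marginal_scan_cpp(const arma::mat& X, const arma::vec& delta,
                       const arma::ivec& risk_end, double tol, int maxit,
                       int max_halv, double bcap) {
  const int p = X.n_cols, n = X.n_rows;
  vec beta(p, fill::zeros), se(p), scorev(p, fill::zeros);
  ivec flags(p, fill::zeros), iters(p, fill::zeros), conv(p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    const double* xj = X.colptr(j);
    double xmax = X.col(j).max(), xmin = X.col(j).min();
    double b = 0.0, sc, inf;
    double ll = cox_eval1(xj, n, delta, risk_end, b, xmax, xmin, sc, inf);
    if (inf < 1e-12) { flags[j] = 1; se[j] = NA_REAL; beta[j] = NA_REAL; continue; }
    int it = 0;
    bool sep = false, converged = std::fabs(sc) < tol;
    while (!converged && it < maxit) {
      ++it;
      double step = sc / std::max(inf, 1e-12);
      double bnew = b + step, llnew, scn, infn;
      int h = 0;
      llnew = cox_eval1(xj, n, delta, risk_end, bnew, xmax, xmin, scn, infn);
      while (llnew < ll - 1e-12 && h < max_halv) {
        ++h;
        step *= 0.5;
        bnew = b + step;
        llnew = cox_eval1(xj, n, delta, risk_end, bnew, xmax, xmin, scn, infn);
      }
      if (llnew < ll - 1e-12) break;   // no ascent achievable
      b = bnew; ll = llnew; sc = scn; inf = infn;
      if (std::fabs(b) > bcap) { sep = true; break; }
      converged = std::fabs(sc) < tol;
    }
    beta[j] = b;
    scorev[j] = sc;
    iters[j] = it;
    conv[j] = converged ? 1 : 0;
    if (sep) flags[j] = 2;
    se[j] = inf > 1e-12 ? 1.0 / std::sqrt(inf) : NA_REAL;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["score"] = scorev,
                      _["flags"] = flags, _["iters"] = iters,
                      _["converged"] = conv);
}

// Damped Newton maximizer of the partial log-likelihood, optionally with a
// quadratic tether (rho/2)||beta - v||^2 subtracted (ridge-stabilized
// subproblems).
// [[Rcpp::export(name = ".cox_newton_cpp")]]
List cox_newton_cpp(const arma::mat& Xt, const arma::vec& delta,
                    const arma::ivec& risk_end, const arma::vec& init,
                    double rho, const arma::vec& v, double tol, int maxit,
                    int max_halv, double bcap) {
  const int d = Xt.n_rows;
  vec b = init, g(d);
  mat nH(d, d);
  bool tether = rho > 0.0;
  double ll = cox_ll_grad_hess(Xt, delta, risk_end, b, g, nH);
  auto obj = [&](double llv, const vec& bb) {
    return tether ? llv - 0.5 * rho * accu(square(bb - v)) : llv;
  };
  double f = obj(ll, b);
  int it = 0;
  bool sep = false, converged = false;
  while (it < maxit) {
    vec geff = g;
    mat Heff = nH;
    if (tether) { geff -= rho * (b - v); Heff.diag() += rho; }
    if (!geff.is_finite() || !Heff.is_finite()) break;
    if (norm(geff, "inf") < tol) { converged = true; break; }
    ++it;
    vec step;
    bool ok = solve(step, Heff, geff, solve_opts::likely_sympd + solve_opts::no_approx);
    double jit = 1e-8 * (1.0 + Heff.diag().max());
    while (!ok) {
      Heff.diag() += jit;
      jit *= 100.0;
      ok = solve(step, Heff, geff, solve_opts::likely_sympd + solve_opts::no_approx);
    }
    double snr = norm(step, 2);
    if (snr > 20.0) step *= 20.0 / snr;   // trust region
    vec bnew = b + step;
    double llnew = cox_ll_grad_hess(Xt, delta, risk_end, bnew, g, nH);
    double fnew = obj(llnew, bnew);
    int h = 0;
    while (fnew < f - 1e-12 && h < max_halv) {
      ++h;
      step *= 0.5;
      bnew = b + step;
      llnew = cox_ll_grad_hess(Xt, delta, risk_end, bnew, g, nH);
      fnew = obj(llnew, bnew);
    }
    if (fnew < f - 1e-12) {               // no ascent achievable: restore
      cox_ll_grad_hess(Xt, delta, risk_end, b, g, nH);
      break;
    }
    b = bnew; ll = llnew; f = fnew;
    if (!tether && norm(b, "inf") > bcap) { sep = true; break; }
  }
  ll = cox_ll_grad_hess(Xt, delta, risk_end, b, g, nH);
  return List::create(_["beta"] = b, _["loglik"] = ll, _["score"] = g,
                      _["neg_hessian"] = nH, _["n_iter"] = it,
                      _["converged"] = converged, _["separation"] = sep);
}

// Consensus ADMM for the cross-study group-lasso penalized sum of Cox
// partial log-likelihoods:
//   minimize  sum_k -l_k(beta_k)  +  lambda * sum_j ||z_j.||_2,  beta = z.
// beta-update: damped quasi-Newton steps on the smooth study subproblems
// with the Cholesky factor of (-H_k + rho I) refreshed periodically (the
// Cox Hessian varies slowly; step-halving on the exact subproblem objective
// keeps the stale-factor step a descent step). z-update: row-wise group
// soft threshold. u: scaled dual, rescaled when residual balancing changes
// rho.
// [[Rcpp::export(name = ".admm_group_cox_cpp")]]
List admm_group_cox_cpp(const List& Xts, const List& deltas, const List& risk_ends,
                        double lambda, arma::mat B, arma::mat Z, arma::mat U,
                        double rho, double eps_abs, double eps_rel, int max_iter,
                        int inner_iter, int hess_freq, bool adapt_rho,
                        int max_halv, bool trace, int adapt_every) {
  const int K = Xts.size();
  const int d = B.n_rows;
  std::vector<mat> Xt(K);
  std::vector<vec> del(K);
  std::vector<ivec> re(K);
  for (int k = 0; k < K; ++k) {
    Xt[k] = as<mat>(Xts[k]);
    del[k] = as<vec>(deltas[k]);
    re[k] = as<ivec>(risk_ends[k]);
  }
  std::vector<mat> chol_f(K);
  bool need_factor = true;
  const double sqdk = std::sqrt((double)(d * K));
  std::vector<double> obj_trace;
  obj_trace.reserve(256);
  double r_pri = NA_REAL, r_dual = NA_REAL;
  bool converged = false;
  int iter = 0;

  // penalized objective evaluated at the (sparse) Z iterate
  auto objective = [&](const mat& Zm) {
    double o = 0.0;
    vec g;
    for (int k = 0; k < K; ++k)
      o -= cox_ll_grad(Xt[k], del[k], re[k], Zm.col(k), false, g);
    for (int j = 0; j < d; ++j) o += lambda * norm(Zm.row(j), 2);
    return o;
  };

  for (iter = 1; iter <= max_iter; ++iter) {
    if (need_factor || ((iter - 1) % hess_freq == 0)) {
      for (int k = 0; k < K; ++k) {
        vec g; mat nH;
        cox_ll_grad_hess(Xt[k], del[k], re[k], B.col(k), g, nH);
        if (!nH.is_finite()) nH = eye(B.n_rows, B.n_rows);  // gradient-type step
        nH.diag() += rho;
        double jit = 1e-8 * (1.0 + nH.diag().max());
        while (!chol(chol_f[k], nH)) {   // subtractive assembly can leave
          nH.diag() += jit;              // tiny negative eigenvalues
          jit *= 100.0;
        }
      }
      need_factor = false;
    }
    // beta-update (per study, quasi-Newton with exact-objective halving)
    for (int k = 0; k < K; ++k) {
      vec v = Z.col(k) - U.col(k);
      vec b = B.col(k), g(d), gdummy;
      double llk = cox_ll_grad(Xt[k], del[k], re[k], b, true, g);
      double f = -llk + 0.5 * rho * accu(square(b - v));
      for (int t = 0; t < inner_iter; ++t) {
        vec gm = -g + rho * (b - v);
        if (norm(gm, "inf") < 1e-10) break;
        vec step = solve(trimatu(chol_f[k]),
                         solve(trimatl(chol_f[k].t()), gm));
        double sn = norm(step, 2);        // trust region: a stale factor or
        if (sn > 20.0) step *= 20.0 / sn; // an underflowed risk set can
                                          // produce absurd Newton steps
        vec bn = b - step;
        // candidates need the objective only; the gradient is refreshed
        // once the step is accepted
        double lln = cox_ll_grad(Xt[k], del[k], re[k], bn, false, gdummy);
        double fn = -lln + 0.5 * rho * accu(square(bn - v));
        int h = 0;
        while (fn > f + 1e-12 && h < max_halv) {
          ++h;
          step *= 0.5;
          bn = b - step;
          lln = cox_ll_grad(Xt[k], del[k], re[k], bn, false, gdummy);
          fn = -lln + 0.5 * rho * accu(square(bn - v));
        }
        if (fn > f + 1e-12) break;        // no descent: reject and stop
        b = bn; f = fn;
        if (t + 1 < inner_iter)
          cox_ll_grad(Xt[k], del[k], re[k], b, true, g);
      }
      B.col(k) = b;
    }
    // z-update: group soft threshold on rows of B + U
    mat Zold = Z;
    mat V = B + U;
    for (int j = 0; j < d; ++j) {
      double nr = norm(V.row(j), 2);
      double sc = nr > 0 ? std::max(0.0, 1.0 - (lambda / rho) / nr) : 0.0;
      Z.row(j) = sc * V.row(j);
    }
    U += B - Z;
    r_pri = norm(B - Z, "fro");
    r_dual = rho * norm(Z - Zold, "fro");
    if (trace) obj_trace.push_back(objective(Z));
    double eps_pri = sqdk * eps_abs + eps_rel * std::max(norm(B, "fro"), norm(Z, "fro"));
    double eps_dua = sqdk * eps_abs + eps_rel * rho * norm(U, "fro");
    if (r_pri < eps_pri && r_dual < eps_dua) { converged = true; break; }
    if (adapt_rho && iter % adapt_every == 0) {
      if (r_pri > 10.0 * r_dual && rho < 1e8) { rho *= 2.0; U /= 2.0; need_factor = true; }
      else if (r_dual > 10.0 * r_pri && rho > 1e-4) { rho /= 2.0; U *= 2.0; need_factor = true; }
    }
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["B"] = B, _["Z"] = Z, _["U"] = U, _["rho"] = rho,
                      _["n_iter"] = iter, _["converged"] = converged,
                      _["primal_residual"] = r_pri, _["dual_residual"] = r_dual,
                      _["objective_trace"] = NumericVector(obj_trace.begin(), obj_trace.end()));
}
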
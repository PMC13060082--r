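// Compiled core: adaptive Dormand-Prince RK45 integration of the network
// spread models, Gaussian observation likelihood, and an adaptive
// Metropolis-within-Gibbs sampler over the transformed parameter space.
//
// Model codes: 0 = DIFF (linear diffusion), 1 = DIFF-R (diffusion + FKPP
// rise), 2 = DIFF-RF (diffusion + rise with dynamic carrying capacity).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Drift operator A = -(sum_k rho_k L_k) acting on u, either dense
// (column-major) or sparse (coordinate triplets over the fixed Laplacian
// pattern, rebuilt cheaply when rho changes).
struct LinOp {
  const double* dense = nullptr;
  int N = 0;
  const int* ri = nullptr;
  const int* ci = nullptr;
  const double* val = nullptr;
  int nnz = 0;
  void apply(const double* y, double* dy) const {
    for (int i = 0; i < N; ++i) dy[i] = 0.0;
    if (dense) {
      for (int j = 0; j < N; ++j) {
        const double uj = y[j];
        if (uj != 0.0) {
          const double* Acol = dense + (size_t)j * N;
          for (int i = 0; i < N; ++i) dy[i] += Acol[i] * uj;
        }
      }
    } else {
      for (int e = 0; e < nnz; ++e) dy[ri[e]] += val[e] * y[ci[e]];
    }
  }
};

// Right-hand sides. State y: DIFF / DIFF-R -> u (length N);
// DIFF-RF -> [u, b] (length 2N).
static void rf_rhs(const double* y, double* dy, const LinOp& A, int N,
                   double alpha, const double* beta, const double* gamma,
                   int model) {
  A.apply(y, dy);
  if (model == 1) {
    for (int i = 0; i < N; ++i) dy[i] += alpha * y[i] * (beta[i] - y[i]);
  } else if (model == 2) {
    const double* b = y + N;
    double* db = dy + N;
    for (int i = 0; i < N; ++i) {
      dy[i] += alpha * y[i] * (b[i] - y[i]);
      db[i] = -gamma[i] * y[i];
    }
  }
}

// Dormand-Prince 5(4) coefficients.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights.
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate from t=0 through sorted output times; fills out (n_state x n_out).
// Returns true on success.
static bool rf_solve(const LinOp& A, int N, double alpha, const double* beta,
                     const double* gamma, int model, const double* y0,
                     int n_state, const double* t_out, int n_out, double rtol,
                     double atol, int max_steps, double* out) {
  std::vector<double> y(y0, y0 + n_state), ynew(n_state), yerr(n_state);
  std::vector<double> k1(n_state), k2(n_state), k3(n_state), k4(n_state),
      k5(n_state), k6(n_state), k7(n_state), ytmp(n_state);
  double t = 0.0;
  int iout = 0;
  while (iout < n_out && t_out[iout] <= 1e-300) {  // outputs at t = 0
    for (int i = 0; i < n_state; ++i) out[(size_t)iout * n_state + i] = y[i];
    ++iout;
  }
  if (iout >= n_out) return true;
  double t_end = t_out[n_out - 1];
  double h = std::min(1e-3, t_end / 100.0);
  if (h <= 0) return false;
  rf_rhs(y.data(), k1.data(), A, N, alpha, beta, gamma, model);
  int steps = 0;
  while (t < t_end) {
    if (++steps > max_steps) return false;
    bool clipped = false;
    double h_try = h;
    if (t + h_try >= t_out[iout]) { h_try = t_out[iout] - t; clipped = true; }
    // stages
    for (int i = 0; i < n_state; ++i) ytmp[i] = y[i] + h_try * a21 * k1[i];
    rf_rhs(ytmp.data(), k2.data(), A, N, alpha, beta, gamma, model);
    for (int i = 0; i < n_state; ++i)
      ytmp[i] = y[i] + h_try * (a31 * k1[i] + a32 * k2[i]);
    rf_rhs(ytmp.data(), k3.data(), A, N, alpha, beta, gamma, model);
    for (int i = 0; i < n_state; ++i)
      ytmp[i] = y[i] + h_try * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rf_rhs(ytmp.data(), k4.data(), A, N, alpha, beta, gamma, model);
    for (int i = 0; i < n_state; ++i)
      ytmp[i] = y[i] + h_try * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
    rf_rhs(ytmp.data(), k5.data(), A, N, alpha, beta, gamma, model);
    for (int i = 0; i < n_state; ++i)
      ytmp[i] = y[i] + h_try * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
    rf_rhs(ytmp.data(), k6.data(), A, N, alpha, beta, gamma, model);
    for (int i = 0; i < n_state; ++i)
      ynew[i] = y[i] + h_try * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    rf_rhs(ynew.data(), k7.data(), A, N, alpha, beta, gamma, model);
    // error estimate: 5th-order minus embedded 4th-order solution
    double err = 0.0;
    for (int i = 0; i < n_state; ++i) {
      double y4 = y[i] + h_try * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                  e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = (ynew[i] - y4) / sc;
      err += r * r;
    }
    err = std::sqrt(err / n_state);
    if (!std::isfinite(err)) { h *= 0.2; if (h < 1e-14) return false; continue; }
    if (err <= 1.0) {  // accept
      t += h_try;
      y.swap(ynew);
      k1.swap(k7);
      double big = 0.0;
      for (int i = 0; i < n_state; ++i) big = std::max(big, std::fabs(y[i]));
      if (big > 1e10) return false;  // blow-up guard
      while (iout < n_out && t >= t_out[iout] - 1e-12) {
        for (int i = 0; i < n_state; ++i)
          out[(size_t)iout * n_state + i] = y[i];
        ++iout;
      }
      if (iout >= n_out) return true;
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      if (!clipped) h = h_try * fac;
      else h = std::max(h, h_try * fac);
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
      h = h_try * fac;
      if (h < 1e-14) return false;
    }
  }
  return iout >= n_out;
}

//' @noRd
// [[Rcpp::export(name = ".rf_integrate")]]
List rf_integrate(NumericMatrix A, double alpha, NumericVector beta,
                  NumericVector gamma, NumericVector y0, NumericVector times,
                  int model, double rtol, double atol,
                  int max_steps = 500000) {
  int N = A.nrow();
  int n_state = (model == 2) ? 2 * N : N;
  if ((int)y0.size() != n_state) stop("state vector has wrong length");
  int n_out = times.size();
  NumericMatrix out(n_state, n_out);
  LinOp op;
  op.dense = REAL(A);
  op.N = N;
  bool ok = rf_solve(op, N, alpha,
                     beta.size() ? REAL(beta) : nullptr,
                     gamma.size() ? REAL(gamma) : nullptr, model, REAL(y0),
                     n_state, REAL(times), n_out, rtol, atol, max_steps,
                     REAL(out));
  return List::create(_["y"] = out, _["success"] = ok);
}

// ---------------------------------------------------------------------------
// Parameter block layout (natural scale):
//   [rho_1..rho_K, (alpha), u0, sigma, (beta_1..beta_N), (gamma_1..gamma_N)]
// with alpha/beta present for models 1-2 and gamma for model 2.
// `positive[j]` flags log-transformed coordinates; priors are Normal or
// zero-truncated Normal per coordinate.

struct RfProblem {
  int model, N, K;  // K = number of transport operators (1 or 2)
  std::vector<const double*> L;  // Laplacians, column-major N x N
  std::vector<int> seeds;        // 0-based
  const double* y;               // observations
  const int* reg;                // 0-based region index per obs
  const int* tix;                // 0-based time index per obs
  int M;                         // number of observations
  const double* t_out;
  int n_out;
  double rtol, atol;
  const double* pr_mu;
  const double* pr_sd;
  const int* pr_trunc;  // 1 = truncated to (0, inf)
  const int* positive;  // 1 = sampled on log scale
  int P;
  // sparse pattern of the (union of) Laplacian(s), fixed per problem
  std::vector<int> nz_r, nz_c;
  std::vector<std::vector<double>> nz_L;  // per-operator values
  mutable std::vector<double> nz_val, y0buf, solbuf;
};

// Simulate and fill predicted value per observation; returns false on failure.
static bool rf_predict(const RfProblem& pb, const double* th, double* pred) {
  int N = pb.N, K = pb.K;
  double alpha = (pb.model >= 1) ? th[K] : 0.0;
  const double* beta = (pb.model >= 1) ? th + K + 3 : nullptr;
  const double* gamma = (pb.model == 2) ? th + K + 3 + N : nullptr;
  double u0 = (pb.model >= 1) ? th[K + 1] : th[K];
  const int nnz = (int)pb.nz_r.size();
  pb.nz_val.assign(nnz, 0.0);
  for (int k = 0; k < K; ++k) {
    const double rho = th[k];
    const double* Lv = pb.nz_L[k].data();
    for (int e = 0; e < nnz; ++e) pb.nz_val[e] -= rho * Lv[e];
  }
  LinOp op;
  op.N = N;
  op.ri = pb.nz_r.data();
  op.ci = pb.nz_c.data();
  op.val = pb.nz_val.data();
  op.nnz = nnz;
  int n_state = (pb.model == 2) ? 2 * N : N;
  pb.y0buf.assign(n_state, 0.0);
  for (int s : pb.seeds) pb.y0buf[s] = u0;
  if (pb.model == 2)
    for (int i = 0; i < N; ++i) pb.y0buf[N + i] = beta[i];
  pb.solbuf.assign((size_t)n_state * pb.n_out, 0.0);
  bool ok = rf_solve(op, N, alpha, beta, gamma, pb.model,
                     pb.y0buf.data(), n_state, pb.t_out, pb.n_out, pb.rtol,
                     pb.atol, 200000, pb.solbuf.data());
  if (!ok) return false;
  for (int m = 0; m < pb.M; ++m)
    pred[m] = pb.solbuf[(size_t)pb.tix[m] * n_state + pb.reg[m]];
  return true;
}

static double rf_logprior(const RfProblem& pb, const double* th) {
  double lp = 0.0;
  for (int j = 0; j < pb.P; ++j) {
    double mu = pb.pr_mu[j], sd = pb.pr_sd[j];
    if (pb.pr_trunc[j]) {
      if (th[j] <= 0) return R_NegInf;
      lp += R::dnorm(th[j], mu, sd, 1) -
            R::pnorm(0.0, mu, sd, 0, 1);  // log P(X > 0)
    } else {
      lp += R::dnorm(th[j], mu, sd, 1);
    }
  }
  return lp;
}

static double rf_loglik_from_pred(const RfProblem& pb, const double* pred,
                                  double sigma, double* pointwise) {
  double ll = 0.0;
  for (int m = 0; m < pb.M; ++m) {
    double l = R::dnorm(pb.y[m], pred[m], sigma, 1);
    if (pointwise) pointwise[m] = l;
    ll += l;
  }
  return ll;
}

static RfProblem rf_make_problem(int model, List Ls, IntegerVector seeds,
                                 NumericVector y, IntegerVector reg,
                                 IntegerVector tix, NumericVector t_out,
                                 double rtol, double atol, NumericVector pr_mu,
                                 NumericVector pr_sd, IntegerVector pr_trunc,
                                 IntegerVector positive) {
  RfProblem pb;
  pb.model = model;
  pb.K = Ls.size();
  NumericMatrix L0 = Ls[0];
  pb.N = L0.nrow();
  for (int k = 0; k < pb.K; ++k) {
    NumericMatrix Lk = Ls[k];
    pb.L.push_back(REAL(Lk));
  }
  // union sparsity pattern across operators
  for (int j = 0; j < pb.N; ++j) {
    for (int i = 0; i < pb.N; ++i) {
      bool nz = false;
      for (int k = 0; k < pb.K; ++k)
        if (pb.L[k][(size_t)j * pb.N + i] != 0.0) { nz = true; break; }
      if (nz) {
        pb.nz_r.push_back(i);
        pb.nz_c.push_back(j);
      }
    }
  }
  pb.nz_L.resize(pb.K);
  for (int k = 0; k < pb.K; ++k) {
    pb.nz_L[k].resize(pb.nz_r.size());
    for (size_t e = 0; e < pb.nz_r.size(); ++e)
      pb.nz_L[k][e] = pb.L[k][(size_t)pb.nz_c[e] * pb.N + pb.nz_r[e]];
  }
  pb.seeds = as<std::vector<int>>(seeds);
  pb.y = REAL(y);
  pb.reg = INTEGER(reg);
  pb.tix = INTEGER(tix);
  pb.M = y.size();
  pb.t_out = REAL(t_out);
  pb.n_out = t_out.size();
  pb.rtol = rtol;
  pb.atol = atol;
  pb.pr_mu = REAL(pr_mu);
  pb.pr_sd = REAL(pr_sd);
  pb.pr_trunc = INTEGER(pr_trunc);
  pb.positive = INTEGER(positive);
  pb.P = pr_mu.size();
  return pb;
}

//' @noRd
// [[Rcpp::export(name = ".rf_logpost")]]
List rf_logpost(NumericVector theta, int model, List Ls, IntegerVector seeds,
                NumericVector y, IntegerVector reg, IntegerVector tix,
                NumericVector t_out, double rtol, double atol,
                NumericVector pr_mu, NumericVector pr_sd,
                IntegerVector pr_trunc, IntegerVector positive) {
  RfProblem pb = rf_make_problem(model, Ls, seeds, y, reg, tix, t_out, rtol,
                                 atol, pr_mu, pr_sd, pr_trunc, positive);
  if ((int)theta.size() != pb.P) stop("theta has wrong length");
  double lp = rf_logprior(pb, REAL(theta));
  NumericVector pw(pb.M);
  double ll = R_NegInf;
  if (std::isfinite(lp) && pb.M > 0) {
    std::vector<double> pred(pb.M);
    if (rf_predict(pb, REAL(theta), pred.data())) {
      int sig_ix = (model >= 1) ? pb.K + 2 : pb.K + 1;
      ll = rf_loglik_from_pred(pb, pred.data(), theta[sig_ix], REAL(pw));
    }
  } else if (pb.M == 0) {
    ll = 0.0;
  }
  return List::create(_["logprior"] = lp, _["loglik"] = ll,
                      _["pointwise"] = pw);
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis-within-Gibbs, one chain. Coordinates with positive
// support are updated on the log scale (Jacobian included). Proposal scales
// adapt in batches of 50 toward 44% acceptance during warmup only.
//' @noRd
// [[Rcpp::export(name = ".rf_mwg_chain")]]
List rf_mwg_chain(NumericVector theta0, int model, List Ls, IntegerVector seeds,
                  NumericVector y, IntegerVector reg, IntegerVector tix,
                  NumericVector t_out, double rtol, double atol,
                  NumericVector pr_mu, NumericVector pr_sd,
                  IntegerVector pr_trunc, IntegerVector positive, int warmup,
                  int n_keep, int thin, double target_accept,
                  NumericVector init_log_scale) {
  RfProblem pb = rf_make_problem(model, Ls, seeds, y, reg, tix, t_out, rtol,
                                 atol, pr_mu, pr_sd, pr_trunc, positive);
  const int P = pb.P, M = pb.M;
  if ((int)theta0.size() != P) stop("theta0 has wrong length");
  const int sig_ix = (model >= 1) ? pb.K + 2 : pb.K + 1;
  std::vector<double> th(REAL(theta0), REAL(theta0) + P);
  std::vector<double> x(P);  // transformed
  for (int j = 0; j < P; ++j)
    x[j] = pb.positive[j] ? std::log(th[j]) : th[j];
  std::vector<double> log_s(P, 0.0);
  if (init_log_scale.size() == P)
    for (int j = 0; j < P; ++j) log_s[j] = init_log_scale[j];

  auto logjac = [&](const std::vector<double>& xx) {
    double lj = 0.0;
    for (int j = 0; j < P; ++j)
      if (pb.positive[j]) lj += xx[j];
    return lj;
  };

  std::vector<double> pred(std::max(M, 1)), pred_prop(std::max(M, 1));
  double lp = rf_logprior(pb, th.data());
  double ll;
  bool have_pred = false;
  if (M == 0) {
    ll = 0.0;
  } else if (std::isfinite(lp) && rf_predict(pb, th.data(), pred.data())) {
    ll = rf_loglik_from_pred(pb, pred.data(), th[sig_ix], nullptr);
    have_pred = true;
  } else {
    ll = R_NegInf;
  }
  if (!std::isfinite(lp + ll))
    stop("initial parameter value has zero posterior density");
  double lpost = lp + ll + logjac(x);

  const int n_iter = warmup + n_keep * thin;
  NumericMatrix draws(n_keep, P);
  NumericMatrix pw(n_keep, std::max(M, 0));
  NumericVector keep_ll(n_keep), keep_lp(n_keep);
  std::vector<int> batch_acc(P, 0);
  std::vector<long> total_acc(P, 0);
  int batch_n = 0, batch_id = 1, kept = 0;
  double log_ridge = -1.0;
  int ridge_acc = 0;
  // adaptive multivariate block over the global parameters (rates, seed
  // value, noise scale), which share a slow likelihood ridge
  const int G = (model >= 1) ? pb.K + 3 : pb.K + 2;
  std::vector<double> g_mean(G, 0.0), g_cov((size_t)G * G, 0.0);
  std::vector<double> g_chol((size_t)G * G, 0.0);
  long g_n = 0;
  double log_gscale = -1.0;
  int block_acc = 0;
  auto update_gmoments = [&]() {
    ++g_n;
    for (int a = 0; a < G; ++a) {
      double d = x[a] - g_mean[a];
      g_mean[a] += d / g_n;
      for (int b = 0; b <= a; ++b)
        g_cov[(size_t)a * G + b] += d * (x[b] - g_mean[b]);
    }
  };
  auto refresh_chol = [&]() {
    // Cholesky of cov/(n-1) + eps I (lower triangular)
    std::vector<double> C((size_t)G * G, 0.0);
    for (int a = 0; a < G; ++a)
      for (int b = 0; b <= a; ++b) {
        double v = g_cov[(size_t)a * G + b] / std::max(g_n - 1L, 1L);
        C[(size_t)a * G + b] = v;
        C[(size_t)b * G + a] = v;
      }
    for (int a = 0; a < G; ++a) C[(size_t)a * G + a] += 1e-8;
    for (int a = 0; a < G; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = C[(size_t)a * G + b];
        for (int k = 0; k < b; ++k)
          s -= g_chol[(size_t)a * G + k] * g_chol[(size_t)b * G + k];
        if (a == b) g_chol[(size_t)a * G + a] = std::sqrt(std::max(s, 1e-12));
        else g_chol[(size_t)a * G + b] = s / g_chol[(size_t)b * G + b];
      }
      for (int b = a + 1; b < G; ++b) g_chol[(size_t)a * G + b] = 0.0;
    }
  };

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < P; ++j) {
      double xj_old = x[j], th_old = th[j];
      double prop = xj_old + std::exp(log_s[j]) * norm_rand();
      x[j] = prop;
      th[j] = pb.positive[j] ? std::exp(prop) : prop;
      double lp_new = rf_logprior(pb, th.data());
      double ll_new;
      bool pred_valid = false;
      if (!std::isfinite(lp_new)) {
        ll_new = R_NegInf;
      } else if (M == 0) {
        ll_new = 0.0;
      } else if (j == sig_ix && have_pred) {
        // sigma does not change the trajectory
        ll_new = rf_loglik_from_pred(pb, pred.data(), th[sig_ix], nullptr);
      } else if (rf_predict(pb, th.data(), pred_prop.data())) {
        ll_new = rf_loglik_from_pred(pb, pred_prop.data(), th[sig_ix], nullptr);
        pred_valid = true;
      } else {
        ll_new = R_NegInf;
      }
      double lpost_new = lp_new + ll_new + logjac(x);
      if (std::isfinite(lpost_new) &&
          std::log(unif_rand()) < lpost_new - lpost) {
        lpost = lpost_new;
        lp = lp_new;
        ll = ll_new;
        if (pred_valid) { pred.swap(pred_prop); have_pred = true; }
        ++batch_acc[j];
        ++total_acc[j];
      } else {
        x[j] = xj_old;
        th[j] = th_old;
      }
    }
    if (it < warmup) {
      update_gmoments();
      if (g_n >= 100 && (g_n % 100 == 0)) refresh_chol();
    }
    if (g_n >= 200) {
      // joint proposal over the global block along its empirical covariance
      double sc = 2.38 / std::sqrt((double)G) * std::exp(log_gscale);
      std::vector<double> z(G);
      for (int a = 0; a < G; ++a) z[a] = norm_rand();
      std::vector<double> x_old(x), th_old(th);
      for (int a = 0; a < G; ++a) {
        double step = 0.0;
        for (int b = 0; b <= a; ++b)
          step += g_chol[(size_t)a * G + b] * z[b];
        x[a] += sc * step;
        th[a] = pb.positive[a] ? std::exp(x[a]) : x[a];
      }
      double lp_new = rf_logprior(pb, th.data());
      double ll_new = R_NegInf;
      bool pred_valid = false;
      if (std::isfinite(lp_new)) {
        if (M == 0) ll_new = 0.0;
        else if (rf_predict(pb, th.data(), pred_prop.data())) {
          ll_new = rf_loglik_from_pred(pb, pred_prop.data(), th[sig_ix],
                                       nullptr);
          pred_valid = true;
        }
      }
      double lpost_new = lp_new + ll_new + logjac(x);
      if (std::isfinite(lpost_new) &&
          std::log(unif_rand()) < lpost_new - lpost) {
        lpost = lpost_new;
        lp = lp_new;
        ll = ll_new;
        if (pred_valid) { pred.swap(pred_prop); have_pred = true; }
        ++block_acc;
      } else {
        x.swap(x_old);
        th.swap(th_old);
      }
    }
    // Ridge move for DIFF_RF: alpha and the carrying capacities are only
    // jointly constrained before trajectories saturate, leaving a
    // log-alpha + log-beta ridge that coordinate updates traverse slowly.
    // Propose a correlated shift along it (volume-preserving in x-space).
    if (model == 2) {
      double d = std::exp(log_ridge) * norm_rand();
      int a_ix = pb.K;
      std::vector<double> x_old(x), th_old(th);
      x[a_ix] += d;
      th[a_ix] = std::exp(x[a_ix]);
      for (int j = pb.K + 3; j < pb.K + 3 + pb.N; ++j) {
        x[j] -= d;
        th[j] = std::exp(x[j]);
      }
      double lp_new = rf_logprior(pb, th.data());
      double ll_new = R_NegInf;
      bool pred_valid = false;
      if (std::isfinite(lp_new)) {
        if (M == 0) ll_new = 0.0;
        else if (rf_predict(pb, th.data(), pred_prop.data())) {
          ll_new = rf_loglik_from_pred(pb, pred_prop.data(), th[sig_ix],
                                       nullptr);
          pred_valid = true;
        }
      }
      double lpost_new = lp_new + ll_new + logjac(x);
      if (std::isfinite(lpost_new) &&
          std::log(unif_rand()) < lpost_new - lpost) {
        lpost = lpost_new;
        lp = lp_new;
        ll = ll_new;
        if (pred_valid) { pred.swap(pred_prop); have_pred = true; }
        ++ridge_acc;
      } else {
        x.swap(x_old);
        th.swap(th_old);
      }
    }
    ++batch_n;
    if (it < warmup && batch_n == 50) {
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_id));
      for (int j = 0; j < P; ++j) {
        if (batch_acc[j] > target_accept * 50) log_s[j] += delta;
        else log_s[j] -= delta;
        batch_acc[j] = 0;
      }
      if (model == 2) {
        if (ridge_acc > target_accept * 50) log_ridge += delta;
        else log_ridge -= delta;
        ridge_acc = 0;
      }
      if (block_acc > 0.28 * 50) log_gscale += delta;
      else log_gscale -= delta;
      block_acc = 0;
      batch_n = 0;
      ++batch_id;
    }
    if (it >= warmup && ((it - warmup + 1) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < P; ++j) draws(kept, j) = th[j];
      keep_ll[kept] = ll;
      keep_lp[kept] = lp;
      if (M > 0) {
        if (!have_pred) rf_predict(pb, th.data(), pred.data());
        std::vector<double> pwrow(M);
        rf_loglik_from_pred(pb, pred.data(), th[sig_ix], pwrow.data());
        for (int m = 0; m < M; ++m) pw(kept, m) = pwrow[m];
      }
      ++kept;
    }
  }
  PutRNGstate();
  NumericVector acc(P), lsv(P);
  for (int j = 0; j < P; ++j) {
    acc[j] = (double)total_acc[j] / n_iter;
    lsv[j] = log_s[j];
  }
  return List::create(_["draws"] = draws, _["loglik_pointwise"] = pw,
                      _["loglik"] = keep_ll, _["logprior"] = keep_lp,
                      _["accept_rate"] = acc, _["log_scale"] = lsv);
}
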
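#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-compartment kinetics with zero-order (infusion) input, solved in closed
// form by superposition over dose events.  All gradients are with respect to
// (log CL, log V), the scale on which the subject-level random effects act.

static const double LOG2PI = 1.8378770664093453;
static const double PRED_FLOOR = 1e-6; // mg/L; keeps the proportional-error
                                       // variance away from zero

// concentration and its gradient wrt (log cl, log v) at a single time
static inline void conc_fg(double t,
                           const double* st, const double* rt, const double* du,
                           int ne, double cl, double v,
                           double& f, double& glc, double& glv) {
  double ke = cl / v;
  f = 0.0; glc = 0.0; glv = 0.0;
  for (int e = 0; e < ne; ++e) {
    double tau = t - st[e];
    if (tau <= 0.0) continue;
    double t1 = tau < du[e] ? tau : du[e];
    double t2 = tau - du[e]; if (t2 < 0.0) t2 = 0.0;
    double A  = rt[e] / cl;
    double E1m = std::exp(-ke * t1);   // e^{-ke t1}
    double E2  = std::exp(-ke * t2);
    double c   = A * (1.0 - E1m) * E2;
    // d c / d log ke
    double dk  = A * ke * (t1 * E1m * E2 - t2 * (1.0 - E1m) * E2);
    f   += c;
    glc += -c + dk;   // cl scales A by 1/s and ke by s
    glv += -dk;       // v scales ke by 1/s
  }
}

struct Subj {
  const double* t;  const double* y;  int n;
  const double* st; const double* rt; const double* du; int ne;
  const double* clt; const double* vt; // typical (covariate-scaled) CL, V per obs
};

// -log joint density of (y, eta) up to nothing (all constants kept), with
// analytic gradient wrt eta = (log-scale deviations on CL and V).
static double nll_fg(const Subj& S, const double* eta,
                     double o2cl, double o2v, double s2,
                     bool a1, bool a2, double* g, bool want_g = true) {
  double ex1 = std::exp(eta[0]), ex2 = std::exp(eta[1]);
  double nll = 0.0, g1 = 0.0, g2 = 0.0;
  for (int j = 0; j < S.n; ++j) {
    double cl = S.clt[j] * ex1;
    double v  = S.vt[j]  * ex2;
    double f, glc, glv;
    conc_fg(S.t[j], S.st, S.rt, S.du, S.ne, cl, v, f, glc, glv);
    if (f < PRED_FLOOR) { f = PRED_FLOOR; glc = 0.0; glv = 0.0; }
    double r  = S.y[j] - f;
    double f2 = f * f;
    nll += 0.5 * (r * r / (s2 * f2) + std::log(s2 * f2) + LOG2PI);
    if (want_g) {
      double w = -r / (s2 * f2) - r * r / (s2 * f2 * f) + 1.0 / f;
      g1 += w * glc;
      g2 += w * glv;
    }
  }
  if (a1) { nll += 0.5 * (eta[0] * eta[0] / o2cl + std::log(o2cl) + LOG2PI); g1 += eta[0] / o2cl; }
  if (a2) { nll += 0.5 * (eta[1] * eta[1] / o2v  + std::log(o2v)  + LOG2PI); g2 += eta[1] / o2v; }
  g[0] = g1; g[1] = g2;
  return nll;
}

// numeric Hessian (central differences of the analytic gradient) on the
// active dimensions; H stored row-major 2x2 with inactive rows/cols = identity
static void num_hess(const Subj& S, const double* eta,
                     double o2cl, double o2v, double s2,
                     bool a1, bool a2, double* H) {
  const double h = 1e-4;
  double gp[2], gm[2], e[2];
  H[0] = H[3] = 1.0; H[1] = H[2] = 0.0;
  bool act[2] = {a1, a2};
  for (int i = 0; i < 2; ++i) {
    if (!act[i]) continue;
    e[0] = eta[0]; e[1] = eta[1];
    e[i] = eta[i] + h; nll_fg(S, e, o2cl, o2v, s2, a1, a2, gp);
    e[i] = eta[i] - h; nll_fg(S, e, o2cl, o2v, s2, a1, a2, gm);
    for (int j = 0; j < 2; ++j)
      if (act[j]) H[2 * i + j] = (gp[j] - gm[j]) / (2.0 * h);
  }
  // symmetrize
  if (a1 && a2) { double m = 0.5 * (H[1] + H[2]); H[1] = H[2] = m; }
}

// one damped-Newton run from a given start; returns nll at the point
// reached, with `gnorm` the final gradient norm
static double newton_run(const Subj& S, double o2cl, double o2v, double s2,
                         bool a1, bool a2, double* eta, double& gnorm) {
  double g[2], H[4];
  double nll = nll_fg(S, eta, o2cl, o2v, s2, a1, a2, g);
  for (int it = 0; it < 80; ++it) {
    double gn = 0.0;
    if (a1) gn += g[0] * g[0];
    if (a2) gn += g[1] * g[1];
    gn = std::sqrt(gn);
    if (gn < 1e-8) break;
    num_hess(S, eta, o2cl, o2v, s2, a1, a2, H);
    // ridge until positive definite on active block
    double ridge = 0.0;
    for (int k = 0; k < 40; ++k) {
      double h00 = H[0] + (a1 ? ridge : 0.0), h11 = H[3] + (a2 ? ridge : 0.0);
      double det = h00 * h11 - H[1] * H[2];
      bool pd = a1 && a2 ? (h00 > 1e-12 && det > 1e-12)
                         : (a1 ? h00 > 1e-12 : h11 > 1e-12);
      if (pd) break;
      ridge = ridge == 0.0 ? 1e-4 : ridge * 10.0;
    }
    double h00 = H[0] + (a1 ? ridge : 0.0), h11 = H[3] + (a2 ? ridge : 0.0);
    double s0 = 0.0, s1 = 0.0;
    if (a1 && a2) {
      double det = h00 * h11 - H[1] * H[2];
      s0 = -( h11 * g[0] - H[1] * g[1]) / det;
      s1 = -(-H[2] * g[0] + h00 * g[1]) / det;
    } else if (a1) s0 = -g[0] / h00;
    else           s1 = -g[1] / h11;
    // cap the step length (trust region) to keep the line search sane
    double sn = std::sqrt(s0 * s0 + s1 * s1);
    if (sn > 3.0) { s0 *= 3.0 / sn; s1 *= 3.0 / sn; }
    bool moved = false;
    for (int pass = 0; pass < 2 && !moved; ++pass) {
      if (pass == 1) { // steepest-descent fallback
        double sc = 1.0 / std::max(gn, 1.0);
        s0 = a1 ? -g[0] * sc : 0.0;
        s1 = a2 ? -g[1] * sc : 0.0;
      }
      double lam = 1.0;
      for (int ls = 0; ls < 22; ++ls) {
        double e[2] = {eta[0] + lam * s0, eta[1] + lam * s1};
        if (e[0] > 20.0) e[0] = 20.0; if (e[0] < -20.0) e[0] = -20.0;
        if (e[1] > 20.0) e[1] = 20.0; if (e[1] < -20.0) e[1] = -20.0;
        double gt[2];
        double nt = nll_fg(S, e, o2cl, o2v, s2, a1, a2, gt);
        if (R_finite(nt) && nt < nll - 1e-13) {
          eta[0] = e[0]; eta[1] = e[1];
          nll = nt; g[0] = gt[0]; g[1] = gt[1];
          moved = true; break;
        }
        lam *= 0.5;
      }
    }
    if (!moved) break;
  }
  gnorm = 0.0;
  if (a1) gnorm += g[0] * g[0];
  if (a2) gnorm += g[1] * g[1];
  gnorm = std::sqrt(gnorm);
  return nll;
}

// inner optimisation.  The joint density over eta can be multimodal for
// sparse subjects, and a path-dependent warm start would make the outer
// objective discontinuous; so the Newton basin is chosen deterministically
// by a coarse grid scan over the prior range (warm start included as one
// candidate, used only when it matches the grid winner's basin value).
static double inner_solve(const Subj& S, double o2cl, double o2v, double s2,
                          bool a1, bool a2, double* eta, double* H, bool& ok) {
  ok = true;
  if (!a1) eta[0] = 0.0;
  if (!a2) eta[1] = 0.0;
  if (!a1 && !a2) {
    double g[2];
    double nll = nll_fg(S, eta, o2cl, o2v, s2, a1, a2, g);
    H[0] = H[3] = 1.0; H[1] = H[2] = 0.0;
    return nll;
  }
  static const double qs[5] = {-2.0, -1.0, 0.0, 1.0, 2.0};
  double s1 = a1 ? std::max(std::sqrt(o2cl), 0.15) : 0.0;
  double s2d = a2 ? std::max(std::sqrt(o2v), 0.15) : 0.0;
  double cand[26][2]; int nc = 0;
  cand[nc][0] = eta[0]; cand[nc][1] = eta[1]; ++nc; // warm start
  if (a1 && a2) {
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j) {
        cand[nc][0] = qs[i] * s1; cand[nc][1] = qs[j] * s2d; ++nc;
      }
  } else {
    for (int i = 0; i < 5; ++i) {
      cand[nc][0] = a1 ? qs[i] * s1 : 0.0;
      cand[nc][1] = a2 ? qs[i] * s2d : 0.0; ++nc;
    }
  }
  double g[2], val[26];
  int gbest = -1; // best grid candidate (excluding the warm start)
  for (int c = 0; c < nc; ++c) {
    val[c] = nll_fg(S, cand[c], o2cl, o2v, s2, a1, a2, g, false);
    if (c > 0 && R_finite(val[c]) && (gbest < 0 || val[c] < val[gbest]))
      gbest = c;
  }
  // always polish from the best grid point (path-independent backbone)
  double etg[2] = {cand[gbest][0], cand[gbest][1]};
  double gng;
  double nll = newton_run(S, o2cl, o2v, s2, a1, a2, etg, gng);
  double gnorm = gng;
  eta[0] = etg[0]; eta[1] = etg[1];
  // the warm start additionally seeds a Newton run when it beats the grid
  if (R_finite(val[0]) && val[0] < val[gbest]) {
    double etw[2] = {cand[0][0], cand[0][1]};
    double gnw;
    double nw = newton_run(S, o2cl, o2v, s2, a1, a2, etw, gnw);
    if (nw < nll - 1e-12) {
      nll = nw; gnorm = gnw; eta[0] = etw[0]; eta[1] = etw[1];
    }
  }
  if (gnorm > 1e-4) ok = false;
  num_hess(S, eta, o2cl, o2v, s2, a1, a2, H);
  return nll;
}

static Subj make_subj(int i, const NumericVector& obs_t, const NumericVector& dv,
                      const IntegerVector& obs_off,
                      const NumericVector& d_st, const NumericVector& d_rt,
                      const NumericVector& d_du, const IntegerVector& dose_off,
                      const NumericVector& clt, const NumericVector& vt) {
  Subj S;
  int o0 = obs_off[i], o1 = obs_off[i + 1];
  int k0 = dose_off[i], k1 = dose_off[i + 1];
  S.t = &obs_t[0] + o0;  S.y = &dv[0] + o0;  S.n = o1 - o0;
  S.st = &d_st[0] + k0;  S.rt = &d_rt[0] + k0; S.du = &d_du[0] + k0; S.ne = k1 - k0;
  S.clt = &clt[0] + o0;  S.vt = &vt[0] + o0;
  return S;
}

//' @noRd
// [[Rcpp::export]]
List ofv_laplace_cpp(NumericVector obs_t, NumericVector dv, IntegerVector obs_off,
                     NumericVector d_st, NumericVector d_rt, NumericVector d_du,
                     IntegerVector dose_off,
                     NumericVector clt, NumericVector vt,
                     double o2cl, double o2v, double s2,
                     NumericMatrix eta_start) {
  int nsub = obs_off.size() - 1;
  bool a1 = o2cl > 0.0, a2 = o2v > 0.0;
  NumericMatrix eta(nsub, 2);
  NumericMatrix hess(nsub, 4);
  double ofv = 0.0; int nflag = 0;
  for (int i = 0; i < nsub; ++i) {
    Subj S = make_subj(i, obs_t, dv, obs_off, d_st, d_rt, d_du, dose_off, clt, vt);
    double et[2] = {eta_start(i, 0), eta_start(i, 1)};
    double H[4]; bool ok;
    double nll = inner_solve(S, o2cl, o2v, s2, a1, a2, et, H, ok);
    int d = (a1 ? 1 : 0) + (a2 ? 1 : 0);
    double logdet = 0.0;
    if (d == 2) {
      double det = H[0] * H[3] - H[1] * H[2];
      if (det <= 1e-12 || H[0] <= 1e-12) { // regularise, flag
        double r = 1e-6;
        while ((H[0] + r) * (H[3] + r) - H[1] * H[2] <= 1e-12 && r < 1e3) r *= 10.0;
        logdet = std::log((H[0] + r) * (H[3] + r) - H[1] * H[2]);
        ++nflag;
      } else logdet = std::log(det);
    } else if (d == 1) {
      double h = a1 ? H[0] : H[3];
      if (h <= 1e-12) { h = 1e-12; ++nflag; }
      logdet = std::log(h);
    }
    ofv += 2.0 * nll + logdet - d * LOG2PI;
    eta(i, 0) = et[0]; eta(i, 1) = et[1];
    for (int k = 0; k < 4; ++k) hess(i, k) = H[k];
  }
  return List::create(_["ofv"] = ofv, _["eta"] = eta,
                      _["hess"] = hess, _["nflag"] = nflag);
}

//' @noRd
// [[Rcpp::export]]
NumericVector conc_cpp(NumericVector times, NumericVector st, NumericVector rt,
                       NumericVector du, double cl, double v) {
  int n = times.size(), ne = st.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double f, a, b;
    conc_fg(times[j], ne ? &st[0] : nullptr, ne ? &rt[0] : nullptr,
            ne ? &du[0] : nullptr, ne, cl, v, f, a, b);
    out[j] = f;
  }
  return out;
}

// predictions and Jacobian wrt (eta_cl, eta_v) with per-observation typical
// parameters (time-varying covariates) at a given eta
//' @noRd
// [[Rcpp::export]]
List pred_jac_cpp(NumericVector obs_t, NumericVector st, NumericVector rt,
                  NumericVector du, NumericVector clt, NumericVector vt,
                  double eta_cl, double eta_v) {
  int n = obs_t.size(), ne = st.size();
  NumericVector f(n); NumericMatrix J(n, 2);
  double e1 = std::exp(eta_cl), e2 = std::exp(eta_v);
  for (int j = 0; j < n; ++j) {
    double fj, glc, glv;
    conc_fg(obs_t[j], ne ? &st[0] : nullptr, ne ? &rt[0] : nullptr,
            ne ? &du[0] : nullptr, ne, clt[j] * e1, vt[j] * e2, fj, glc, glv);
    f[j] = fj; J(j, 0) = glc; J(j, 1) = glv;
  }
  return List::create(_["f"] = f, _["J"] = J);
}

// bulk simulation of model predictions for K replicate eta draws
//' @noRd
// [[Rcpp::export]]
NumericMatrix pred_bulk_cpp(NumericVector obs_t, IntegerVector obs_off,
                            NumericVector d_st, NumericVector d_rt,
                            NumericVector d_du, IntegerVector dose_off,
                            NumericVector clt, NumericVector vt,
                            NumericMatrix eta_cl, NumericMatrix eta_v) {
  int nsub = obs_off.size() - 1, K = eta_cl.ncol(), nobs = obs_t.size();
  NumericMatrix out(nobs, K);
  for (int i = 0; i < nsub; ++i) {
    int o0 = obs_off[i], o1 = obs_off[i + 1];
    int k0 = dose_off[i], k1 = dose_off[i + 1];
    int ne = k1 - k0;
    for (int k = 0; k < K; ++k) {
      double e1 = std::exp(eta_cl(i, k)), e2 = std::exp(eta_v(i, k));
      for (int j = o0; j < o1; ++j) {
        double fj, a, b;
        conc_fg(obs_t[j], ne ? &d_st[k0] : nullptr, ne ? &d_rt[k0] : nullptr,
                ne ? &d_du[k0] : nullptr, ne, clt[j] * e1, vt[j] * e2, fj, a, b);
        out(j, k) = fj;
      }
    }
  }
  return out;
}
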
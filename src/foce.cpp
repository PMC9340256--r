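// Compiled inner (empirical-Bayes) search for the one-compartment PK
// model: per-subject Levenberg-Marquardt damped Gauss-Newton on the
// FOCE-I penalized deviance, followed by an exact-Newton polish using a
// finite difference of the analytic gradient. Mirrors the generic R
// engine (foce_inner) exactly; the R path remains the reference for
// arbitrary model callbacks and the two are compared in the tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Design {
  // uniform multiple-dose observations
  std::vector<int> ui, usub;
  std::vector<double> uk, us, utau, uamt;
  // irregular-history superposition pairs
  std::vector<int> pobs, psub;
  std::vector<double> pdt, pamt;
  int n_obs, n_sub;
  std::vector<double> y;
  std::vector<int> obs_sub;      // 0-based
  std::vector<double> cl_base, v_base;
  double ka;
};

// predictions and (optionally) d f / d(log cl, log v) at eta
void model_eval(const Design& D, const std::vector<double>& eta1,
                const std::vector<double>& eta2, bool deriv,
                std::vector<double>& f, std::vector<double>& J1,
                std::vector<double>& J2) {
  std::fill(f.begin(), f.end(), 0.0);
  if (deriv) {
    std::fill(J1.begin(), J1.end(), 0.0);
    std::fill(J2.begin(), J2.end(), 0.0);
  }
  const double ka = D.ka;
  std::vector<double> cl(D.n_sub), v(D.n_sub), kes(D.n_sub);
  for (int i = 0; i < D.n_sub; ++i) {
    cl[i] = D.cl_base[i] * std::exp(eta1[i]);
    v[i] = D.v_base[i] * std::exp(eta2[i]);
    double ke = cl[i] / v[i];
    if (std::fabs(ka - ke) < 1e-9 * ka) ke = ka * (1.0 - 1e-9);
    kes[i] = ke;
  }
  for (size_t t = 0; t < D.ui.size(); ++t) {
    const int j = D.ui[t], i = D.usub[t];
    const double ke = kes[i];
    const double a = 1000.0 * D.uamt[t] / v[i];
    const double r = ka / (ka - ke);
    const double k = D.uk[t], s = D.us[t], tau = D.utau[t];
    const double xe = std::exp(-ke * tau);
    const double Se = (1.0 - std::pow(xe, k)) / (1.0 - xe);
    const double ees = std::exp(-ke * s);
    const double ue = ees * Se;
    const double xa = std::exp(-ka * tau);
    const double ua = std::exp(-ka * s) * (1.0 - std::pow(xa, k)) /
                      (1.0 - xa);
    const double cu = a * r * (ue - ua);
    f[j] = cu;
    if (deriv) {
      const double dSdx = (Se - k * std::pow(xe, k - 1.0)) / (1.0 - xe);
      const double due = -s * ue + ees * dSdx * (-tau * xe);
      const double dke = a * (r / (ka - ke) * (ue - ua) + r * due);
      J1[j] = dke * ke;
      J2[j] = -cu - dke * ke;
    }
  }
  for (size_t t = 0; t < D.pobs.size(); ++t) {
    const int j = D.pobs[t], i = D.psub[t];
    const double ke = kes[i];
    const double a = 1000.0 * D.pamt[t] / v[i];
    const double de = ka - ke;
    const double E1 = std::exp(-ke * D.pdt[t]);
    const double EA = std::exp(-ka * D.pdt[t]);
    const double r = ka / de;
    const double term = a * r * (E1 - EA);
    f[j] += term;
    if (deriv) {
      const double Tke = a * r * ((E1 - EA) / de - D.pdt[t] * E1);
      J1[j] += Tke * ke;
      J2[j] += -term - Tke * ke;
    }
  }
}

struct State {
  std::vector<double> f, J1, J2, obj, g1, g2, A11, A12, A22;
};

// penalized deviance, gradient and Gauss-Newton information per subject
void eval_full(const Design& D, const std::vector<double>& eta1,
               const std::vector<double>& eta2, double s2p, double s2a,
               bool interaction, const std::vector<double>& f0,
               const double Oi[3], State& st) {
  const int n = D.n_sub, m = D.n_obs;
  model_eval(D, eta1, eta2, true, st.f, st.J1, st.J2);
  std::fill(st.obj.begin(), st.obj.end(), 0.0);
  std::fill(st.g1.begin(), st.g1.end(), 0.0);
  std::fill(st.g2.begin(), st.g2.end(), 0.0);
  std::fill(st.A11.begin(), st.A11.end(), 0.0);
  std::fill(st.A12.begin(), st.A12.end(), 0.0);
  std::fill(st.A22.begin(), st.A22.end(), 0.0);
  for (int j = 0; j < m; ++j) {
    const int i = D.obs_sub[j];
    const double fj = st.f[j];
    const double fv = interaction ? fj : f0[j];
    double var = s2p * fv * fv + s2a;
    if (var < 1e-12) var = 1e-12;
    const double res = D.y[j] - fj;
    st.obj[i] += res * res / var + std::log(var);
    double w = -2.0 * res / var;
    if (interaction)
      w += -2.0 * s2p * fj * res * res / (var * var) +
           2.0 * s2p * fj / var;
    st.g1[i] += w * st.J1[j];
    st.g2[i] += w * st.J2[j];
    st.A11[i] += st.J1[j] * st.J1[j] / var;
    st.A12[i] += st.J1[j] * st.J2[j] / var;
    st.A22[i] += st.J2[j] * st.J2[j] / var;
  }
  for (int i = 0; i < n; ++i) {
    const double q1 = Oi[0] * eta1[i] + Oi[1] * eta2[i];
    const double q2 = Oi[1] * eta1[i] + Oi[2] * eta2[i];
    st.obj[i] += eta1[i] * q1 + eta2[i] * q2;
    st.g1[i] += 2.0 * q1;
    st.g2[i] += 2.0 * q2;
  }
}

void eval_obj(const Design& D, const std::vector<double>& eta1,
              const std::vector<double>& eta2, double s2p, double s2a,
              bool interaction, const std::vector<double>& f0,
              const double Oi[3], std::vector<double>& fbuf,
              std::vector<double>& obj) {
  std::vector<double> dum;
  model_eval(D, eta1, eta2, false, fbuf, dum, dum);
  std::fill(obj.begin(), obj.end(), 0.0);
  for (int j = 0; j < D.n_obs; ++j) {
    const int i = D.obs_sub[j];
    const double fv = interaction ? fbuf[j] : f0[j];
    double var = s2p * fv * fv + s2a;
    if (var < 1e-12) var = 1e-12;
    const double res = D.y[j] - fbuf[j];
    obj[i] += res * res / var + std::log(var);
  }
  for (int i = 0; i < D.n_sub; ++i) {
    const double q1 = Oi[0] * eta1[i] + Oi[1] * eta2[i];
    const double q2 = Oi[1] * eta1[i] + Oi[2] * eta2[i];
    obj[i] += eta1[i] * q1 + eta2[i] * q2;
  }
}

inline void solve2(double h11, double h12, double h22, double g1,
                   double g2, double& s1, double& s2) {
  double det = h11 * h22 - h12 * h12;
  if (det < 1e-300) det = 1e-300;
  s1 = (h22 * g1 - h12 * g2) / det;
  s2 = (h11 * g2 - h12 * g1) / det;
}

void run_phase(const Design& D, std::vector<double>& eta1,
               std::vector<double>& eta2, double s2p, double s2a,
               bool interaction, const std::vector<double>& f0,
               const double Oi[3], double gtol, int maxit, State& st,
               std::vector<double>& gn) {
  const int n = D.n_sub;
  eval_full(D, eta1, eta2, s2p, s2a, interaction, f0, Oi, st);
  std::vector<double> lam(n, 0.0), step1(n), step2(n), t(n);
  std::vector<double> c1(n), c2(n), n1(n), n2(n), objtry(n), fbuf(D.n_obs);
  std::vector<bool> frozen(n, false), ok(n), full(n);
  for (int it = 0; it < maxit; ++it) {
    bool all_done = true;
    for (int i = 0; i < n; ++i) {
      gn[i] = std::max(std::fabs(st.g1[i]), std::fabs(st.g2[i]));
      if (!(frozen[i] || gn[i] < gtol)) all_done = false;
    }
    if (all_done) break;
    for (int i = 0; i < n; ++i) {
      solve2(2.0 * (Oi[0] + st.A11[i]) + lam[i],
             2.0 * (Oi[1] + st.A12[i]),
             2.0 * (Oi[2] + st.A22[i]) + lam[i],
             st.g1[i], st.g2[i], step1[i], step2[i]);
      const bool done = frozen[i] || gn[i] < gtol;
      t[i] = done ? 0.0 : 1.0;
      ok[i] = done;
      full[i] = false;
      n1[i] = eta1[i];
      n2[i] = eta2[i];
    }
    for (int ls = 0; ls < 9; ++ls) {
      for (int i = 0; i < n; ++i) {
        if (ok[i]) { c1[i] = n1[i]; c2[i] = n2[i]; }
        else { c1[i] = eta1[i] - step1[i] * t[i];
               c2[i] = eta2[i] - step2[i] * t[i]; }
      }
      eval_obj(D, c1, c2, s2p, s2a, interaction, f0, Oi, fbuf, objtry);
      bool all_ok = true;
      for (int i = 0; i < n; ++i) {
        if (!ok[i] && objtry[i] <= st.obj[i] + 1e-10) {
          n1[i] = c1[i]; n2[i] = c2[i];
          full[i] = (ls == 0);
          ok[i] = true;
        }
        if (!ok[i]) { all_ok = false; t[i] *= 0.5; }
      }
      if (all_ok) break;
    }
    bool any_fail = false, moved = false;
    for (int i = 0; i < n; ++i) {
      if (!ok[i]) {
        any_fail = true;
        lam[i] = std::max(lam[i] * 10.0, 1.0);
        if (lam[i] > 1e8) frozen[i] = true;
      }
      if (full[i]) { lam[i] /= 10.0; if (lam[i] < 1e-8) lam[i] = 0.0; }
      if (n1[i] != eta1[i] || n2[i] != eta2[i]) moved = true;
      eta1[i] = n1[i];
      eta2[i] = n2[i];
    }
    if (!moved && !any_fail) break;
    eval_full(D, eta1, eta2, s2p, s2a, interaction, f0, Oi, st);
  }
  for (int i = 0; i < n; ++i)
    gn[i] = std::max(std::fabs(st.g1[i]), std::fabs(st.g2[i]));

  // exact-Newton polish on the analytic gradient norm
  bool need = false;
  for (int i = 0; i < n; ++i) if (gn[i] > 1e-11) { need = true; break; }
  if (need) {
    const double hh = 1e-5;
    State sp = st, sm = st;
    std::vector<double> e1p(eta1), e1m(eta1), e2p(eta2), e2m(eta2);
    for (int i = 0; i < n; ++i) {
      e1p[i] += hh;
      e1m[i] -= hh;
      e2p[i] += hh;
      e2m[i] -= hh;
    }
    eval_full(D, e1p, eta2, s2p, s2a, interaction, f0, Oi, sp);
    eval_full(D, e1m, eta2, s2p, s2a, interaction, f0, Oi, sm);
    std::vector<double> th11(n), th12a(n), th12b(n), th22(n);
    for (int i = 0; i < n; ++i) {
      th11[i] = (sp.g1[i] - sm.g1[i]) / (2 * hh);
      th12a[i] = (sp.g2[i] - sm.g2[i]) / (2 * hh);
    }
    eval_full(D, eta1, e2p, s2p, s2a, interaction, f0, Oi, sp);
    eval_full(D, eta1, e2m, s2p, s2a, interaction, f0, Oi, sm);
    for (int i = 0; i < n; ++i) {
      th12b[i] = (sp.g1[i] - sm.g1[i]) / (2 * hh);
      th22[i] = (sp.g2[i] - sm.g2[i]) / (2 * hh);
    }
    std::vector<double> c1(n), c2(n), gn_try(n), tpol(n, 1.0);
    State stry = st;
    for (int it = 0; it < 12; ++it) {
      bool any_act = false;
      for (int i = 0; i < n; ++i) {
        c1[i] = eta1[i];
        c2[i] = eta2[i];
        if (gn[i] > 1e-11 && tpol[i] > 1e-4) {
          any_act = true;
          double h12 = 0.5 * (th12a[i] + th12b[i]);
          double det = th11[i] * th22[i] - h12 * h12;
          double s1, s2;
          if (th11[i] > 0 && det > 0)
            solve2(th11[i], h12, th22[i], st.g1[i], st.g2[i], s1, s2);
          else
            solve2(2.0 * (Oi[0] + st.A11[i]), 2.0 * (Oi[1] + st.A12[i]),
                   2.0 * (Oi[2] + st.A22[i]), st.g1[i], st.g2[i], s1,
                   s2);
          const double sn = std::max(std::fabs(s1), std::fabs(s2));
          double sc = tpol[i];
          if (sn * sc > 0.5) sc = 0.5 / sn;   // cap runaway steps
          c1[i] -= s1 * sc;
          c2[i] -= s2 * sc;
        }
      }
      if (!any_act) break;
      eval_full(D, c1, c2, s2p, s2a, interaction, f0, Oi, stry);
      for (int i = 0; i < n; ++i) {
        gn_try[i] = std::max(std::fabs(stry.g1[i]),
                             std::fabs(stry.g2[i]));
        if (gn[i] > 1e-11 && tpol[i] > 1e-4) {
          if (gn_try[i] < gn[i]) {
            eta1[i] = c1[i];
            eta2[i] = c2[i];
            tpol[i] = std::min(1.0, tpol[i] * 2.0);
          } else {
            tpol[i] *= 0.25;
          }
        }
      }
      eval_full(D, eta1, eta2, s2p, s2a, interaction, f0, Oi, st);
      for (int i = 0; i < n; ++i)
        gn[i] = std::max(std::fabs(st.g1[i]), std::fabs(st.g2[i]));
    }
  }
}

Design make_design(List design, NumericVector cl_base,
                   NumericVector v_base, double ka) {
  Design D;
  IntegerVector ui = design["uni_idx"], usub = design["uni_sub"];
  NumericVector uk = design["uni_k"], us = design["uni_s"],
                utau = design["uni_tau"], uamt = design["uni_amt"];
  IntegerVector pobs = design["pair_obs"], psub = design["pair_sub"];
  NumericVector pdt = design["pair_dt"], pamt = design["pair_amt"];
  NumericVector y = design["y"];
  IntegerVector obs_sub = design["obs_sub"];
  D.n_obs = as<int>(design["n_obs"]);
  D.n_sub = as<int>(design["n_sub"]);
  for (int t = 0; t < ui.size(); ++t) {
    D.ui.push_back(ui[t] - 1);
    D.usub.push_back(usub[t] - 1);
    D.uk.push_back(uk[t]);
    D.us.push_back(us[t]);
    D.utau.push_back(utau[t]);
    D.uamt.push_back(uamt[t]);
  }
  for (int t = 0; t < pobs.size(); ++t) {
    D.pobs.push_back(pobs[t] - 1);
    D.psub.push_back(psub[t] - 1);
    D.pdt.push_back(pdt[t]);
    D.pamt.push_back(pamt[t]);
  }
  D.y.assign(y.begin(), y.end());
  for (int j = 0; j < obs_sub.size(); ++j)
    D.obs_sub.push_back(obs_sub[j] - 1);
  D.cl_base.assign(cl_base.begin(), cl_base.end());
  D.v_base.assign(v_base.begin(), v_base.end());
  D.ka = ka;
  return D;
}

} // namespace

// [[Rcpp::export(name = ".foce_inner_pk")]]
List foce_inner_pk(List design, NumericVector cl_base,
                   NumericVector v_base, double ka, NumericMatrix Omega,
                   double s2p, double s2a, bool interaction,
                   Nullable<NumericMatrix> eta_start, double gtol,
                   int maxit) {
  Design D = make_design(design, cl_base, v_base, ka);
  const int n = D.n_sub;
  const double det =
      Omega(0, 0) * Omega(1, 1) - Omega(0, 1) * Omega(1, 0);
  const double Oi[3] = {Omega(1, 1) / det, -Omega(0, 1) / det,
                        Omega(0, 0) / det};
  std::vector<double> eta1(n, 0.0), eta2(n, 0.0);
  bool warm = false;
  if (eta_start.isNotNull()) {
    NumericMatrix es(eta_start);
    for (int i = 0; i < n; ++i) {
      eta1[i] = es(i, 0);
      eta2[i] = es(i, 1);
      if (eta1[i] != 0.0 || eta2[i] != 0.0) warm = true;
    }
  }
  std::vector<double> f0;
  if (!interaction) {
    std::vector<double> z1(n, 0.0), z2(n, 0.0), dum;
    f0.assign(D.n_obs, 0.0);
    model_eval(D, z1, z2, false, f0, dum, dum);
  }
  State st;
  st.f.assign(D.n_obs, 0.0);
  st.J1.assign(D.n_obs, 0.0);
  st.J2.assign(D.n_obs, 0.0);
  st.obj.assign(n, 0.0);
  st.g1.assign(n, 0.0);
  st.g2.assign(n, 0.0);
  st.A11.assign(n, 0.0);
  st.A12.assign(n, 0.0);
  st.A22.assign(n, 0.0);
  std::vector<double> gn(n, 0.0);
  run_phase(D, eta1, eta2, s2p, s2a, interaction, f0, Oi, gtol, maxit,
            st, gn);
  const double accept_tol = std::max(gtol, 1e-3);
  if (warm) {
    bool any_bad = false;
    for (int i = 0; i < n; ++i) if (gn[i] >= accept_tol) any_bad = true;
    if (any_bad) {
      // restart unconverged subjects from the origin, keep the better
      std::vector<double> r1(eta1), r2(eta2), gn2(n, 0.0);
      for (int i = 0; i < n; ++i)
        if (gn[i] >= accept_tol) { r1[i] = 0.0; r2[i] = 0.0; }
      State st2 = st;
      run_phase(D, r1, r2, s2p, s2a, interaction, f0, Oi, gtol, maxit,
                st2, gn2);
      bool any_take = false;
      for (int i = 0; i < n; ++i)
        if (st2.obj[i] <= st.obj[i]) {
          eta1[i] = r1[i];
          eta2[i] = r2[i];
          any_take = true;
        }
      if (any_take)
        run_phase(D, eta1, eta2, s2p, s2a, interaction, f0, Oi, gtol,
                  maxit, st, gn);
    }
  }
  NumericMatrix eta(n, 2), J(D.n_obs, 2), A(n, 3);
  NumericVector obj(n), f(D.n_obs), varv(D.n_obs), res(D.n_obs),
      gnv(n);
  LogicalVector conv(n);
  for (int i = 0; i < n; ++i) {
    eta(i, 0) = eta1[i];
    eta(i, 1) = eta2[i];
    obj[i] = st.obj[i];
    A(i, 0) = st.A11[i];
    A(i, 1) = st.A12[i];
    A(i, 2) = st.A22[i];
    gnv[i] = gn[i];
    conv[i] = gn[i] < accept_tol;
  }
  for (int j = 0; j < D.n_obs; ++j) {
    f[j] = st.f[j];
    J(j, 0) = st.J1[j];
    J(j, 1) = st.J2[j];
    res[j] = D.y[j] - st.f[j];
    const double fv = interaction ? st.f[j] : f0[j];
    double var = s2p * fv * fv + s2a;
    if (var < 1e-12) var = 1e-12;
    varv[j] = var;
  }
  return List::create(_["eta"] = eta, _["obj"] = obj, _["f"] = f,
                      _["J"] = J, _["res"] = res, _["varv"] = varv,
                      _["A"] = A, _["grad_norm"] = gnv,
                      _["converged"] = conv);
}
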
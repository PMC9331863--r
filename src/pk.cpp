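#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-form concentration-time solutions for 1/2/3-compartment mammillary
// models with constant-rate IV infusion input, plus the Laplace-approximate
// marginal -2 log-likelihood used for population fitting.  Disposition is
// parameterised by (CL, V1 [, Q2, V2 [, Q3, V3]]); rates in 1/h, volumes L.

// ---- disposition eigenvalues (decay rates, descending) -------------------

// 2-cmt: roots of l^2 - (k10+k12+k21) l + k10*k21
static void eig2(double k10, double k12, double k21, double *l) {
  double s = k10 + k12 + k21;
  double disc = std::sqrt(std::max(s * s - 4.0 * k10 * k21, 0.0));
  l[0] = (s + disc) / 2.0;
  l[1] = (s - disc) / 2.0;
}

// 3-cmt: three real positive roots of the cubic; trigonometric solution
static void eig3(double k10, double k12, double k21, double k13, double k31,
                 double *l) {
  double a2 = k10 + k12 + k13 + k21 + k31;
  double a1 = k10 * k21 + k10 * k31 + k12 * k31 + k13 * k21 + k21 * k31;
  double a0 = k10 * k21 * k31;
  // depressed cubic t^3 + p t + q, l = t + a2/3
  double p = a1 - a2 * a2 / 3.0;
  double q = -2.0 * a2 * a2 * a2 / 27.0 + a2 * a1 / 3.0 - a0;
  double m = 2.0 * std::sqrt(std::max(-p / 3.0, 1e-300));
  double arg = 3.0 * q / (p * m);
  arg = std::min(1.0, std::max(-1.0, arg));
  double phi = std::acos(arg) / 3.0;
  for (int i = 0; i < 3; i++)
    l[i] = m * std::cos(phi - 2.0 * M_PI * i / 3.0) + a2 / 3.0;
  // descending order
  for (int i = 0; i < 2; i++)
    for (int j = i + 1; j < 3; j++)
      if (l[j] > l[i]) std::swap(l[i], l[j]);
}

struct Disposition {
  int nl;            // number of exponentials
  double lam[3];     // decay rates, descending
  double coef[3];    // per-unit-rate coefficients: C_during = sum coef_i (1 - e^{-l t})
};

// coef_i = prod_j (k_j1 - l_i) / (V1 * l_i * prod_{j != i} (l_j - l_i))
static bool disposition(const double *p, int ncmt, Disposition &d) {
  double CL = p[0], V1 = p[1];
  if (!(CL > 0.0) || !(V1 > 0.0)) return false;
  double k10 = CL / V1;
  if (ncmt == 1) {
    d.nl = 1;
    d.lam[0] = k10;
    d.coef[0] = 1.0 / (V1 * k10);
    return true;
  }
  double Q2 = p[2], V2 = p[3];
  if (Q2 < 0.0 || !(V2 > 0.0)) return false;
  if (Q2 == 0.0) return disposition(p, 1, d);  // collapses to one compartment
  double k12 = Q2 / V1, k21 = Q2 / V2;
  if (ncmt == 2) {
    d.nl = 2;
    eig2(k10, k12, k21, d.lam);
    for (int i = 0; i < 2; i++) {
      double li = d.lam[i];
      d.coef[i] = (k21 - li) / (V1 * li * (d.lam[1 - i] - li));
    }
    return true;
  }
  double Q3 = p[4], V3 = p[5];
  if (Q3 < 0.0 || !(V3 > 0.0)) return false;
  if (Q3 == 0.0) return disposition(p, 2, d);
  double k13 = Q3 / V1, k31 = Q3 / V3;
  d.nl = 3;
  eig3(k10, k12, k21, k13, k31, d.lam);
  for (int i = 0; i < 3; i++) {
    double li = d.lam[i];
    double num = (k21 - li) * (k31 - li);
    double den = V1 * li;
    for (int j = 0; j < 3; j++)
      if (j != i) den *= (d.lam[j] - li);
    d.coef[i] = num / den;
  }
  return true;
}

// concentration at time t (h since first dose) from one infusion
static double conc_one_dose(const Disposition &d, double amt, double start,
                            double dur, double t) {
  double tt = t - start;
  if (tt <= 0.0 || amt <= 0.0) return 0.0;
  double R0 = amt / dur;
  double c = 0.0;
  if (tt <= dur) {
    for (int i = 0; i < d.nl; i++)
      c += d.coef[i] * (1.0 - std::exp(-d.lam[i] * tt));
  } else {
    double tp = tt - dur;
    for (int i = 0; i < d.nl; i++)
      c += d.coef[i] * (1.0 - std::exp(-d.lam[i] * dur)) *
           std::exp(-d.lam[i] * tp);
  }
  return R0 * c;
}

static void conc_all(const double *p, int ncmt, const double *amt,
                     const double *start, const double *dur, int ndose,
                     const double *t, int nt, double *out, bool &ok) {
  Disposition d;
  ok = disposition(p, ncmt, d);
  if (!ok) return;
  for (int k = 0; k < nt; k++) {
    double c = 0.0;
    for (int i = 0; i < ndose; i++)
      c += conc_one_dose(d, amt[i], start[i], dur[i], t[k]);
    out[k] = c;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector params, int ncmt, NumericVector amt,
                       NumericVector start, NumericVector dur,
                       NumericVector times) {
  int nt = times.size();
  NumericVector out(nt);
  bool ok;
  conc_all(REAL(params), ncmt, REAL(amt), REAL(start), REAL(dur), amt.size(),
           REAL(times), nt, REAL(out), ok);
  if (!ok) stop("invalid PK parameters (must be strictly positive)");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_disposition_rates(NumericVector params, int ncmt) {
  Disposition d;
  if (!disposition(REAL(params), ncmt, d))
    stop("invalid PK parameters (must be strictly positive)");
  NumericVector out(d.nl);
  for (int i = 0; i < d.nl; i++) out[i] = d.lam[i];
  return out;
}

// ---- subject-level likelihood --------------------------------------------

struct SubjData {
  std::vector<double> amt, start, dur;  // dosing
  std::vector<double> t, y;             // observations
};

// -log p(y | individual params) under combined error sd = sqrt(a^2 + (b f)^2)
static double nll_data(const double *p, int ncmt, const SubjData &s,
                       double a, double b) {
  int nt = (int)s.t.size();
  std::vector<double> f(nt);
  bool ok;
  conc_all(p, ncmt, s.amt.data(), s.start.data(), s.dur.data(),
           (int)s.amt.size(), s.t.data(), nt, f.data(), ok);
  if (!ok) return 1e10;
  double nll = 0.0;
  for (int k = 0; k < nt; k++) {
    double sd = std::sqrt(a * a + b * b * f[k] * f[k]);
    if (!(sd > 0.0) || !std::isfinite(sd)) return 1e10;
    double r = (s.y[k] - f[k]) / sd;
    nll += 0.5 * std::log(2.0 * M_PI) + std::log(sd) + 0.5 * r * r;
  }
  return std::isfinite(nll) ? nll : 1e10;
}

// posterior objective h(eta) = -log p(y|eta) - log p(eta); eta enters only
// through free indices (omega > 0), individual param = typ * exp(eta)
struct EtaObj {
  const double *typ;       // typical values, length npar
  const double *omega;     // IIV sd, length npar
  const std::vector<int> *free_idx;
  int ncmt, npar;
  double a, b;
  const SubjData *s;

  double operator()(const double *eta_free) const {
    double p[6];
    for (int j = 0; j < npar; j++) p[j] = typ[j];
    double prior = 0.0;
    for (size_t i = 0; i < free_idx->size(); i++) {
      int j = (*free_idx)[i];
      double e = eta_free[i];
      p[j] = typ[j] * std::exp(e);
      prior += 0.5 * std::log(2.0 * M_PI) + std::log(omega[j]) +
               0.5 * e * e / (omega[j] * omega[j]);
    }
    return nll_data(p, ncmt, *s, a, b) + prior;
  }
};

// Nelder-Mead simplex minimiser, d <= 6
static double nelder_mead(const EtaObj &f, std::vector<double> &x, int maxit) {
  int d = (int)x.size();
  if (d == 0) return f(x.data());
  int n = d + 1;
  std::vector<std::vector<double> > S(n, x);
  std::vector<double> fv(n);
  for (int i = 1; i < n; i++) S[i][i - 1] += 0.25;
  for (int i = 0; i < n; i++) fv[i] = f(S[i].data());
  std::vector<double> xc(d), xr(d), xe(d), xk(d);
  for (int it = 0; it < maxit; it++) {
    // order
    for (int i = 0; i < n - 1; i++)
      for (int j = i + 1; j < n; j++)
        if (fv[j] < fv[i]) { std::swap(fv[i], fv[j]); S[i].swap(S[j]); }
    if (fv[n - 1] - fv[0] < 1e-10 * (1.0 + std::fabs(fv[0]))) break;
    for (int k = 0; k < d; k++) {
      double c = 0.0;
      for (int i = 0; i < n - 1; i++) c += S[i][k];
      xc[k] = c / (n - 1);
    }
    for (int k = 0; k < d; k++) xr[k] = xc[k] + (xc[k] - S[n - 1][k]);
    double fr = f(xr.data());
    if (fr < fv[0]) {
      for (int k = 0; k < d; k++) xe[k] = xc[k] + 2.0 * (xc[k] - S[n - 1][k]);
      double fe = f(xe.data());
      if (fe < fr) { S[n - 1] = xe; fv[n - 1] = fe; }
      else { S[n - 1] = xr; fv[n - 1] = fr; }
    } else if (fr < fv[n - 2]) {
      S[n - 1] = xr; fv[n - 1] = fr;
    } else {
      for (int k = 0; k < d; k++) xk[k] = xc[k] + 0.5 * (S[n - 1][k] - xc[k]);
      double fk = f(xk.data());
      if (fk < fv[n - 1]) { S[n - 1] = xk; fv[n - 1] = fk; }
      else {  // shrink
        for (int i = 1; i < n; i++) {
          for (int k = 0; k < d; k++) S[i][k] = S[0][k] + 0.5 * (S[i][k] - S[0][k]);
          fv[i] = f(S[i].data());
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < n; i++) if (fv[i] < fv[best]) best = i;
  x = S[best];
  return fv[best];
}

// log-determinant of the (regularised) Hessian of h at eta_hat, central diff
static double hess_logdet(const EtaObj &f, const std::vector<double> &x,
                          double f0, bool &pd) {
  int d = (int)x.size();
  pd = true;
  if (d == 0) return 0.0;
  const double h = 1e-4;
  std::vector<std::vector<double> > H(d, std::vector<double>(d));
  std::vector<double> xp(x), fpl(d), fmi(d);
  for (int i = 0; i < d; i++) {
    xp = x; xp[i] += h; fpl[i] = f(xp.data());
    xp = x; xp[i] -= h; fmi[i] = f(xp.data());
    H[i][i] = (fpl[i] - 2.0 * f0 + fmi[i]) / (h * h);
  }
  for (int i = 0; i < d; i++)
    for (int j = i + 1; j < d; j++) {
      xp = x; xp[i] += h; xp[j] += h; double fpp = f(xp.data());
      xp = x; xp[i] -= h; xp[j] -= h; double fmm = f(xp.data());
      H[i][j] = H[j][i] =
          (fpp - fpl[i] - fpl[j] + 2.0 * f0 - fmi[i] - fmi[j] + fmm) /
          (2.0 * h * h);
    }
  // Cholesky with ridge fallback
  for (int attempt = 0; attempt < 6; attempt++) {
    std::vector<std::vector<double> > L(d, std::vector<double>(d, 0.0));
    double logdet = 0.0;
    bool ok = true;
    for (int i = 0; i < d && ok; i++) {
      for (int j = 0; j <= i; j++) {
        double s = H[i][j];
        for (int k = 0; k < j; k++) s -= L[i][k] * L[j][k];
        if (i == j) {
          if (s <= 0.0) { ok = false; break; }
          L[i][i] = std::sqrt(s);
          logdet += 2.0 * std::log(L[i][i]);
        } else L[i][j] = s / L[j][j];
      }
    }
    if (ok) return logdet;
    pd = false;
    double ridge = std::pow(10.0, attempt - 4);
    for (int i = 0; i < d; i++) H[i][i] += ridge;
  }
  return 0.0;
}

static SubjData subj_from_list(const List &sub) {
  SubjData s;
  NumericVector amt = sub["amt"], start = sub["start"], dur = sub["dur"];
  NumericVector t = sub["time"], y = sub["conc"];
  s.amt.assign(amt.begin(), amt.end());
  s.start.assign(start.begin(), start.end());
  s.dur.assign(dur.begin(), dur.end());
  s.t.assign(t.begin(), t.end());
  s.y.assign(y.begin(), y.end());
  return s;
}

// Laplace-approximate -2 log marginal likelihood over subjects.
// typical: n_subj x npar matrix of covariate-adjusted typical values;
// subjects: list of lists with amt/start/dur/time/conc;
// eta_warm: n_subj x npar warm starts (updated in place semantics via return).
// [[Rcpp::export]]
List cpp_m2ll(NumericMatrix typical, NumericVector omega, double err_a,
              double err_b, List subjects, int ncmt, NumericMatrix eta_warm,
              int inner_maxit = 400) {
  int nsub = subjects.size();
  int npar = typical.ncol();
  std::vector<int> free_idx;
  for (int j = 0; j < npar; j++)
    if (omega[j] > 0.0) free_idx.push_back(j);
  int d = (int)free_idx.size();
  NumericVector per(nsub);
  NumericMatrix eta_out(nsub, npar);
  double total = 0.0;
  bool all_pd = true;
  for (int i = 0; i < nsub; i++) {
    SubjData s = subj_from_list(subjects[i]);
    std::vector<double> typ(npar);
    for (int j = 0; j < npar; j++) typ[j] = typical(i, j);
    EtaObj obj;
    obj.typ = typ.data(); obj.omega = REAL(omega); obj.free_idx = &free_idx;
    obj.ncmt = ncmt; obj.npar = npar; obj.a = err_a; obj.b = err_b; obj.s = &s;
    std::vector<double> eta(d);
    for (int k = 0; k < d; k++) eta[k] = eta_warm(i, free_idx[k]);
    double h0 = nelder_mead(obj, eta, inner_maxit);
    bool pd;
    double logdet = hess_logdet(obj, eta, h0, pd);
    all_pd = all_pd && pd;
    // -2 log Lm = 2 h(eta^) - d log(2 pi) + log|H|
    double m2 = 2.0 * h0 - d * std::log(2.0 * M_PI) + logdet;
    per[i] = m2;
    total += m2;
    for (int k = 0; k < d; k++) eta_out(i, free_idx[k]) = eta[k];
  }
  return List::create(_["m2ll"] = total, _["per_subject"] = per,
                      _["eta"] = eta_out, _["hessian_pd"] = all_pd);
}
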
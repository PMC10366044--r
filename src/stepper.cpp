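#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chemo-transport sub-stepping core. Trapezoidal (Newton-Cotes) rule in time
// for the diffusive flux, nodal instantaneous-equilibrium closure re-solved
// after every linear update (staggered Newton on the coupled system), supply
// and equilibrium coefficient interpolated linearly across the mechanical
// step. Matrices arrive as tridiagonal bands; the linear solves use the
// Thomas algorithm.

namespace {

inline void tri_mult(int n, const double* dl, const double* d, const double* du,
                     const double* x, double* y) {
  for (int i = 0; i < n; ++i) {
    double v = d[i] * x[i];
    if (i > 0) v += dl[i - 1] * x[i - 1];
    if (i < n - 1) v += du[i] * x[i + 1];
    y[i] = v;
  }
}

// solve tridiagonal system; rhs overwritten with solution
inline void tri_solve(int n, const double* dl, const double* d, const double* du,
                      double* rhs, double* cp) {
  double piv = d[0];
  if (piv == 0.0) stop("singular tridiagonal system");
  cp[0] = du[0] / piv;
  rhs[0] = rhs[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = d[i] - dl[i - 1] * cp[i - 1];
    if (piv == 0.0) stop("singular tridiagonal system");
    if (i < n - 1) cp[i] = du[i] / piv;
    rhs[i] = (rhs[i] - dl[i - 1] * rhs[i - 1]) / piv;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
}

struct EqBase { double cR, cL, cC, beta; };

// unique non-negative root of cR^2 + (al - cD) cR - al (SL + cD) = 0,
// closures cL = SL al/(al + cR), cC = SL cR/(al + cR); beta = dcR/dcD
inline EqBase eq_base(double cD, double SL, double al) {
  double tot = SL + cD;
  if (tot < 0.0) {
    double scale = std::max(1.0, std::max(std::fabs(cD), SL));
    if (tot < -1e-8 * scale)
      stop("infeasible state: S_L + c_D < 0 in equilibrium solve");
    tot = 0.0;
  }
  double q = al - cD;
  double s = std::sqrt(q * q + 4.0 * al * tot);
  double cR = (q > 0.0) ? (2.0 * al * tot / (q + s)) : 0.5 * (s - q);
  if (cR < 0.0) cR = 0.0;
  double beta = 0.5 * (1.0 + (2.0 * al - q) / std::max(s, 1e-300));
  if (beta < 0.0) beta = 0.0;
  double cL = SL * al / (al + cR);
  EqBase out;
  out.cR = cR; out.cL = cL; out.cC = SL - cL; out.beta = beta;
  return out;
}

struct EqSplit { double cRm, cRi, cL, cCm, cCi, beta; };

// scalar ligand equation cL (1 + (cm+ci)/(al+cL)) = SL, closed-form root;
// beta = d cRm / d cm at fixed ci, SL, al
inline EqSplit eq_split(double cm, double ci, double SL, double al) {
  if (cm < 0.0) {
    if (cm < -1e-8) stop("negative mobile total in split equilibrium solve");
    cm = 0.0;
  }
  double ctot = cm + ci;
  double B = al + ctot - SL;
  double s = std::sqrt(B * B + 4.0 * SL * al);
  double cL = (B >= 0.0) ? (2.0 * SL * al / (B + s)) : 0.5 * (s - B);
  if (cL > SL) cL = SL;
  double denom = al + cL;
  double dcL = 0.5 * (-1.0 + B / std::max(s, 1e-300)); // d cL / d cm
  double frac = al / denom;
  EqSplit out;
  out.cRm = cm * frac;
  out.cRi = ci * frac;
  out.cL = cL;
  out.cCm = cm - out.cRm;
  out.cCi = ci - out.cRi;
  out.beta = frac - cm * al / (denom * denom) * dcL;
  if (out.beta < 0.0) out.beta = 0.0;
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_advance_base(NumericVector cD0, NumericVector SL0, NumericVector SL1,
                      NumericVector al0, NumericVector al1,
                      NumericVector Md, NumericVector Ml, NumericVector Mu,
                      NumericVector Kd, NumericVector Kl, NumericVector Ku,
                      double dt, int substeps, double tol, int maxit) {
  const int n = cD0.size();
  const double sdt = dt / substeps, h2 = 0.5 * sdt;
  std::vector<double> cD(cD0.begin(), cD0.end());
  std::vector<double> cDa(n), cRa(n), SLa(n), SLb(n), alb(n);
  std::vector<double> cR(n), beta(n), F(n), Jd(n), Jl(n - 1), Ju(n - 1), cp(n);
  NumericVector cRout(n), cLout(n), cCout(n);

  for (int i = 0; i < n; ++i) {
    SLa[i] = SL0[i];
    EqBase e = eq_base(cD[i], SLa[i], al0[i]);
    cRa[i] = e.cR;
  }
  int itmax = 0;
  for (int k = 1; k <= substeps; ++k) {
    double fr = double(k) / substeps;
    for (int i = 0; i < n; ++i) {
      SLb[i] = SL0[i] + fr * (SL1[i] - SL0[i]);
      alb[i] = al0[i] + fr * (al1[i] - al0[i]);
      cDa[i] = cD[i];
      cD[i] = cDa[i] - (SLb[i] - SLa[i]);   // supply-only predictor
    }
    int it = 0;
    std::vector<double> flux(n), sum(n), Mx(n);
    for (; it < maxit; ++it) {
      double cdmax = 1.0;
      for (int i = 0; i < n; ++i) {
        EqBase e = eq_base(cD[i], SLb[i], alb[i]);
        cR[i] = e.cR; beta[i] = e.beta;
        sum[i] = cR[i] + cRa[i];
        Mx[i] = cD[i] - cDa[i] + (SLb[i] - SLa[i]);
        if (std::fabs(cD[i]) > cdmax) cdmax = std::fabs(cD[i]);
      }
      // residual F = M (cD - cDa + dSL) + h2 K (cR + cRa)
      tri_mult(n, Ml.begin(), Md.begin(), Mu.begin(), Mx.data(), F.data());
      tri_mult(n, Kl.begin(), Kd.begin(), Ku.begin(), sum.data(), flux.data());
      for (int i = 0; i < n; ++i) F[i] = -(F[i] + h2 * flux[i]);
      // Jacobian J = M + h2 K diag(beta)
      for (int i = 0; i < n; ++i) Jd[i] = Md[i] + h2 * Kd[i] * beta[i];
      for (int i = 0; i < n - 1; ++i) {
        Jl[i] = Ml[i] + h2 * Kl[i] * beta[i];
        Ju[i] = Mu[i] + h2 * Ku[i] * beta[i + 1];
      }
      tri_solve(n, Jl.data(), Jd.data(), Ju.data(), F.data(), cp.data());
      double dmax = 0.0;
      for (int i = 0; i < n; ++i) {
        cD[i] += F[i];
        double a = std::fabs(F[i]);
        if (a > dmax) dmax = a;
      }
      if (dmax / cdmax < tol) { ++it; break; }
    }
    if (it >= maxit)
      stop("chemo sub-step failed to converge in %d iterations (substep %d)",
           maxit, k);
    if (it > itmax) itmax = it;
    for (int i = 0; i < n; ++i) {
      EqBase e = eq_base(cD[i], SLb[i], alb[i]);
      cRa[i] = e.cR;
      SLa[i] = SLb[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    EqBase e = eq_base(cD[i], SLa[i], al1[i]);
    cRout[i] = e.cR; cLout[i] = e.cL; cCout[i] = e.cC;
  }
  return List::create(_["c_D"] = NumericVector(cD.begin(), cD.end()),
                      _["c_R"] = cRout, _["c_L"] = cLout, _["c_C"] = cCout,
                      _["iterations"] = itmax);
}

// [[Rcpp::export]]
List cpp_advance_split(NumericVector cm0, NumericVector ci,
                       NumericVector SL0, NumericVector SL1,
                       NumericVector al0, NumericVector al1,
                       NumericVector Md, NumericVector Ml, NumericVector Mu,
                       NumericVector Kd, NumericVector Kl, NumericVector Ku,
                       double dt, int substeps, double tol, int maxit) {
  const int n = cm0.size();
  const double sdt = dt / substeps, h2 = 0.5 * sdt;
  std::vector<double> cm(cm0.begin(), cm0.end());
  std::vector<double> cma(n), cRma(n), SLb(n), alb(n);
  std::vector<double> cRm(n), beta(n), F(n), Mx(n), flux(n), sum(n);
  std::vector<double> Jd(n), Jl(n - 1), Ju(n - 1), cp(n);
  NumericVector cRmout(n), cRiout(n), cLout(n), cCmout(n), cCiout(n);

  std::vector<double> SLa(SL0.begin(), SL0.end());
  for (int i = 0; i < n; ++i) {
    EqSplit e = eq_split(cm[i], ci[i], SLa[i], al0[i]);
    cRma[i] = e.cRm;
  }
  int itmax = 0;
  for (int k = 1; k <= substeps; ++k) {
    double fr = double(k) / substeps;
    for (int i = 0; i < n; ++i) {
      SLb[i] = SL0[i] + fr * (SL1[i] - SL0[i]);
      alb[i] = al0[i] + fr * (al1[i] - al0[i]);
      cma[i] = cm[i];
    }
    int it = 0;
    for (; it < maxit; ++it) {
      double cmmax = 1.0;
      for (int i = 0; i < n; ++i) {
        EqSplit e = eq_split(cm[i], ci[i], SLb[i], alb[i]);
        cRm[i] = e.cRm; beta[i] = e.beta;
        sum[i] = cRm[i] + cRma[i];
        if (std::fabs(cm[i]) > cmmax) cmmax = std::fabs(cm[i]);
      }
      for (int i = 0; i < n; ++i) Mx[i] = cm[i] - cma[i];
      tri_mult(n, Ml.begin(), Md.begin(), Mu.begin(), Mx.data(), F.data());
      tri_mult(n, Kl.begin(), Kd.begin(), Ku.begin(), sum.data(), flux.data());
      for (int i = 0; i < n; ++i) F[i] = -(F[i] + h2 * flux[i]);
      for (int i = 0; i < n; ++i) Jd[i] = Md[i] + h2 * Kd[i] * beta[i];
      for (int i = 0; i < n - 1; ++i) {
        Jl[i] = Ml[i] + h2 * Kl[i] * beta[i];
        Ju[i] = Mu[i] + h2 * Ku[i] * beta[i + 1];
      }
      tri_solve(n, Jl.data(), Jd.data(), Ju.data(), F.data(), cp.data());
      double dmax = 0.0;
      for (int i = 0; i < n; ++i) {
        cm[i] += F[i];
        double a = std::fabs(F[i]);
        if (a > dmax) dmax = a;
      }
      if (dmax / cmmax < tol) { ++it; break; }
    }
    if (it >= maxit)
      stop("split chemo sub-step failed to converge in %d iterations (substep %d)",
           maxit, k);
    if (it > itmax) itmax = it;
    for (int i = 0; i < n; ++i) {
      EqSplit e = eq_split(cm[i], ci[i], SLb[i], alb[i]);
      cRma[i] = e.cRm;
    }
  }
  for (int i = 0; i < n; ++i) {
    EqSplit e = eq_split(cm[i], ci[i], SL1[i], al1[i]);
    cRmout[i] = e.cRm; cRiout[i] = e.cRi; cLout[i] = e.cL;
    cCmout[i] = e.cCm; cCiout[i] = e.cCi;
  }
  return List::create(_["c_m"] = NumericVector(cm.begin(), cm.end()),
                      _["c_R_m"] = cRmout, _["c_R_i"] = cRiout,
                      _["c_L"] = cLout, _["c_C_m"] = cCmout,
                      _["c_C_i"] = cCiout, _["iterations"] = itmax);
}
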
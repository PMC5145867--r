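// Biophysical fruit growth core: water/carbon fluxes, Lockhart turgor,
// fixed-step RK4 integration.  Units: g, h, bar, cm, degrees C.
//
// The fruit turgor Pf satisfies an algebraic balance at every instant:
//   V*phi(t)*max(Pf - Y, 0) = dV/dt(Pf)
// where dV/dt(Pf) from the mass balance is piecewise linear and strictly
// decreasing in Pf (the only kink is the sign change of the phloem mass
// flow Up).  The root is therefore available in closed form per branch.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// gas constant in cm^3 bar mol^-1 K^-1
static const double RGAS_BAR = 83.14;
// gas constant J mol^-1 K^-1 and molar mass of water (transpiration)
static const double RGAS_SI = 8.314;
static const double MW_WATER = 18.015;

// index maps for the packed parameter vectors (kept in step with the R
// constructors genotype_par_vector(), generic_par_vector(), plant_par_vector())
enum ParIdx { P_PHIMAX, P_LP, P_NUM, P_TSTAR, P_TAUA, P_TAUS, P_LP1,
              P_LX, P_LX1, P_ASSRAT, P_BSSRAT, P_W0, P_S0 };
enum GenIdx { G_KM, G_PS, G_AP, G_AX, G_QG, G_QM20, G_Q10, G_Y,
              G_TAUPHI, G_HF, G_RHOS, G_MSUGAR, G_GAMMAA, G_RW,
              G_SCALEUA };
enum PlantIdx { I_PSIPRE, I_PSIMID, I_CP, I_RHOSURF, I_PIOTHER };

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// soluble sugar fraction of dry mass, linear in time (t in hours)
static inline double ssrat_at(double t, double assrat, double bssrat) {
  return clip01(assrat * t / 24.0 + bssrat);
}

// reflection coefficient of the composite membrane, rises from 0 toward 1
static inline double sigma_p_at(double t, double tauS) {
  return 1.0 - std::exp(-tauS * t * t);
}

// overflow-safe logistic decline of the active uptake capacity
static inline double nu_active_at(double t, double nuM, double tstar,
                                  double tauA) {
  double z = (t - tstar) / tauA;
  if (z > 50.0) return nuM * std::exp(-z);
  return nuM / (1.0 + std::exp(z));
}

// van 't Hoff osmotic pressure (bar) of conc g solute per g water
static inline double vant_hoff(double conc, double tempC, double msugar) {
  return conc / msugar * RGAS_BAR * (tempC + 273.15);
}

// saturation vapour pressure (Pa), Buck/Magnus form
static inline double psat_pa(double tempC) {
  return 611.21 * std::exp(17.502 * tempC / (240.97 + tempC));
}

// saturation vapour density g cm^-3
static inline double alpha_vap(double tempC) {
  return MW_WATER * psat_pa(tempC) / (RGAS_SI * (tempC + 273.15)) * 1e-6;
}

// diurnal stem water potential: maximum (predawn value) at 05:00, minimum
// (midday value) at 13:00, half-cosine interpolation in between
static inline double psi_stem_at(double t, double psiPre, double psiMid) {
  // hour of day without fmod (fmod needs glibc >= 2.38 on this toolchain)
  double h = t - 24.0 * std::floor(t / 24.0);
  double f;  // weight of the midday value
  if (h >= 5.0 && h < 13.0) {
    f = 0.5 * (1.0 - std::cos(M_PI * (h - 5.0) / 8.0));
  } else {
    double hh = h - 13.0;
    if (hh < 0) hh += 24.0;
    f = 0.5 * (1.0 + std::cos(M_PI * hh / 16.0));
  }
  return psiPre + f * (psiMid - psiPre);
}

struct EnvGrid {
  double t0, dt;
  const double *T, *RH;
  int n;
  inline void at(double t, double &tempC, double &rh) const {
    double u = (t - t0) / dt;
    if (u <= 0) { tempC = T[0]; rh = RH[0]; return; }
    if (u >= n - 1) { tempC = T[n - 1]; rh = RH[n - 1]; return; }
    int i = (int)u;
    double w = u - i;
    tempC = T[i] * (1.0 - w) + T[i + 1] * w;
    rh = RH[i] * (1.0 - w) + RH[i + 1] * w;
  }
};

struct Fluxes {
  double Pf, resid;
  int growing;
  double Ux, Up, Ua, Um, Ud, Us, Tf, Rf, dwdt, dsdt;
};

// full right-hand side at (t, w, s); solves the turgor balance in closed form
static Fluxes rhs_at(double t, double w, double s, const double *par,
                     const double *gen, const double *plant,
                     const EnvGrid &env) {
  Fluxes out;
  double tempC, rh;
  env.at(t, tempC, rh);

  double rhoS = gen[G_RHOS], qg = gen[G_QG];
  double V = w + s / rhoS;
  double Af = gen[G_GAMMAA] * std::pow(V, 2.0 / 3.0);

  double ssrat = ssrat_at(t, par[P_ASSRAT], par[P_BSSRAT]);
  double Cf = ssrat * s / w;
  double Cp = plant[I_CP];
  double pif = vant_hoff(Cf, tempC, gen[G_MSUGAR]) + plant[I_PIOTHER];
  double pip = vant_hoff(Cp, tempC, gen[G_MSUGAR]);
  double sig = sigma_p_at(t, par[P_TAUS]);
  double psi = psi_stem_at(t, plant[I_PSIPRE], plant[I_PSIMID]);

  // series conductances: pedicel element then membrane element
  double kx = 1.0 / (1.0 / par[P_LX1] + 1.0 / (gen[G_AX] * Af * par[P_LX]));
  double kp = 1.0 / (1.0 / par[P_LP1] + 1.0 / (gen[G_AP] * Af * par[P_LP]));
  double Dx = psi + pif;                       // Ux = kx (Dx - Pf)
  double Dp = psi + pip - sig * (pip - pif);   // Up = kp (Dp - Pf)

  double nu = nu_active_at(t, par[P_NUM], par[P_TSTAR], par[P_TAUA]);
  if (gen[G_SCALEUA] > 0.5) nu *= s;   // optional dry-mass scaling
  double Ua = nu * Cp / (gen[G_KM] + Cp);
  double Ud = gen[G_PS] * gen[G_AP] * Af * (Cp - Cf);
  double m = (1.0 - sig) * 0.5 * (Cp + Cf);  // Um = m * max(Up, 0)

  double qm = gen[G_QM20] * std::pow(gen[G_Q10], (tempC - 20.0) / 10.0);
  double Tf = Af * plant[I_RHOSURF] * alpha_vap(tempC) * (gen[G_HF] - rh);
  if (Tf < 0) Tf = 0;

  // dV/dt(Pf) = A_b - B_b * Pf on branch b (b = 1: Up >= 0, b = 0: Up < 0)
  double c = (gen[G_RW] * qg + 1.0 / rhoS) / (1.0 + qg);
  auto coefA = [&](double mb) {
    double U0 = Ua + Ud + mb * kp * Dp;
    return kx * Dx + kp * Dp - Tf +
           gen[G_RW] * (qg * U0 + qm * s) / (1.0 + qg) +
           (U0 - qm * s) / ((1.0 + qg) * rhoS);
  };
  auto coefB = [&](double mb) { return kx + kp + c * mb * kp; };

  // solve A_b - B_b*Pf = c1*Pf + c0 across the Up-sign kink at Pf = Dp
  auto pw_solve = [&](double c0, double c1) {
    double r = (coefA(m) - c0) / (coefB(m) + c1);
    if (r <= Dp) return r;
    r = (coefA(0.0) - c0) / (coefB(0.0) + c1);
    if (r >= Dp) return r;
    return Dp;
  };

  double phi = par[P_PHIMAX] * std::exp(-t / gen[G_TAUPHI]);
  double Y = gen[G_Y];
  double Ps = pw_solve(0.0, 0.0);  // static root: dV/dt = 0
  double Pf;
  int growing;
  if (Ps > Y) {  // mass balance pushes past yield: Lockhart growth
    Pf = pw_solve(-V * phi * Y, V * phi);
    growing = 1;
  } else {
    Pf = Ps > 0.0 ? Ps : 0.0;
    growing = 0;
  }

  // evaluate fluxes at the solved Pf
  double Ux = kx * (Dx - Pf);
  double Up = kp * (Dp - Pf);
  double Um = Up > 0 ? m * Up : 0.0;
  double Us = Ua + Um + Ud;
  double dsdt = (Us - qm * s) / (1.0 + qg);
  double Rf = Us - dsdt;
  double dwdt = Ux + Up + gen[G_RW] * Rf - Tf;
  double dVdt = dwdt + dsdt / rhoS;
  double lockhart = growing ? V * phi * (Pf - Y) : 0.0;
  double scale = std::max(1.0, std::fabs(dVdt));
  out.resid = (dVdt - lockhart) / scale;
  if (!growing && Pf == 0.0) out.resid = 0.0;  // dV/dt may be negative at Pf=0

  out.Pf = Pf; out.growing = growing;
  out.Ux = Ux; out.Up = Up; out.Ua = Ua; out.Um = Um; out.Ud = Ud;
  out.Us = Us; out.Tf = Tf; out.Rf = Rf; out.dwdt = dwdt; out.dsdt = dsdt;
  return out;
}

// [[Rcpp::export]]
List cpp_rhs(double t, double w, double s, NumericVector par,
             NumericVector gen, NumericVector plant,
             double env_t0, double env_dt, NumericVector envT,
             NumericVector envRH) {
  if (!std::isfinite(t) || !std::isfinite(w) || !std::isfinite(s) ||
      w <= 0 || s <= 0)
    stop("cpp_rhs: non-finite or non-positive state (t=%g, w=%g, s=%g)",
         t, w, s);
  EnvGrid env{env_t0, env_dt, envT.begin(), envRH.begin(),
              (int)envT.size()};
  Fluxes f = rhs_at(t, w, s, par.begin(), gen.begin(), plant.begin(), env);
  return List::create(
      _["Pf"] = f.Pf, _["regime"] = f.growing ? "growing" : "static",
      _["resid"] = f.resid, _["Ux"] = f.Ux, _["Up"] = f.Up, _["Ua"] = f.Ua,
      _["Um"] = f.Um, _["Ud"] = f.Ud, _["Us"] = f.Us, _["Tf"] = f.Tf,
      _["Rf"] = f.Rf, _["dwdt"] = f.dwdt, _["dsdt"] = f.dsdt);
}

struct Budget {
  double Ux = 0, Up = 0, Us = 0, Tf = 0, Rf = 0;
  double maxResid = 0;
};

// one RK4 step with positivity guard (recursive halving down to hMin);
// budgets accumulate the same RK4 quadrature that advances the state
static void advance(double &t, double &w, double &s, double h, double hMin,
                    const double *par, const double *gen, const double *plant,
                    const EnvGrid &env, Budget &bud) {
  Fluxes k1 = rhs_at(t, w, s, par, gen, plant, env);
  Fluxes k2 = rhs_at(t + h / 2, w + h / 2 * k1.dwdt, s + h / 2 * k1.dsdt,
                     par, gen, plant, env);
  Fluxes k3 = rhs_at(t + h / 2, w + h / 2 * k2.dwdt, s + h / 2 * k2.dsdt,
                     par, gen, plant, env);
  Fluxes k4 = rhs_at(t + h, w + h * k3.dwdt, s + h * k3.dsdt,
                     par, gen, plant, env);
  double dw = h / 6 * (k1.dwdt + 2 * k2.dwdt + 2 * k3.dwdt + k4.dwdt);
  double ds = h / 6 * (k1.dsdt + 2 * k2.dsdt + 2 * k3.dsdt + k4.dsdt);
  if (!std::isfinite(dw) || !std::isfinite(ds) ||
      w + dw <= 0 || s + ds <= 0) {
    if (h / 2 < hMin)
      stop("integration step underflow at t=%g h (w=%g, s=%g): "
           "non-physical inputs", t, w, s);
    advance(t, w, s, h / 2, hMin, par, gen, plant, env, bud);
    advance(t, w, s, h / 2, hMin, par, gen, plant, env, bud);
    return;
  }
#define ACC(fld) bud.fld += h / 6 * (k1.fld + 2 * k2.fld + 2 * k3.fld + k4.fld)
  ACC(Ux); ACC(Up); ACC(Us); ACC(Tf); ACC(Rf);
#undef ACC
  double r = std::max(std::max(std::fabs(k1.resid), std::fabs(k2.resid)),
                      std::max(std::fabs(k3.resid), std::fabs(k4.resid)));
  if (r > bud.maxResid) bud.maxResid = r;
  t += h; w += dw; s += ds;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector par, NumericVector gen, NumericVector plant,
                  double env_t0, double env_dt, NumericVector envT,
                  NumericVector envRH, double t0, double tEnd, double dt,
                  double dtMin) {
  if (tEnd < t0) stop("tEnd < t0");
  EnvGrid env{env_t0, env_dt, envT.begin(), envRH.begin(), (int)envT.size()};
  const double *p = par.begin(), *g = gen.begin(), *pl = plant.begin();
  int nOut = (int)std::ceil((tEnd - t0) / dt - 1e-9) + 1;
  if (tEnd == t0) nOut = 1;
  NumericMatrix out(nOut, 14);
  Budget bud;
  double t = t0, w = p[P_W0], s = p[P_S0];
  for (int i = 0; i < nOut; ++i) {
    Fluxes f = rhs_at(t, w, s, p, g, pl, env);
    out(i, 0) = t; out(i, 1) = w; out(i, 2) = s; out(i, 3) = w + s;
    out(i, 4) = s / (w + s); out(i, 5) = f.Pf; out(i, 6) = f.growing;
    out(i, 7) = f.Ux; out(i, 8) = f.Up; out(i, 9) = f.Us; out(i, 10) = f.Tf;
    out(i, 11) = f.Rf; out(i, 12) = f.Ua; out(i, 13) = f.Um;
    if (i == nOut - 1) break;
    double h = std::min(dt, tEnd - t);
    advance(t, w, s, h, dtMin, p, g, pl, env, bud);
  }
  return List::create(
      _["traj"] = out,
      _["budget"] = NumericVector::create(
          _["Ux"] = bud.Ux, _["Up"] = bud.Up, _["Us"] = bud.Us,
          _["Tf"] = bud.Tf, _["Rf"] = bud.Rf),
      _["maxResid"] = bud.maxResid);
}

// integrate and report (w, s) at requested times (sorted, >= t0);
// linear interpolation between integration grid points
// [[Rcpp::export]]
NumericMatrix cpp_sim_masses(NumericVector par, NumericVector gen,
                             NumericVector plant, double env_t0,
                             double env_dt, NumericVector envT,
                             NumericVector envRH, double t0,
                             NumericVector times, double dt, double dtMin) {
  int nt = times.size();
  NumericMatrix out(nt, 2);  // w, s
  if (nt == 0) return out;
  double tEnd = times[nt - 1];
  if (times[0] < t0) stop("requested time before t0");
  EnvGrid env{env_t0, env_dt, envT.begin(), envRH.begin(), (int)envT.size()};
  const double *p = par.begin(), *g = gen.begin(), *pl = plant.begin();
  Budget bud;
  double t = t0, w = p[P_W0], s = p[P_S0];
  int j = 0;
  while (j < nt && times[j] <= t + 1e-9) {
    out(j, 0) = w; out(j, 1) = s; ++j;
  }
  while (t < tEnd - 1e-9) {
    double h = std::min(dt, tEnd - t);
    double tPrev = t, wPrev = w, sPrev = s;
    advance(t, w, s, h, dtMin, p, g, pl, env, bud);
    while (j < nt && times[j] <= t + 1e-9) {
      double u = (times[j] - tPrev) / (t - tPrev);
      out(j, 0) = wPrev + u * (w - wPrev);
      out(j, 1) = sPrev + u * (s - sPrev);
      ++j;
    }
  }
  while (j < nt) { out(j, 0) = w; out(j, 1) = s; ++j; }
  return out;
}
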
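#' @useDynLib virtualfruit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reference R implementations of the elementary model operations.  The
# compiled integrator in src/ re-derives the same quantities; the test
# suite pins the two paths together on random states, so these functions
# are the readable single source of truth for the functional forms.

#' Soluble sugar fraction of the dry mass
#'
#' Linear in time, `assrat * t/24 + bssrat`, clipped to `[0, 1]`.
#'
#' @param t time since anthesis (h)
#' @param assrat slope (day^-1)
#' @param bssrat intercept (dimensionless)
#' @export
soluble_sugar_fraction <- function(t, assrat, bssrat) {
  stopifnot(all(t >= 0))
  pmin(pmax(assrat * t / 24 + bssrat, 0), 1)
}

#' Reflection coefficient of the composite membrane
#'
#' `sigma_p(t) = 1 - exp(-tauS * t^2)`: the membrane becomes progressively
#' semipermeable, shutting down the mass-flow component of sugar uptake.
#'
#' @param t time since anthesis (h)
#' @param tauS rise rate (h^-2), positive
#' @export
reflection_coefficient <- function(t, tauS) {
  stopifnot(all(t >= 0), all(tauS > 0))
  1 - exp(-tauS * t^2)
}

#' Active sugar uptake (Michaelis-Menten with logistic decline)
#'
#' `nu(t) * Cp / (Km + Cp)` with `nu(t) = nuM / (1 + exp((t - tstar)/tauA))`,
#' evaluated overflow-safely; the result always lies in `[0, nuM]`.
#'
#' @param t time (h)
#' @param Cp phloem sugar concentration (g g^-1)
#' @param nuM maximal uptake rate (g h^-1)
#' @param tstar decline onset (h)
#' @param tauA decline time scale (h)
#' @param Km Michaelis constant (g g^-1)
#' @export
active_uptake <- function(t, Cp, nuM, tstar, tauA, Km) {
  stopifnot(Cp > 0)
  z <- (t - tstar) / tauA
  nu <- ifelse(z > 50, nuM * exp(-z), nuM / (1 + exp(z)))
  nu * Cp / (Km + Cp)
}

#' Fruit volume and surface area from the water and dry masses
#'
#' `V = w + s/rhoS` (water density 1 g cm^-3) and the allometric surface
#' `Af = gammaA * V^(2/3)`; the default `gammaA = (36*pi)^(1/3)` is exact
#' for a sphere.
#'
#' @param w,s water and dry mass (g), positive
#' @param rhoS dry-matter density (g cm^-3)
#' @param gammaA allometry coefficient
#' @return list with `V` (cm^3) and `Af` (cm^2)
#' @export
fruit_geometry <- function(w, s, rhoS = 1.6, gammaA = (36 * pi)^(1 / 3)) {
  stopifnot(all(w > 0), all(s > 0))
  V <- w + s / rhoS
  list(V = V, Af = gammaA * V^(2 / 3))
}

# van 't Hoff osmotic pressure (bar) of conc g solute per g water
vant_hoff_bar <- function(conc, T_C, Msugar = 180) {
  conc / Msugar * 83.14 * (T_C + 273.15)
}

#' Fruit osmotic pressure
#'
#' Sugar contribution by van 't Hoff (concentration expressed as g sugar
#' per g water, `ssrat(t) * s / w`), plus the measured osmotic pressure of
#' non-sugar solutes.
#'
#' @inheritParams fruit_geometry
#' @param t time (h)
#' @param T_C temperature (C)
#' @param piOther non-sugar osmotic pressure (bar)
#' @param assrat,bssrat soluble-sugar fraction coefficients
#' @param Msugar sugar molar mass (g mol^-1)
#' @export
osmotic_pressure <- function(w, s, t, T_C, piOther, assrat, bssrat,
                             Msugar = 180) {
  stopifnot(all(w > 0))
  ssrat <- soluble_sugar_fraction(t, assrat, bssrat)
  vant_hoff_bar(ssrat * s / w, T_C, Msugar) + piOther
}

# saturation vapour density (g cm^-3), Buck/Magnus saturation pressure
vapour_density <- function(T_C) {
  psat <- 611.21 * exp(17.502 * T_C / (240.97 + T_C))  # Pa
  18.015 * psat / (8.314 * (T_C + 273.15)) * 1e-6
}

#' Fruit transpiration
#'
#' Surface-proportional vapour loss `Af * rhoSurf * alpha(T) * (Hf - RH)`,
#' floored at zero (no condensation gain is modelled).
#'
#' @param Af fruit surface area (cm^2)
#' @param T_C temperature (C)
#' @param RH air relative humidity (fraction)
#' @param rhoSurf surface conductance (cm h^-1)
#' @param Hf internal relative humidity (fraction)
#' @return water loss rate (g h^-1)
#' @export
transpiration <- function(Af, T_C, RH, rhoSurf, Hf = 0.996) {
  stopifnot(all(Af > 0))
  pmax(Af * rhoSurf * vapour_density(T_C) * (Hf - RH), 0)
}

#' Diurnal stem water potential
#'
#' Half-cosine interpolation between the predawn value (daily maximum, at
#' 05:00) and the midday value (daily minimum, at 13:00), repeated daily.
#'
#' @param t time (h since anthesis; hour-of-day is `t mod 24`)
#' @param psiPre,psiMid predawn and midday stem water potential (bar)
#' @export
stem_water_potential <- function(t, psiPre, psiMid) {
  h <- t %% 24
  f <- ifelse(h >= 5 & h < 13,
              0.5 * (1 - cos(pi * (h - 5) / 8)),
              0.5 * (1 + cos(pi * ((h - 13) %% 24) / 16)))
  psiPre + f * (psiMid - psiPre)
}

#' Water inflows through the xylem and phloem pathways
#'
#' Each pathway is a pedicel conduit in series with a composite-membrane
#' element scaled by the vascular area.  Xylem sap is treated as pure
#' water (fully reflected at the membrane); along the phloem the membrane
#' reflects the fraction `sigma_p(t)` of the osmotic gradient.  Both fluxes
#' are linear and strictly decreasing in the fruit turgor `Pf`, and the
#' series form conserves flow through the vasculature node exactly.
#'
#' @param Pf fruit turgor pressure (bar)
#' @param w,s state masses (g)
#' @param t time (h)
#' @param T_C temperature (C)
#' @param genotype [genotype_params()]
#' @param inputs [plant_inputs()]
#' @param generic [generic_params()]
#' @return list with `Ux`, `Up` (g h^-1) and the conductances/driving
#'   forces `kx`, `kp`, `Dx`, `Dp` used by downstream operations
#' @export
water_fluxes <- function(Pf, w, s, t, T_C, genotype, inputs, generic) {
  if (!all(is.finite(c(Pf, w, s, t, T_C)))) stop("water_fluxes: non-finite input")
  stopifnot(Pf >= 0)
  geo <- fruit_geometry(w, s, generic$rhoS, generic$gammaA)
  lx <- genotype_lx(genotype)
  bssrat <- if (is.na(genotype$bssrat)) inputs$bssrat else genotype$bssrat
  pif <- osmotic_pressure(w, s, t, T_C, inputs$piOther, inputs$assrat,
                          bssrat, generic$Msugar)
  pip <- vant_hoff_bar(inputs$Cp, T_C, generic$Msugar)
  sig <- reflection_coefficient(t, genotype$tauS)
  psi <- stem_water_potential(t, inputs$psiStemPredawn, inputs$psiStemMidday)
  kx <- 1 / (1 / lx[["lx1"]] + 1 / (generic$ax * geo$Af * lx[["lx"]]))
  kp <- 1 / (1 / genotype$lp1 + 1 / (generic$ap * geo$Af * genotype$Lp))
  Dx <- psi + pif
  Dp <- psi + pip - sig * (pip - pif)
  list(Ux = kx * (Dx - Pf), Up = kp * (Dp - Pf),
       kx = kx, kp = kp, Dx = Dx, Dp = Dp)
}

#' Sugar uptake from the phloem
#'
#' Three parallel mechanisms: active (Michaelis-Menten, declining
#' logistically after `tstar`), mass flow carried by the phloem water
#' influx (zeroed when `Up <= 0`; mean concentration `(Cp + Cf)/2` and
#' membrane passage factor `1 - sigma_p`), and Fickian diffusion down the
#' concentration gradient.
#'
#' @param Up phloem water inflow (g h^-1), computed at the same `(Pf, t)`
#' @inheritParams water_fluxes
#' @return list with `Ua`, `Um`, `Ud` and their sum `Us` (g h^-1)
#' @export
sugar_flux <- function(Up, w, s, t, T_C, genotype, inputs, generic) {
  geo <- fruit_geometry(w, s, generic$rhoS, generic$gammaA)
  bssrat <- if (is.na(genotype$bssrat)) inputs$bssrat else genotype$bssrat
  Cf <- soluble_sugar_fraction(t, inputs$assrat, bssrat) * s / w
  sig <- reflection_coefficient(t, genotype$tauS)
  nuM <- if (generic$active_uptake_scaling == "dry_mass")
    genotype$nuM * s else genotype$nuM
  Ua <- active_uptake(t, inputs$Cp, nuM, genotype$tstar, genotype$tauA,
                      generic$Km)
  Um <- (1 - sig) * (inputs$Cp + Cf) / 2 * max(Up, 0)
  Ud <- generic$ps * generic$ap * geo$Af * (inputs$Cp - Cf)
  list(Ua = Ua, Um = Um, Ud = Ud, Us = Ua + Um + Ud)
}

#' Growth and maintenance respiration, coupled to dry-mass change
#'
#' Respiration `Rf = qg * ds/dt + qm(T) * s` depends on the growth rate it
#' itself reduces; the implicit pair is solved in closed form:
#' `ds/dt = (Us - qm(T) s) / (1 + qg)` and `Rf = Us - ds/dt`.
#'
#' @param Us total sugar uptake (g h^-1)
#' @param s dry mass (g)
#' @param T_C temperature (C)
#' @param generic [generic_params()]
#' @return list with `dsdt` and `Rf` (g h^-1)
#' @export
respiration_coupled <- function(Us, s, T_C, generic = generic_params()) {
  stopifnot(all(s > 0))
  qm <- generic$qm20 * generic$Q10^((T_C - 20) / 10)
  dsdt <- (Us - qm * s) / (1 + generic$qg)
  list(dsdt = dsdt, Rf = Us - dsdt)
}

# net mass-balance rates at a prescribed turgor (helper for the root solve)
mass_balance_rates <- function(Pf, w, s, t, T_C, RH, genotype, inputs,
                               generic) {
  wf <- water_fluxes(Pf, w, s, t, T_C, genotype, inputs, generic)
  sf <- sugar_flux(wf$Up, w, s, t, T_C, genotype, inputs, generic)
  rr <- respiration_coupled(sf$Us, s, T_C, generic)
  geo <- fruit_geometry(w, s, generic$rhoS, generic$gammaA)
  Tf <- transpiration(geo$Af, T_C, RH, inputs$rhoSurf, generic$Hf)
  dwdt <- wf$Ux + wf$Up + generic$rw * rr$Rf - Tf
  list(dwdt = dwdt, dsdt = rr$dsdt, dVdt = dwdt + rr$dsdt / generic$rhoS,
       Ux = wf$Ux, Up = wf$Up, Us = sf$Us, Ua = sf$Ua, Um = sf$Um,
       Ud = sf$Ud, Tf = Tf, Rf = rr$Rf, V = geo$V)
}

#' Solve the turgor balance at one instant
#'
#' Finds the fruit turgor `Pf >= 0` equating the Lockhart expansion rate
#' `V * phi(t) * max(Pf - Y, 0)` (with `phi(t) = phiMax * exp(-t/tauPhi)`)
#' to the volume change implied by the mass balance.  The mass-balance
#' rate is strictly decreasing in `Pf` and the Lockhart rate
#' non-decreasing, so the root is unique.  If the balancing turgor would
#' be negative, `Pf = 0` is returned and the volume change takes its
#' (possibly negative) value there.
#'
#' This implementation brackets and bisects via [stats::uniroot()]; the
#' compiled integrator uses the equivalent closed-form piecewise-linear
#' solution.  `regime` is `"growing"` when `Pf > Y`, `"static"` otherwise.
#'
#' @inheritParams water_fluxes
#' @param RH air relative humidity (fraction)
#' @return list with `Pf`, `regime`, and the residual of the balance
#'   (relative, in cm^3 h^-1)
#' @export
solve_turgor <- function(w, s, t, T_C, RH, genotype, inputs, generic) {
  phi <- genotype$phiMax * exp(-t / generic$tauPhi)
  Y <- generic$Y
  V <- fruit_geometry(w, s, generic$rhoS, generic$gammaA)$V
  g <- function(Pf) {
    mb <- mass_balance_rates(Pf, w, s, t, T_C, RH, genotype, inputs,
                             generic)
    mb$dVdt - V * phi * max(Pf - Y, 0)
  }
  g0 <- g(0)
  if (g0 <= 0)
    return(list(Pf = 0, regime = "static", resid = 0))
  bssrat <- if (is.na(genotype$bssrat)) inputs$bssrat else genotype$bssrat
  pif <- osmotic_pressure(w, s, t, T_C, inputs$piOther, inputs$assrat,
                          bssrat, generic$Msugar)
  pip <- vant_hoff_bar(inputs$Cp, T_C, generic$Msugar)
  psi <- stem_water_potential(t, inputs$psiStemPredawn, inputs$psiStemMidday)
  hi <- psi + pip + pif + 100
  if (g(hi) > 0)
    stop(sprintf(paste0("solve_turgor: no root in [0, %g] at t=%g, w=%g, ",
                        "s=%g"), hi, t, w, s))
  Pf <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  dV <- mass_balance_rates(Pf, w, s, t, T_C, RH, genotype, inputs,
                           generic)$dVdt
  list(Pf = Pf,
       regime = if (Pf > Y) "growing" else "static",
       resid = (dV - V * phi * max(Pf - Y, 0)) / max(1, abs(dV)))
}

env_interp <- function(env, t) {
  T_C <- stats::approx(env$t_h, env$T_C, xout = t, rule = 2)$y
  RH <- stats::approx(env$t_h, env$RH, xout = t, rule = 2)$y
  list(T_C = T_C, RH = RH)
}

#' Advance the fruit state by one time step
#'
#' Fourth-order Runge-Kutta step of the water/dry-mass balance, with the
#' turgor balance re-solved at every stage evaluation.  Steps that would
#' drive a mass non-positive are re-taken at half the step, down to
#' `dt_min` (below which an error signals non-physical inputs).
#'
#' @param state list with `t` (h), `w`, `s` (g)
#' @param dt step (h), positive
#' @param genotype,inputs,generic model parameters
#' @param env [env_series()]
#' @param dt_min smallest admissible sub-step (h)
#' @return updated state list (`t`, `w`, `s`, plus diagnostic `Pf`,
#'   `regime` at the new time)
#' @export
step_fruit <- function(state, dt, genotype, inputs, env,
                       generic = generic_params(), dt_min = 1 / 64) {
  stopifnot(dt > 0)
  res <- cpp_simulate(genotype_par_vector_at(genotype, inputs, state),
                      generic_par_vector(generic),
                      plant_par_vector(inputs),
                      env$t_h[1], env$t_h[2] - env$t_h[1],
                      env$T_C, env$RH, state$t, state$t + dt, dt, dt_min)
  tr <- res$traj
  n <- nrow(tr)
  list(t = tr[n, 1], w = tr[n, 2], s = tr[n, 3], Pf = tr[n, 6],
       regime = if (tr[n, 7] > 0.5) "growing" else "static")
}

# pack a genotype vector but with initial masses taken from a state
genotype_par_vector_at <- function(genotype, inputs, state) {
  v <- genotype_par_vector(genotype, inputs)
  v[12] <- state$w
  v[13] <- state$s
  v
}

#' Simulate one fruit from early development to a stated end time
#'
#' Integrates the water and dry-mass balances hourly from `t0` (default
#' 192 h = 8 days after anthesis) to `tEnd`, with the stem water potential
#' following its diurnal course and the climate interpolated from the
#' hourly series.  Deterministic: no random number is drawn.
#'
#' @param genotype [genotype_params()]
#' @param inputs [plant_inputs()]; supplies the initial masses unless the
#'   genotype carries ideotype-mode `w0`/`s0`
#' @param env [env_series()]
#' @param t0,tEnd simulation window (h since anthesis)
#' @param dt integration/reporting step (h)
#' @param generic [generic_params()]
#' @param dt_min smallest admissible sub-step (h)
#' @return a `fruit_trajectory`: data.frame with hourly state (`t_h`,
#'   `w_g`, `s_g`, `fm_g`, `dm_frac`, `Pf_bar`, `regime`) and diagnostic
#'   fluxes (`Ux`, `Up`, `Us`, `Tf`, `Rf`, `Ua`, `Um`), with attributes
#'   `budget` (exact RK4-quadrature integrals of the five fluxes over the
#'   run) and `max_resid` (largest turgor-balance residual seen)
#' @export
simulate_fruit <- function(genotype, inputs, env, t0 = 192, tEnd,
                           dt = 1, generic = generic_params(),
                           dt_min = 1 / 64) {
  stopifnot(inherits(env, "env_series"), tEnd >= t0)
  res <- tryCatch(
    cpp_simulate(genotype_par_vector(genotype, inputs),
                 generic_par_vector(generic), plant_par_vector(inputs),
                 env$t_h[1], env$t_h[2] - env$t_h[1], env$T_C, env$RH,
                 t0, tEnd, dt, dt_min),
    error = function(e) stop("simulate_fruit [", inputs$treatment, "]: ",
                             conditionMessage(e), call. = FALSE))
  tr <- res$traj
  out <- data.frame(t_h = tr[, 1], w_g = tr[, 2], s_g = tr[, 3],
                    fm_g = tr[, 4], dm_frac = tr[, 5], Pf_bar = tr[, 6],
                    regime = ifelse(tr[, 7] > 0.5, "growing", "static"),
                    Ux = tr[, 8], Up = tr[, 9], Us = tr[, 10],
                    Tf = tr[, 11], Rf = tr[, 12], Ua = tr[, 13],
                    Um = tr[, 14])
  structure(out, class = c("fruit_trajectory", "data.frame"),
            budget = res$budget, max_resid = res$maxResid,
            treatment = inputs$treatment)
}

#' Simulated water and dry mass at requested times
#'
#' Fast path used by calibration: integrates once up to the last requested
#' time and reads the state at each time (linear interpolation between
#' grid points).
#'
#' @inheritParams simulate_fruit
#' @param times_h requested times (h), sorted, all `>= t0`
#' @return data.frame with `t_h`, `w_g`, `s_g`, `fm_g`, `dm_frac`
#' @export
simulate_at <- function(genotype, inputs, env, times_h, t0 = 192, dt = 1,
                        generic = generic_params(), dt_min = 1 / 64) {
  stopifnot(!is.unsorted(times_h))
  m <- cpp_sim_masses(genotype_par_vector(genotype, inputs),
                      generic_par_vector(generic), plant_par_vector(inputs),
                      env$t_h[1], env$t_h[2] - env$t_h[1], env$T_C, env$RH,
                      t0, as.numeric(times_h), dt, dt_min)
  data.frame(t_h = times_h, w_g = m[, 1], s_g = m[, 2],
             fm_g = m[, 1] + m[, 2], dm_frac = m[, 2] / (m[, 1] + m[, 2]))
}
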
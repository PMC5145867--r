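# Elementary operations of the fruit model, and the integrator.

test_that("soluble sugar fraction is linear in time and clipped", {
  expect_equal(soluble_sugar_fraction(0, 0.002, 0.1), 0.1)
  expect_equal(soluble_sugar_fraction(240, 0.002, 0.1), 0.12)
  expect_equal(soluble_sugar_fraction(1e6, 0.002, 0.1), 1.0)
  expect_equal(soluble_sugar_fraction(100, 0.002, -1), 0)
})

test_that("reflection coefficient rises from 0, monotone in t and tauS", {
  expect_equal(reflection_coefficient(0, 1.5e-5), 0)
  expect_equal(reflection_coefficient(300, 1.5e-5), 1 - exp(-1.35))
  t <- seq(10, 1000, by = 10)
  s1 <- reflection_coefficient(t, 7e-6)
  s2 <- reflection_coefficient(t, 1.4e-5)
  expect_true(all(diff(s1) > 0))
  expect_true(all(s2 > s1))
  expect_true(all(s2 < 1))
})

test_that("active uptake: logistic midpoint, tail, saturation, overflow", {
  Cp <- 0.14; Km <- 0.08; nuM <- 0.1
  expect_equal(active_uptake(500, Cp, nuM, 500, 50, Km),
               nuM / 2 * Cp / (Km + Cp))
  expect_equal(active_uptake(500 + 10 * 50, Cp, nuM, 500, 50, Km),
               nuM / (1 + exp(10)) * Cp / (Km + Cp), tolerance = 1e-12)
  # saturation factor -> 1 for Cp >> Km
  expect_equal(active_uptake(0, 1e4, nuM, 500, 50, Km) /
                 (nuM / (1 + exp(-10))), 1, tolerance = 1e-3)
  # overflow-safe far past the decline onset
  v <- active_uptake(1e7, Cp, nuM, 500, 50, Km)
  expect_true(is.finite(v) && v >= 0 && v <= nuM)
})

test_that("fruit geometry: sphere identity, 2/3-power scaling, volume", {
  g <- fruit_geometry(1, 1e-12)
  expect_equal(g$V, 1, tolerance = 1e-9)
  expect_equal(g$Af, (36 * pi)^(1 / 3), tolerance = 1e-9)
  g1 <- fruit_geometry(2, 0.4)
  g8 <- fruit_geometry(16, 3.2)
  expect_equal(g8$V, 8 * g1$V)
  expect_equal(g8$Af, 4 * g1$Af)
  expect_equal(fruit_geometry(8, 1.6, rhoS = 1.6)$V, 9)
})

test_that("osmotic pressure: van 't Hoff sugar term plus piOther", {
  # no sugar
  expect_equal(osmotic_pressure(1, 1e-15, 0, 20, 2, 0.002, 0.1), 2,
               tolerance = 1e-9)
  # linearity in s
  p1 <- osmotic_pressure(1, 0.05, 0, 20, 0, 0, 1)
  p2 <- osmotic_pressure(1, 0.10, 0, 20, 0, 0, 1)
  expect_equal(p2, 2 * p1)
  # closed-form value: 0.05 g sugar per g water at 20 C, hexose
  expect_equal(p1, 0.05 / 180 * 83.14 * 293.15, tolerance = 1e-12)
})

test_that("transpiration: equilibrium, floor, surface proportionality", {
  expect_equal(transpiration(50, 22, 0.996, 30, Hf = 0.996), 0)
  expect_equal(transpiration(50, 22, 0.999, 30, Hf = 0.996), 0)
  t1 <- transpiration(50, 22, 0.6, 30)
  expect_equal(transpiration(100, 22, 0.6, 30), 2 * t1)
  expect_gt(transpiration(50, 30, 0.6, 30), t1)  # increasing in T
})

test_that("stem water potential: predawn max at 05:00, midday min at 13:00", {
  psi <- stem_water_potential(0:47, -2, -6)
  expect_equal(stem_water_potential(5, -2, -6), -2)
  expect_equal(stem_water_potential(13, -2, -6), -6)
  expect_equal(stem_water_potential(29, -2, -6), -2)  # daily repeat
  expect_true(all(psi >= -6 & psi <= -2))
})

test_that("water fluxes: zero driving force and membrane-limited limit", {
  g <- fix_genotype(); inp <- plant_inputs(); gen <- generic_params()
  w <- 5; s <- 0.5; t <- 400; T_C <- 22
  pif <- osmotic_pressure(w, s, t, T_C, inp$piOther, inp$assrat,
                          inp$bssrat, gen$Msugar)
  psi <- stem_water_potential(t, inp$psiStemPredawn, inp$psiStemMidday)
  wf <- water_fluxes(max(psi + pif, 0), w, s, t, T_C, g, inp, gen)
  expect_equal(wf$Ux, 0, tolerance = 1e-12)
  # pedicel -> infinity: membrane-limited xylem flux
  g2 <- g; g2$lp1 <- 1e12 / g$rxp  # lx1 = rxp * lp1 huge
  wf2 <- water_fluxes(1, w, s, t, T_C, g2, inp, gen)
  Af <- fruit_geometry(w, s, gen$rhoS, gen$gammaA)$Af
  expect_equal(wf2$Ux, gen$ax * Af * (g2$rxp * g2$Lp) * (psi + pif - 1),
               tolerance = 1e-6)
  expect_error(water_fluxes(NaN, w, s, t, T_C, g, inp, gen), "non-finite")
})

test_that("series conductance equals two-node flow-balance oracle", {
  set.seed(2024)
  gen <- generic_params()
  worst <- 0
  for (i in 1:20) {
    inp <- rand_inputs()
    g <- sample_genotype()
    w <- runif(1, 0.3, 80); s <- w * runif(1, 0.05, 0.3)
    t <- runif(1, 192, 1300); T_C <- runif(1, 15, 32)
    Pf <- runif(1, 0, 10)
    wf <- water_fluxes(Pf, w, s, t, T_C, g, inp, gen)
    orc <- oracle_fluxes(Pf, w, s, t, T_C, g, inp, gen)
    worst <- max(worst,
                 abs(wf$Ux - orc$Ux) / max(1e-12, abs(orc$Ux)),
                 abs(wf$Up - orc$Up) / max(1e-12, abs(orc$Up)))
  }
  expect_lt(worst, 1e-9)
})

test_that("sugar flux: no gradient, semipermeable, no back-flow", {
  g <- fix_genotype(); inp <- plant_inputs(); gen <- generic_params()
  w <- 5; t <- 300; T_C <- 22
  # Cf == Cp -> no diffusion
  ssrat <- soluble_sugar_fraction(t, inp$assrat, inp$bssrat)
  s_eq <- inp$Cp * w / ssrat
  sf <- sugar_flux(0.5, w, s_eq, t, T_C, g, inp, gen)
  expect_equal(sf$Ud, 0, tolerance = 1e-12)
  # sigma -> 1 kills mass flow
  g2 <- g; g2$tauS <- 1  # fully reflecting within seconds
  sf2 <- sugar_flux(0.5, w, 0.5, t, T_C, g2, inp, gen)
  expect_equal(sf2$Um, 0, tolerance = 1e-10)
  # no solute export when phloem water flow reverses
  sf3 <- sugar_flux(-0.5, w, 0.5, t, T_C, g, inp, gen)
  expect_equal(sf3$Um, 0)
})

test_that("respiration couples to growth in closed form", {
  gen <- generic_params(qg = 0.2, qm20 = 0.002)
  r <- respiration_coupled(0.01, 1, 20, gen)   # qm*s = 0.002
  expect_equal(r$dsdt, 0.008 / 1.2)
  expect_equal(r$Rf, 0.01 - 0.008 / 1.2)
  # maintenance exactly consumes uptake
  r2 <- respiration_coupled(0.002, 1, 20, gen)
  expect_equal(r2$dsdt, 0)
  expect_equal(r2$Rf, 0.002)
  # Q10 doubles maintenance at +10 C
  r3 <- respiration_coupled(0, 1, 30, gen)
  expect_equal(r3$dsdt * (1 + gen$qg), -0.004)
})

test_that("turgor solve: Lockhart balance, regimes, limits", {
  gen <- generic_params()
  env <- fix_env()
  set.seed(5)
  for (i in 1:20) {
    inp <- rand_inputs(); g <- sample_genotype()
    w <- runif(1, 0.5, 40); s <- w * runif(1, 0.06, 0.25)
    t <- runif(1, 192, 1200)
    cl <- env_interp(env, t)
    sol <- solve_turgor(w, s, t, cl$T_C, cl$RH, g, inp, gen)
    expect_gte(sol$Pf, 0)
    expect_lt(abs(sol$resid), 1e-8)
    if (sol$regime == "growing") expect_gt(sol$Pf, gen$Y)
    # mass balance at the solved turgor matches the Lockhart rate
    mb <- mass_balance_rates(sol$Pf, w, s, t, cl$T_C, cl$RH, g, inp, gen)
    phi <- g$phiMax * exp(-t / gen$tauPhi)
    lock <- mb$V * phi * max(sol$Pf - gen$Y, 0)
    if (sol$Pf > 0)
      expect_lt(abs(mb$dVdt - lock), 1e-8 * max(1, abs(mb$dVdt)))
  }
  # extensibility -> 0: growing root collapses onto the static root
  g <- fix_genotype(); inp <- plant_inputs()
  g1 <- g; g1$phiMax <- 1e-12
  s1 <- solve_turgor(2, 0.2, 400, 22, 0.65, g1, inp, gen)
  g0 <- g; g0$phiMax <- 1e-300   # effectively zero
  s0 <- solve_turgor(2, 0.2, 400, 22, 0.65, g0, inp, gen)
  expect_lt(abs(s1$Pf - s0$Pf), 1e-4)
})

test_that("R operations and the compiled core agree on random states", {
  set.seed(77)
  gen <- generic_params()
  for (i in 1:100) {
    inp <- rand_inputs(); g <- sample_genotype()
    w <- runif(1, 0.3, 60); s <- w * runif(1, 0.05, 0.3)
    t <- runif(1, 192, 1300)
    T_C <- runif(1, 15, 32); RH <- runif(1, 0.4, 0.9)
    cc <- cpp_rhs(t, w, s, genotype_par_vector(g, inp),
                  generic_par_vector(gen), plant_par_vector(inp),
                  0, 1, rep(T_C, 2), rep(RH, 2))
    sol <- solve_turgor(w, s, t, T_C, RH, g, inp, gen)
    expect_lt(abs(cc$Pf - sol$Pf), 1e-7 * max(1, sol$Pf))
    mb <- mass_balance_rates(sol$Pf, w, s, t, T_C, RH, g, inp, gen)
    near <- function(a, b, tol = 1e-8)
      expect_lt(abs(a - b), tol * max(1, abs(b)))
    near(cc$dwdt, mb$dwdt)
    near(cc$dsdt, mb$dsdt)
    near(cc$Us, mb$Us)
    near(cc$Tf, mb$Tf)
  }
})

test_that("respired water: dw/dt = rw * Rf when all other fluxes vanish", {
  # conductances zero, transpiration suppressed, uptake active
  g <- genotype_params(phiMax = 1e-3, Lp = 0, nuM = 0.05, tstar = 900,
                       tauA = 100, tauS = 1e-5, lp1 = 0, rxp = 0.3)
  inp <- plant_inputs()
  env <- env_series(0:1400, rep(20, 1401), rep(0.996, 1401))
  gen <- generic_params(Hf = 0.996)
  tr <- simulate_fruit(g, inp, env, t0 = 192, tEnd = 292, generic = gen)
  bud <- attr(tr, "budget")
  expect_equal(bud[["Ux"]], 0)
  expect_equal(bud[["Up"]], 0)
  expect_equal(bud[["Tf"]], 0)
  expect_gt(bud[["Rf"]], 0)
  dw <- tr$w_g[nrow(tr)] - tr$w_g[1]
  expect_equal(dw, 9 / 16 * bud[["Rf"]], tolerance = 1e-10)
})

test_that("step: convergence under dt halving, positivity", {
  g <- fix_genotype(); inp <- plant_inputs(); env <- fix_env()
  t1 <- simulate_fruit(g, inp, env, tEnd = 1200, dt = 1)
  t2 <- simulate_fruit(g, inp, env, tEnd = 1200, dt = 0.5)
  n1 <- nrow(t1); n2 <- nrow(t2)
  expect_lt(abs(t1$w_g[n1] - t2$w_g[n2]) / t2$w_g[n2], 1e-3)
  expect_lt(abs(t1$s_g[n1] - t2$s_g[n2]) / t2$s_g[n2], 1e-3)
  st <- step_fruit(list(t = 192, w = 0.5, s = 0.05), 1, g, inp, env)
  expect_equal(st$t, 193)
  expect_true(st$w > 0 && st$s > 0)
})

test_that("simulate: degenerate window, determinism, WD direction", {
  g <- fix_genotype(); inp <- plant_inputs(); env <- fix_env()
  tr0 <- simulate_fruit(g, inp, env, tEnd = 192)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$w_g, inp$w0obs)
  expect_equal(tr0$s_g, inp$s0obs)
  trA <- simulate_fruit(g, inp, env, tEnd = 1200)
  trB <- simulate_fruit(g, inp, env, tEnd = 1200)
  expect_identical(trA$w_g, trB$w_g)    # bit-identical, no RNG
  wd <- make_treatment_inputs(inp, "WD")
  trW <- simulate_fruit(g, wd, env, tEnd = 1200)
  n <- nrow(trA)
  expect_lt(trW$fm_g[n], trA$fm_g[n])
  expect_gte(trW$dm_frac[n], trA$dm_frac[n])
})

test_that("trajectory invariants: dm in (0,1), budget closure, residuals", {
  set.seed(31)
  env <- fix_env()
  for (i in 1:5) {
    g <- sample_genotype(); inp <- rand_inputs()
    tr <- simulate_fruit(g, inp, env, tEnd = 50 * 24)
    expect_true(all(tr$dm_frac > 0 & tr$dm_frac < 1))
    expect_lt(attr(tr, "max_resid"), 1e-8)
    # exact quadrature budgets close the mass balances to round-off
    bud <- attr(tr, "budget")
    n <- nrow(tr)
    dw <- tr$w_g[n] - tr$w_g[1]
    ds <- tr$s_g[n] - tr$s_g[1]
    expect_equal(dw, bud[["Ux"]] + bud[["Up"]] + 9 / 16 * bud[["Rf"]] -
                   bud[["Tf"]], tolerance = 1e-9)
    expect_equal(ds, bud[["Us"]] - bud[["Rf"]], tolerance = 1e-9)
    # trapezoid over the reported hourly fluxes agrees within 0.5%
    trap <- function(x) sum((utils::head(x, -1) + x[-1]) / 2)
    dwTrap <- trap(tr$Ux) + trap(tr$Up) + 9 / 16 * trap(tr$Rf) -
      trap(tr$Tf)
    expect_lt(abs(dwTrap - dw) / max(abs(dw), 1e-6), 0.005)
  }
})

test_that("raising stem water potential never decreases final fresh mass", {
  set.seed(55)
  env <- fix_env()
  for (i in 1:20) {
    g <- sample_genotype(); inp <- rand_inputs()
    up <- inp
    up$psiStemPredawn <- min(inp$psiStemPredawn + 1, 0)
    up$psiStemMidday <- inp$psiStemMidday + 1
    f1 <- simulate_fruit(g, inp, env, tEnd = 1100)
    f2 <- simulate_fruit(g, up, env, tEnd = 1100)
    expect_gte(f2$fm_g[nrow(f2)], f1$fm_g[nrow(f1)] * (1 - 1e-9))
  }
})
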
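# Shared fixtures, built in code (no files).

fix_env <- function(nDays = 60) make_environment(nDays)

fix_genotype <- function() {
  b <- table1_bounds("calibration")
  mid <- exp((log(b[, "lower"]) + log(b[, "upper"])) / 2)
  do.call(genotype_params, as.list(mid))
}

# random but valid plant inputs (control condition)
rand_inputs <- function() {
  pre <- stats::runif(1, -4, -1)
  w0 <- stats::runif(1, 0.2, 0.8)
  plant_inputs(psiStemPredawn = pre,
               psiStemMidday = pre - stats::runif(1, 2, 5),
               Cp = stats::runif(1, 0.10, 0.18),
               rhoSurf = stats::runif(1, 15, 60),
               piOther = stats::runif(1, 3, 8),
               assrat = stats::runif(1, 0.004, 0.008),
               bssrat = stats::runif(1, 0.08, 0.16),
               w0obs = w0, s0obs = w0 * stats::runif(1, 0.08, 0.12))
}

# hand-constructed small-class ideotype: wall-limited growth (low phiMax),
# sustained moderate active uptake, narrow pedicel; verified feasible and
# selected by the decision filter under the default stated world
hand_ideotype <- function() {
  c(phiMax = 0.003, Lp = 0.1, nuM = 0.004, tstar = 600, tauA = 300,
    tauS = 1e-5, lp1 = 0.0028, rxp = 0.3, s0 = 0.03, w0 = 0.25,
    bssrat = 0.1)
}

# independent two-node flow-balance oracle for the pedicel + membrane
# pathways: root-find the vasculature node pressure so that pedicel flow
# equals membrane flow, then report the common flux
oracle_fluxes <- function(Pf, w, s, t, T_C, g, inp, gen) {
  Af <- fruit_geometry(w, s, gen$rhoS, gen$gammaA)$Af
  pif <- osmotic_pressure(w, s, t, T_C, inp$piOther, inp$assrat,
                          inp$bssrat, gen$Msugar)
  pip <- vant_hoff_bar(inp$Cp, T_C, gen$Msugar)
  sig <- reflection_coefficient(t, g$tauS)
  psi <- stem_water_potential(t, inp$psiStemPredawn, inp$psiStemMidday)
  lx <- genotype_lx(g)
  fx <- function(Pv) lx[["lx1"]] * (psi - Pv) -
    gen$ax * Af * lx[["lx"]] * (Pv - Pf + pif)
  Pvx <- stats::uniroot(fx, c(-1e4, 1e4), tol = 1e-13)$root
  fp <- function(Pv) g$lp1 * ((psi + pip) - Pv) -
    gen$ap * Af * g$Lp * (Pv - Pf - sig * (pip - pif))
  Pvp <- stats::uniroot(fp, c(-1e4, 1e4), tol = 1e-13)$root
  list(Ux = lx[["lx1"]] * (psi - Pvx),
       Up = g$lp1 * ((psi + pip) - Pvp))
}

# brute-force O(n^2 m) non-dominated sorting oracle
oracle_sort <- function(F, cv = rep(0, nrow(F))) {
  n <- nrow(F)
  dom <- function(i, j) dominates(F[i, ], F[j, ], cv[i], cv[j])
  rank <- integer(n)
  left <- seq_len(n)
  lev <- 0L
  while (length(left)) {
    lev <- lev + 1L
    nd <- left[vapply(left, function(i)
      !any(vapply(left, function(j) j != i && dom(j, i), logical(1))),
      logical(1))]
    rank[nd] <- lev
    left <- setdiff(left, nd)
  }
  rank
}
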
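#' Genotype-specific model parameters
#'
#' The parameter set that constitutes a genotype's phenotypic fingerprint.
#' Eight parameters are estimated during calibration; three more (`s0`,
#' `w0`, `bssrat`) are free only in ideotype-design mode and default to
#' `NA`, in which case the measured values carried by [plant_inputs()] are
#' used instead.
#'
#' The xylem conductivities are never stored: they derive from the
#' xylem:phloem ratio as `lx = rxp * Lp` (composite membrane) and
#' `lx1 = rxp * lp1` (pedicel), see [genotype_lx()].
#'
#' @param phiMax maximal cell-wall extensibility (bar^-1 h^-1)
#' @param Lp composite-membrane phloem water conductivity
#'   (g cm^-2 bar^-1 h^-1)
#' @param nuM maximal active sugar uptake rate (g h^-1)
#' @param tstar time at which active uptake starts to decline (h)
#' @param tauA time scale of the active-uptake decline (h); larger values
#'   mean a slower decline
#' @param tauS rise rate of the membrane reflection coefficient (h^-2)
#' @param lp1 pedicel phloem conductance (g bar^-1 h^-1)
#' @param rxp xylem:phloem conductivity ratio (dimensionless)
#' @param s0,w0 initial dry and water mass (g); ideotype mode only
#' @param bssrat intercept of the soluble-sugar fraction; ideotype mode only
#' @param check bounds mode to validate against (`"calibration"`,
#'   `"ideotype"`, or `NA` to skip bounds checking)
#' @return an object of class `genotype_params`
#' @seealso [table1_bounds()] for the admissible boxes
#' @export
genotype_params <- function(phiMax, Lp, nuM, tstar, tauA, tauS, lp1, rxp,
                            s0 = NA_real_, w0 = NA_real_,
                            bssrat = NA_real_, check = NA_character_) {
  g <- list(phiMax = phiMax, Lp = Lp, nuM = nuM, tstar = tstar,
            tauA = tauA, tauS = tauS, lp1 = lp1, rxp = rxp,
            s0 = s0, w0 = w0, bssrat = bssrat)
  num <- vapply(g, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) stop("genotype_params: all fields must be numeric scalars")
  if (!is.na(check)) {
    b <- table1_bounds(check)
    for (nm in rownames(b)) {
      v <- g[[nm]]
      if (is.na(v)) {
        if (check == "ideotype")
          stop("genotype_params: '", nm, "' required in ideotype mode")
        next
      }
      if (v < b[nm, "lower"] || v > b[nm, "upper"])
        stop(sprintf("genotype_params: %s = %g outside [%g, %g]",
                     nm, v, b[nm, "lower"], b[nm, "upper"]))
    }
  }
  structure(g, class = "genotype_params")
}

#' Derived xylem conductivities
#'
#' @param g a [genotype_params()] object
#' @return named vector with `lx = rxp * Lp` and `lx1 = rxp * lp1`
#' @export
genotype_lx <- function(g) {
  c(lx = g$rxp * g$Lp, lx1 = g$rxp * g$lp1)
}

#' Parameter search boxes
#'
#' Lower/upper boundaries of the genotypic parameters, for the calibration
#' search space (8 parameters) or the ideotype-design search space
#' (11 parameters, adding `s0`, `w0` and `bssrat`).
#'
#' @param mode `"calibration"` or `"ideotype"`
#' @return matrix with rownames = parameter names, columns `lower`, `upper`
#' @export
table1_bounds <- function(mode = c("calibration", "ideotype")) {
  mode <- match.arg(mode)
  if (mode == "calibration") {
    m <- rbind(
      phiMax = c(1e-4, 0.01),
      Lp     = c(5e-4, 0.4),
      nuM    = c(0.002, 0.15),
      tstar  = c(10, 900),
      tauA   = c(5, 900),
      tauS   = c(5e-6, 1.5e-5),
      lp1    = c(5e-5, 0.1),
      rxp    = c(0.1, 0.6))
  } else {
    m <- rbind(
      phiMax = c(0.002, 0.02),
      Lp     = c(0.02, 0.6),
      nuM    = c(0.002, 0.2),
      tstar  = c(10, 900),
      tauA   = c(72, 900),
      tauS   = c(1.5e-6, 2e-5),
      lp1    = c(0.002, 0.2),
      rxp    = c(0.1, 0.8),
      s0     = c(0.019, 0.086),
      w0     = c(0.126, 1.0),
      bssrat = c(0.043, 0.22))
  }
  colnames(m) <- c("lower", "upper")
  m
}

#' Generic (non-genotypic) model constants
#'
#' Constants of the fruit model that are held fixed across genotypes.  They
#' cannot be measured directly at the genotype level and are documented as
#' tunable defaults, not as truths; defaults are chosen so that a
#' mid-bounds genotype reaches a ripe fresh mass inside the observed
#' 5--160 g envelope.  The respiratory water conversion `rw = 9/16` is a
#' stoichiometric constant and cannot be overridden.
#'
#' @param Km Michaelis constant of active sugar uptake (g g^-1)
#' @param ps diffusion permeability of the membrane per unit area
#'   (g cm^-2 h^-1 per unit concentration difference)
#' @param ap,ax vascular-to-fruit-surface area ratios (phloem, xylem)
#' @param qg growth respiration coefficient (dimensionless)
#' @param qm20 maintenance respiration coefficient at 20 C (h^-1)
#' @param Q10 respiration temperature factor
#' @param Y Lockhart yield threshold (bar)
#' @param tauPhi decay time scale of wall extensibility (h)
#' @param Hf fruit internal relative humidity (fraction)
#' @param rhoS dry-matter density (g cm^-3)
#' @param Msugar molar mass of the transported sugar (g mol^-1); 180 for
#'   hexoses
#' @param gammaA surface-volume allometry coefficient; the default
#'   `(36*pi)^(1/3)` is the spherical value
#' @param active_uptake_scaling `"none"` (absolute uptake, g h^-1) or
#'   `"dry_mass"` (uptake proportional to dry mass)
#' @return object of class `generic_params`
#' @export
generic_params <- function(Km = 0.08, ps = 0.002, ap = 0.1, ax = 0.1,
                           qg = 0.15, qm20 = 2.5e-4, Q10 = 2, Y = 1,
                           tauPhi = 1500, Hf = 0.996, rhoS = 1.6,
                           Msugar = 180, gammaA = (36 * pi)^(1 / 3),
                           active_uptake_scaling = c("none", "dry_mass")) {
  active_uptake_scaling <- match.arg(active_uptake_scaling)
  g <- list(Km = Km, ps = ps, ap = ap, ax = ax, qg = qg, qm20 = qm20,
            Q10 = Q10, Y = Y, tauPhi = tauPhi, Hf = Hf, rhoS = rhoS,
            Msugar = Msugar, gammaA = gammaA, rw = 9 / 16,
            active_uptake_scaling = active_uptake_scaling)
  vals <- unlist(g[setdiff(names(g), "active_uptake_scaling")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("generic_params: all constants must be finite and positive")
  if (Hf > 1) stop("generic_params: Hf must satisfy 0 < Hf <= 1")
  structure(g, class = "generic_params")
}

#' Treatment-specific plant and initial-state inputs
#'
#' Measured (or emulated) inputs that carry the irrigation treatment into
#' the simulator: stem water potentials, phloem sap sugar concentration,
#' fruit surface conductance, non-sugar osmotic pressure, soluble-sugar
#' fraction coefficients, and the initial fruit masses at the start of the
#' simulated period.
#'
#' @param psiStemPredawn,psiStemMidday stem water potential (bar, <= 0) at
#'   predawn and at solar noon; midday must not exceed predawn
#' @param Cp phloem sap sugar concentration (g sugar per g water), held
#'   constant over fruit development
#' @param rhoSurf fruit surface conductance to water vapour (cm h^-1)
#' @param piOther osmotic pressure of non-sugar solutes (bar)
#' @param assrat slope of the soluble-sugar fraction (day^-1; converted to
#'   hours inside the model)
#' @param bssrat intercept of the soluble-sugar fraction (used when the
#'   genotype does not carry its own, i.e. outside ideotype mode)
#' @param w0obs,s0obs measured initial water and dry mass (g)
#' @param treatment `"C"` (control) or `"WD"` (water deficit)
#' @return object of class `plant_inputs`
#' @export
plant_inputs <- function(psiStemPredawn = -2, psiStemMidday = -6,
                         Cp = 0.14, rhoSurf = 30, piOther = 6,
                         assrat = 0.006, bssrat = 0.12,
                         w0obs = 0.5, s0obs = 0.05,
                         treatment = c("C", "WD")) {
  treatment <- match.arg(treatment)
  if (psiStemPredawn > 0 || psiStemMidday > psiStemPredawn)
    stop("plant_inputs: require psiStemMidday <= psiStemPredawn <= 0")
  if (Cp <= 0 || rhoSurf <= 0)
    stop("plant_inputs: Cp and rhoSurf must be positive")
  if (w0obs <= 0 || s0obs <= 0)
    stop("plant_inputs: initial masses must be positive")
  structure(list(psiStemPredawn = psiStemPredawn,
                 psiStemMidday = psiStemMidday, Cp = Cp,
                 rhoSurf = rhoSurf, piOther = piOther, assrat = assrat,
                 bssrat = bssrat, w0obs = w0obs, s0obs = s0obs,
                 treatment = treatment),
            class = "plant_inputs")
}

#' Hourly climate series
#'
#' @param t_h time since anthesis (h), strictly increasing on a uniform
#'   hourly-type grid
#' @param T_C air (= fruit) temperature (C)
#' @param RH relative humidity (fraction in `[0, 1]`)
#' @return data.frame of class `env_series`
#' @export
env_series <- function(t_h, T_C, RH) {
  if (length(t_h) < 2L) stop("env_series: need at least two records")
  d <- diff(t_h)
  if (any(d <= 0)) stop("env_series: t_h must be strictly increasing")
  if (max(d) - min(d) > 1e-8)
    stop("env_series: t_h must be a uniform grid")
  if (any(RH < 0 | RH > 1)) stop("env_series: RH must lie in [0, 1]")
  if (length(T_C) != length(t_h) || length(RH) != length(t_h))
    stop("env_series: column lengths differ")
  structure(data.frame(t_h = t_h, T_C = T_C, RH = RH),
            class = c("env_series", "data.frame"))
}

# ---- packed vectors for the C++ core (order fixed, see src/) --------------

genotype_par_vector <- function(genotype, inputs) {
  lx <- genotype_lx(genotype)
  bssrat <- if (is.na(genotype$bssrat)) inputs$bssrat else genotype$bssrat
  w0 <- if (is.na(genotype$w0)) inputs$w0obs else genotype$w0
  s0 <- if (is.na(genotype$s0)) inputs$s0obs else genotype$s0
  c(genotype$phiMax, genotype$Lp, genotype$nuM, genotype$tstar,
    genotype$tauA, genotype$tauS, genotype$lp1, lx[["lx"]], lx[["lx1"]],
    inputs$assrat, bssrat, w0, s0)
}

generic_par_vector <- function(generic) {
  c(generic$Km, generic$ps, generic$ap, generic$ax, generic$qg,
    generic$qm20, generic$Q10, generic$Y, generic$tauPhi, generic$Hf,
    generic$rhoS, generic$Msugar, generic$gammaA, generic$rw,
    as.numeric(generic$active_uptake_scaling == "dry_mass"))
}

plant_par_vector <- function(inputs) {
  c(inputs$psiStemPredawn, inputs$psiStemMidday, inputs$Cp,
    inputs$rhoSurf, inputs$piOther)
}
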
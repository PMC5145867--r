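# Synthetic recombinant-inbred-line populations: true parameter vectors,
# per-treatment plant inputs, greenhouse-like climate, and noisy fruit
# observations following the phenotyping design (3 fruits at each of
# three early stages, 15-20 fruits at ripeness, two treatments).

#' Sampling design of a synthetic phenotyping experiment
#'
#' @param nGenotypes number of genotypes
#' @param stages data.frame with columns `daa_min`, `daa_max`, `n`
#'   (fruits per stage); the ripe stage is handled separately
#' @param nRipe range (length-2) of the number of fruits sampled at
#'   ripeness
#' @param ripe_daa range (length-2) of the per-genotype ripeness age (days)
#' @param noiseCV multiplicative lognormal coefficient of variation
#'   applied per fruit to fresh mass and to dry-matter content
#' @param seed RNG seed
#' @export
synthetic_design <- function(nGenotypes = 20,
                             stages = data.frame(
                               daa_min = c(8, 12, 20),
                               daa_max = c(10, 15, 25),
                               n = c(3, 3, 3)),
                             nRipe = c(15, 20), ripe_daa = c(45, 60),
                             noiseCV = 0.05, seed = 1L) {
  stopifnot(noiseCV >= 0, all(stages$n >= 1))
  structure(list(nGenotypes = as.integer(nGenotypes), stages = stages,
                 nRipe = nRipe, ripe_daa = ripe_daa, noiseCV = noiseCV,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Draw one genotype inside the admissible box
#'
#' Log-uniform for parameters whose box spans two or more decades,
#' uniform otherwise.
#'
#' @param bounds box matrix (default calibration columns)
#' @param mode passed to [genotype_params()] validation
#' @export
sample_genotype <- function(bounds = table1_bounds("calibration"),
                            mode = "calibration") {
  tr <- search_transform(bounds)
  z <- stats::runif(nrow(bounds), tr$lower, tr$upper)
  x <- tr$from_search(z)
  names(x) <- rownames(bounds)
  do.call(genotype_params, c(as.list(x), list(check = mode)))
}

#' Emulated greenhouse climate
#'
#' Hourly sinusoidal temperature (default 18--28 C, warmest at 14:00) and
#' relative humidity (0.5--0.8, in antiphase with temperature), with
#' optional day-to-day jitter on the daily midpoints.
#'
#' @param nDays length of the series (days)
#' @param T_range,RH_range daily min/max of temperature and humidity
#' @param jitter standard deviation of the day-to-day midpoint jitter
#'   (degrees C; humidity jitter is scaled by the RH range)
#' @return [env_series()] starting at t = 0
#' @export
make_environment <- function(nDays = 60, T_range = c(18, 28),
                             RH_range = c(0.5, 0.8), jitter = 0) {
  t_h <- seq(0, nDays * 24 - 1)
  hod <- t_h %% 24
  day <- t_h %/% 24
  Tmid <- mean(T_range); Tamp <- diff(T_range) / 2
  Rmid <- mean(RH_range); Ramp <- diff(RH_range) / 2
  dT <- if (jitter > 0) stats::rnorm(nDays, 0, jitter) else numeric(nDays)
  T_C <- Tmid + dT[day + 1] + Tamp * cos(2 * pi * (hod - 14) / 24)
  RH <- Rmid - dT[day + 1] * (Ramp / Tamp) -
    Ramp * cos(2 * pi * (hod - 14) / 24)
  env_series(t_h, T_C, pmin(pmax(RH, 0), 1))
}

#' Derive treatment-specific plant inputs
#'
#' Water deficit is emulated through its measured consequences on the
#' model inputs: the stem water potential is shifted down, the initial
#' water mass reduced, and the non-sugar osmotic pressure raised.  The
#' phloem sugar concentration `Cp` is left identical across treatments.
#'
#' @param base [plant_inputs()] describing the control state
#' @param treatment `"C"` (returns `base`) or `"WD"`
#' @param dPsi downward shift of both stem water potentials (bar)
#' @param w0_scale multiplier on the initial water mass
#' @param piOther_scale multiplier on the non-sugar osmotic pressure
#' @export
make_treatment_inputs <- function(base, treatment = c("C", "WD"),
                                  dPsi = 3, w0_scale = 0.8,
                                  piOther_scale = 1.3) {
  treatment <- match.arg(treatment)
  if (treatment == "C") return(base)
  plant_inputs(psiStemPredawn = base$psiStemPredawn - dPsi,
               psiStemMidday = base$psiStemMidday - dPsi,
               Cp = base$Cp, rhoSurf = base$rhoSurf,
               piOther = base$piOther * piOther_scale,
               assrat = base$assrat, bssrat = base$bssrat,
               w0obs = base$w0obs * w0_scale, s0obs = base$s0obs,
               treatment = "WD")
}

#' Draw the ground truth of a synthetic population
#'
#' Per genotype: a true parameter vector inside the calibration box, a
#' ripeness age, and control/water-deficit plant inputs derived from a
#' common base.
#'
#' @param design [synthetic_design()]
#' @param base control-condition [plant_inputs()]
#' @param ... passed to [make_treatment_inputs()]
#' @return list of class `synthetic_truth` with one element per genotype:
#'   `genotype`, `ripe_daa`, `inputsC`, `inputsWD`, `id`
#' @export
sample_truth <- function(design, base = plant_inputs(), ...) {
  set.seed(design$seed)
  out <- lapply(seq_len(design$nGenotypes), function(i) {
    g <- sample_genotype()
    ripe <- sample(seq(design$ripe_daa[1], design$ripe_daa[2]), 1)
    list(id = sprintf("G%03d", i), genotype = g, ripe_daa = ripe,
         inputsC = make_treatment_inputs(base, "C", ...),
         inputsWD = make_treatment_inputs(base, "WD", ...))
  })
  structure(out, class = "synthetic_truth", seed = design$seed)
}

#' Generate noisy fruit observations from a synthetic truth
#'
#' For each genotype and treatment the truth trajectory is simulated once;
#' each sampled fruit draws an integer age uniformly inside its stage
#' window (the ripe stage uses the genotype's fixed ripeness age), reads
#' the simulated fresh mass and dry-matter content at that age, and
#' applies independent multiplicative lognormal noise with the design's
#' CV to both.  Dry mass is re-derived as content times fresh mass, which
#' keeps it below the fresh mass.  Genotypes whose truth cannot be
#' simulated are dropped with a warning.
#'
#' @param truth [sample_truth()] output
#' @param design [synthetic_design()]
#' @param env [env_series()]
#' @param generic [generic_params()]
#' @return observation table: `genotype`, `treatment`, `daa`, `fruit_id`,
#'   `fresh_g`, `dry_g`
#' @export
generate_observations <- function(truth, design, env,
                                  generic = generic_params()) {
  set.seed(design$seed + 1L)
  sdlog <- sqrt(log(1 + design$noiseCV^2))
  rows <- list()
  for (gt in truth) {
    daas <- unlist(Map(function(lo, hi, n) sample(seq(lo, hi), n,
                                                  replace = TRUE),
                       design$stages$daa_min, design$stages$daa_max,
                       design$stages$n))
    nR <- sample(seq(design$nRipe[1], design$nRipe[2]), 1)
    daas <- c(daas, rep(gt$ripe_daa, nR))
    daas <- sort(daas)
    for (tr in c("C", "WD")) {
      inputs <- if (tr == "C") gt$inputsC else gt$inputsWD
      sim <- tryCatch(
        simulate_at(gt$genotype, inputs, env, unique(daas) * 24,
                    generic = generic),
        error = function(e) NULL)
      if (is.null(sim)) {
        warning("dropping genotype ", gt$id, " (", tr,
                "): simulation failed")
        next
      }
      idx <- match(daas * 24, sim$t_h)
      fm <- sim$fm_g[idx] *
        stats::rlnorm(length(daas), -sdlog^2 / 2, sdlog)
      dm <- sim$dm_frac[idx] *
        stats::rlnorm(length(daas), -sdlog^2 / 2, sdlog)
      dm <- pmin(dm, 0.95)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = gt$id, treatment = tr, daa = daas,
        fruit_id = sprintf("%s_%s_f%02d", gt$id, tr, seq_along(daas)),
        fresh_g = fm, dry_g = dm * fm)
    }
  }
  if (!length(rows)) stop("generate_observations: no genotype simulated")
  do.call(rbind, rows)
}

#' Generate a full synthetic data set
#'
#' Convenience wrapper: climate, truth, observations.
#'
#' @inheritParams generate_observations
#' @param base control [plant_inputs()]
#' @param nDays climate length (days); defaults to covering the latest
#'   ripeness age
#' @return list with `env`, `truth`, `obs`, `design`
#' @export
synthesize_population <- function(design = synthetic_design(),
                                  base = plant_inputs(),
                                  generic = generic_params(),
                                  nDays = NULL) {
  if (is.null(nDays)) nDays <- design$ripe_daa[2] + 2
  set.seed(design$seed)
  env <- make_environment(nDays)
  truth <- sample_truth(design, base)
  obs <- generate_observations(truth, design, env, generic)
  list(env = env, truth = truth, obs = obs, design = design)
}
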
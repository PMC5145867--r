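# Genotype-wise estimation of the eight genotypic parameters from
# fresh/dry-mass time courses under control and water-deficit irrigation.

#' Normalized root mean squared error
#'
#' `100 * sqrt(mean((obs - sim)^2)) / mean(obs)`, in percent.  One entry
#' per sampled fruit, so stages with more fruits weigh more.
#'
#' @param obs,sim observed and simulated values, equal length, `n >= 1`
#' @export
nrmse <- function(obs, sim) {
  if (length(obs) != length(sim) || length(obs) < 1)
    stop("nrmse: obs and sim must have equal positive length")
  m <- mean(obs)
  if (m <= 0) stop("nrmse: mean(obs) must be positive")
  100 * sqrt(mean((obs - sim)^2)) / m
}

# split an observation table into per-treatment lists of (times_h, fresh,
# dry) sorted by time; times are daa * 24
obs_components <- function(obs) {
  lapply(split(obs, obs$treatment), function(d) {
    d <- d[order(d$daa), ]
    list(times_h = d$daa * 24, fresh = d$fresh_g, dry = d$dry_g)
  })
}

#' Calibration objectives for one parameter vector
#'
#' Simulates the SAME parameter vector under both treatments (genotypic
#' parameters are environment independent; only the plant inputs differ),
#' matches the simulated masses to every sampled fruit's age, and
#' aggregates the four error components into two objectives: `f1` = mean
#' of the fresh- and dry-mass NRMSE under control, `f2` = the same under
#' water deficit.
#'
#' @param x named parameter vector (the 8 calibrated parameters, natural
#'   units)
#' @param obs observation table (columns `treatment`, `daa`, `fresh_g`,
#'   `dry_g`) for one genotype, both treatments present
#' @param inputsC,inputsWD [plant_inputs()] per treatment
#' @param env [env_series()]
#' @param generic [generic_params()]
#' @param dt integration step (h)
#' @param penalty objective value substituted when a simulation fails
#' @return named vector `c(f1, f2, fC, dC, fWD, dWD)` (all NRMSE, percent)
#' @export
calibration_objectives <- function(x, obs, inputsC, inputsWD, env,
                                   generic = generic_params(), dt = 1,
                                   penalty = 1e6) {
  g <- do.call(genotype_params, as.list(x[c("phiMax", "Lp", "nuM", "tstar",
                                            "tauA", "tauS", "lp1", "rxp")]))
  comp <- obs_components(obs)
  if (!all(c("C", "WD") %in% names(comp)))
    stop("calibration_objectives: both treatments must be present")
  one <- function(inputs, co) {
    sim <- tryCatch(
      simulate_at(g, inputs, env, co$times_h, dt = dt, generic = generic),
      error = function(e) NULL)
    if (is.null(sim) || !all(is.finite(sim$fm_g)))
      return(c(f = penalty, d = penalty))
    c(f = nrmse(co$fresh, sim$fm_g), d = nrmse(co$dry, sim$s_g))
  }
  eC <- one(inputsC, comp$C)
  eWD <- one(inputsWD, comp$WD)
  c(f1 = mean(eC), f2 = mean(eWD),
    fC = eC[["f"]], dC = eC[["d"]], fWD = eWD[["f"]], dWD = eWD[["d"]])
}

#' Min-max selection over a Pareto archive
#'
#' Picks the solution minimizing its worst objective, `max(f1, f2)`;
#' ties broken by smaller `f1 + f2`, then by lexicographic order of the
#' parameter vector (deterministic).
#'
#' @param F objective matrix (two columns)
#' @param X parameter matrix aligned with `F`
#' @return index of the chosen row
#' @export
select_minmax <- function(F, X = NULL) {
  worst <- apply(F, 1, max)
  cand <- which(worst == min(worst))
  if (length(cand) > 1) {
    sums <- rowSums(F[cand, , drop = FALSE])
    cand <- cand[sums == min(sums)]
  }
  if (length(cand) > 1 && !is.null(X)) {
    o <- do.call(order, as.data.frame(X[cand, , drop = FALSE]))
    cand <- cand[o[1]]
  }
  cand[1]
}

#' Calibrate one genotype
#'
#' Runs NSGA-II `nRepeats` times (seeds `seed, seed+1, ...`) on the
#' two-objective aggregated-NRMSE problem over the calibration bounds
#' (parameters spanning two or more decades are searched in log10 space),
#' merges the per-repeat archives into a single non-dominated set, and
#' selects the final solution by the min-max criterion.
#'
#' @param obs observation table for this genotype (both treatments)
#' @param inputsC,inputsWD [plant_inputs()] per treatment
#' @param env [env_series()]
#' @param config [moea_config()]; its `seed` seeds the first repeat
#' @param nRepeats number of independent optimizer runs
#' @param bounds parameter box (default the calibration columns)
#' @param generic [generic_params()]
#' @param dt integration step (h)
#' @return list of class `calib_result`: `chosen` (named vector),
#'   `objectives` (f1, f2 and the four components at the chosen point),
#'   `archive` (merged `X`, `F`), `transform` metadata, `seeds`
#' @export
calibrate_genotype <- function(obs, inputsC, inputsWD, env,
                               config = moea_config(), nRepeats = 10,
                               bounds = table1_bounds("calibration"),
                               generic = generic_params(), dt = 1) {
  tr <- search_transform(bounds)
  nm <- rownames(bounds)
  comp <- obs_components(obs)
  evaluate <- function(Z) {
    Xn <- tr$from_search(Z)
    F <- matrix(0, nrow(Z), 2)
    for (i in seq_len(nrow(Z))) {
      x <- Xn[i, ]; names(x) <- nm
      o <- calibration_objectives(x, obs, inputsC, inputsWD, env,
                                  generic = generic, dt = dt)
      F[i, ] <- o[1:2]
    }
    list(F = F, G = NULL)
  }
  problem <- list(dim = nrow(bounds), lower = tr$lower, upper = tr$upper,
                  evaluate = evaluate)
  seeds <- config$seed + seq_len(nRepeats) - 1L
  Xs <- NULL; Fs <- NULL; rep_id <- integer(0)
  for (r in seq_len(nRepeats)) {
    cfg <- config; cfg$seed <- seeds[r]
    run <- nsga2_run(problem, cfg)
    Xs <- rbind(Xs, run$archive$X)
    Fs <- rbind(Fs, run$archive$F)
    rep_id <- c(rep_id, rep(r, nrow(run$archive$X)))
  }
  nd <- nondominated_indices(Fs)
  Xs <- Xs[nd, , drop = FALSE]; Fs <- Fs[nd, , drop = FALSE]
  rep_id <- rep_id[nd]
  Xnat <- tr$from_search(Xs)
  colnames(Xnat) <- nm
  pick <- select_minmax(Fs, Xnat)
  chosen <- Xnat[pick, ]
  objs <- calibration_objectives(chosen, obs, inputsC, inputsWD, env,
                                 generic = generic, dt = dt)
  structure(list(chosen = chosen, objectives = objs,
                 archive = list(X = Xnat, F = Fs, repeat_id = rep_id),
                 transform = tr$logmask, seeds = seeds),
            class = "calib_result")
}

#' Correlations among near-optimal parameter sets
#'
#' Diagnostic (not a gate): Pearson correlations between parameters over
#' the archive members whose worst objective is within `slack` of the
#' chosen solution's.
#'
#' @param result a `calib_result`
#' @param slack admissible worsening of `max(f1, f2)` (percent NRMSE)
#' @return correlation matrix, or `NULL` if fewer than 3 such solutions
#' @export
parameter_correlation <- function(result, slack = 2) {
  worst <- apply(result$archive$F, 1, max)
  keep <- worst <= min(worst) + slack
  if (sum(keep) < 3) return(NULL)
  X <- result$archive$X[keep, , drop = FALSE]
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(X) < 2) return(NULL)
  stats::cor(X)
}
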
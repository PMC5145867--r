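# File schemas: observation tables, plant-input tables, climate series,
# trajectories, and the JSON run configuration.

obs_cols <- c("genotype", "treatment", "daa", "fruit_id", "fresh_g",
              "dry_g")

#' Read / write an observation table
#'
#' CSV schema: `genotype,treatment,daa,fruit_id,fresh_g,dry_g`.  Rows are
#' validated (treatment in C/WD, `daa >= 8`, positive masses, dry below
#' fresh) and offending row numbers reported.
#'
#' @param path CSV file
#' @return validated data.frame
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(d)), sort(obs_cols)))
    stop("read_observations: expected columns ",
         paste(obs_cols, collapse = ","), "; got ",
         paste(names(d), collapse = ","))
  d <- d[, obs_cols]
  validate_observations(d)
  d
}

validate_observations <- function(d) {
  bad <- function(cond, msg) {
    if (any(cond))
      stop("observation table: ", msg, " at row(s) ",
           paste(utils::head(which(cond), 5), collapse = ", "))
  }
  bad(!d$treatment %in% c("C", "WD"), "treatment must be C or WD")
  bad(!is.finite(d$daa) | d$daa < 8, "daa must be >= 8")
  bad(!is.finite(d$fresh_g) | d$fresh_g <= 0, "fresh_g must be positive")
  bad(!is.finite(d$dry_g) | d$dry_g <= 0, "dry_g must be positive")
  bad(d$dry_g >= d$fresh_g, "dry_g must be below fresh_g")
  cnt <- stats::aggregate(daa ~ genotype + treatment, d,
                          function(x) length(unique(x)))
  if (any(cnt$daa < 2))
    stop("observation table: need >= 2 distinct daa per genotype x ",
         "treatment")
  invisible(d)
}

#' @rdname read_observations
#' @param obs observation table
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs[, obs_cols])
  utils::write.csv(obs[, obs_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an hourly climate series
#'
#' CSV schema: `t_h,T_C,RH`.
#'
#' @param path CSV file
#' @export
read_env <- function(path) {
  d <- utils::read.csv(path)
  env_series(d$t_h, d$T_C, d$RH)
}

#' @rdname read_env
#' @param env [env_series()]
#' @export
write_env <- function(env, path) {
  utils::write.csv(as.data.frame(env), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write per-treatment plant inputs
#'
#' CSV with one row per genotype x treatment; columns are the
#' [plant_inputs()] fields plus `genotype`.
#'
#' @param path CSV file
#' @return named list (by genotype) of lists with `C` and `WD` entries
#' @export
read_plant_inputs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    pi <- plant_inputs(r$psiStemPredawn, r$psiStemMidday, r$Cp, r$rhoSurf,
                       r$piOther, r$assrat, r$bssrat, r$w0obs, r$s0obs,
                       r$treatment)
    out[[r$genotype]][[r$treatment]] <- pi
  }
  out
}

#' @rdname read_plant_inputs
#' @param inputs named list as returned by [read_plant_inputs()]
#' @export
write_plant_inputs <- function(inputs, path) {
  rows <- list()
  for (g in names(inputs)) for (tr in names(inputs[[g]])) {
    p <- inputs[[g]][[tr]]
    rows[[length(rows) + 1]] <- data.frame(
      genotype = g, treatment = p$treatment,
      psiStemPredawn = p$psiStemPredawn, psiStemMidday = p$psiStemMidday,
      Cp = p$Cp, rhoSurf = p$rhoSurf, piOther = p$piOther,
      assrat = p$assrat, bssrat = p$bssrat, w0obs = p$w0obs,
      s0obs = p$s0obs)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `t_h,w_g,s_g,fm_g,dm_frac,Pf_bar,Ux,Up,Us,Tf,Rf`.
#'
#' @param traj a `fruit_trajectory`
#' @param path CSV file
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(
    traj[, c("t_h", "w_g", "s_g", "fm_g", "dm_frac", "Pf_bar",
             "Ux", "Up", "Us", "Tf", "Rf")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' All pipeline knobs in one validated list with documented defaults;
#' unknown keys are rejected.  Serializable to/from JSON.
#'
#' @param ... overrides of the defaults (see the returned list)
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genotypes = 10L,
    noise_cv = 0.05,
    moea = list(popSize = 40L, generations = 60L, etaC = 15, pC = 0.9,
                etaM = 20, pM = NA_real_),
    calib_repeats = 3L,
    ideotype_repeats = 5L,
    ideotype_class = "small",
    loss_form = "plain",
    active_uptake_scaling = "none",
    dt = 1,
    wd_dpsi = 3, wd_w0_scale = 0.8, wd_piother_scale = 1.3,
    cluster_k = 5L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' @rdname run_config
#' @param path JSON file
#' @export
read_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname run_config
#' @param cfg configuration list
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
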
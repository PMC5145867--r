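# Umbrella pipeline: synthetic data -> per-genotype calibration ->
# parameter-space analysis -> ideotype design, with a JSON manifest that
# records seeds and the configuration hash so completed stages can be
# skipped on rerun.

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

stage_done <- function(manifest, stage, hash) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$hash, hash)
}

read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' Stages: (1) synthesize a population (climate, truth, noisy
#' observations); (2) calibrate every genotype; (3) PCA + clustering of
#' the calibrated parameters; (4) ideotype design for the configured size
#' class.  Artifacts are CSV/JSON files under `out_dir`; a manifest
#' records the configuration hash per completed stage, and a rerun with
#' an unchanged configuration skips completed stages.
#'
#' @param cfg [run_config()]
#' @param out_dir output directory (created if missing)
#' @param quiet suppress progress messages
#' @return invisible list of artifact paths
#' @export
pipeline_run <- function(cfg = run_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  manifest <- read_manifest(out_dir)
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = cfg$seed, stages = list())
  }
  say <- function(...) if (!quiet) message(...)
  paths <- list(obs = file.path(out_dir, "obs.csv"),
                env = file.path(out_dir, "env.csv"),
                inputs = file.path(out_dir, "inputs.csv"),
                truth = file.path(out_dir, "truth.json"),
                calib = file.path(out_dir, "calibrated.csv"),
                calib_json = file.path(out_dir, "calibration.json"),
                scores = file.path(out_dir, "scores.csv"),
                loadings = file.path(out_dir, "loadings.csv"),
                clusters = file.path(out_dir, "clusters.csv"),
                ideo = file.path(out_dir, "ideotypes.csv"))
  generic <- generic_params(active_uptake_scaling =
                              cfg$active_uptake_scaling)

  # stage 1: synthetic population
  if (!stage_done(manifest, "synth", hash)) {
    say("stage synth ...")
    design <- synthetic_design(nGenotypes = cfg$n_genotypes,
                               noiseCV = cfg$noise_cv, seed = cfg$seed)
    pop <- synthesize_population(design, generic = generic)
    write_observations(pop$obs, paths$obs)
    write_env(pop$env, paths$env)
    inp <- stats::setNames(
      lapply(pop$truth, function(g) list(C = g$inputsC, WD = g$inputsWD)),
      vapply(pop$truth, `[[`, "", "id"))
    write_plant_inputs(inp, paths$inputs)
    jsonlite::write_json(
      lapply(pop$truth, function(g)
        list(id = g$id, ripe_daa = g$ripe_daa,
             params = unclass(g$genotype))),
      paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
    manifest$stages$synth <- list(hash = hash, seed = cfg$seed)
    write_manifest(manifest, out_dir)
  } else say("stage synth: cached")

  obs <- read_observations(paths$obs)
  env <- read_env(paths$env)
  inputs <- read_plant_inputs(paths$inputs)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = FALSE)

  # stage 2: calibration of every genotype
  if (!stage_done(manifest, "calibrate", hash)) {
    say("stage calibrate ...")
    mcfg <- do.call(moea_config, c(cfg$moea, list(seed = cfg$seed)))
    res <- list()
    for (g in names(inputs)) {
      og <- obs[obs$genotype == g, ]
      if (!nrow(og)) next
      say("  genotype ", g)
      r <- calibrate_genotype(og, inputs[[g]]$C, inputs[[g]]$WD, env,
                              config = mcfg, nRepeats = cfg$calib_repeats,
                              generic = generic, dt = cfg$dt)
      res[[g]] <- r
    }
    tab <- do.call(rbind, lapply(names(res), function(g)
      data.frame(genotype = g, t(res[[g]]$chosen),
                 t(res[[g]]$objectives))))
    utils::write.csv(tab, paths$calib, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(res, function(r)
        list(chosen = as.list(r$chosen),
             objectives = as.list(r$objectives), seeds = r$seeds)),
      paths$calib_json, auto_unbox = TRUE, digits = NA)
    manifest$stages$calibrate <- list(hash = hash, seed = cfg$seed)
    write_manifest(manifest, out_dir)
  } else say("stage calibrate: cached")

  # stage 3: PCA + clustering
  if (!stage_done(manifest, "analyze", hash)) {
    say("stage analyze ...")
    tab <- utils::read.csv(paths$calib)
    act <- as.matrix(tab[, c("phiMax", "Lp", "nuM", "tstar", "tauA",
                             "tauS", "lp1", "rxp")])
    pca <- pca_params(act)
    k <- min(cfg$cluster_k, nrow(act) - 1)
    cl <- if (nrow(act) > 2 && k >= 2)
      hcluster_scores(pca, k = k) else list(labels = rep(1, nrow(act)))
    utils::write.csv(data.frame(genotype = tab$genotype,
                                pca$scores[, 1:min(3, ncol(pca$scores))]),
                     paths$scores, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(variable = rownames(pca$loadings),
                                pca$loadings),
                     paths$loadings, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(genotype = tab$genotype,
                                cluster = cl$labels),
                     paths$clusters, row.names = FALSE, quote = FALSE)
    manifest$stages$analyze <- list(hash = hash, seed = cfg$seed)
    write_manifest(manifest, out_dir)
  } else say("stage analyze: cached")

  # stage 4: ideotype design
  if (!stage_done(manifest, "ideotype", hash)) {
    say("stage ideotype ...")
    base <- plant_inputs()
    prob <- ideotype_problem(cfg$ideotype_class,
                             inputsC = base,
                             inputsWD = make_treatment_inputs(
                               base, "WD", dPsi = cfg$wd_dpsi,
                               w0_scale = cfg$wd_w0_scale,
                               piOther_scale = cfg$wd_piother_scale),
                             env = env, lossForm = cfg$loss_form,
                             generic = generic, dt = cfg$dt)
    mcfg <- do.call(moea_config, c(cfg$moea, list(seed = cfg$seed)))
    des <- design_ideotypes(prob, config = mcfg,
                            nRepeats = cfg$ideotype_repeats)
    utils::write.csv(data.frame(des$X, des$outcomes,
                                feasible = des$feasible,
                                selected = des$selected),
                     paths$ideo, row.names = FALSE, quote = FALSE)
    manifest$stages$ideotype <- list(hash = hash, seed = cfg$seed)
    write_manifest(manifest, out_dir)
  } else say("stage ideotype: cached")

  invisible(paths)
}

# ---- minimal command-line front end ---------------------------------------

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("cli: unexpected argument ", a)
    key <- gsub("-", "_", substring(a, 3))
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `simulate`, `calibrate`, `analyze`,
#' `design-ideotypes`, `run-all`.  See the package README for usage; an
#' executable wrapper lives in `inst/cli/virtualfruit`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`
#' @export
vf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: virtualfruit <subcommand> [--key value]")
  cmd <- args[1]
  opt <- cli_args(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d) if (is.null(x)) d else x
  seed <- as.integer(num(opt$seed, 1))
  switch(cmd,
    "synth" = {
      design <- synthetic_design(nGenotypes = as.integer(num(opt$n, 10)),
                                 seed = seed)
      pop <- synthesize_population(design)
      dir.create(opt$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_observations(pop$obs, file.path(opt$out_dir, "obs.csv"))
      write_env(pop$env, file.path(opt$out_dir, "env.csv"))
      inp <- stats::setNames(
        lapply(pop$truth, function(g) list(C = g$inputsC,
                                           WD = g$inputsWD)),
        vapply(pop$truth, `[[`, "", "id"))
      write_plant_inputs(inp, file.path(opt$out_dir, "inputs.csv"))
    },
    "simulate" = {
      env <- read_env(opt$env)
      inputs <- read_plant_inputs(opt$inputs)[[opt$genotype]][[
        chr(opt$treatment, "C")]]
      p <- jsonlite::read_json(opt$params, simplifyVector = TRUE)
      p <- p[!vapply(p, is.null, logical(1))]
      g <- do.call(genotype_params, p)
      traj <- simulate_fruit(g, inputs, env,
                             tEnd = num(opt$tend_daa, 50) * 24)
      write_trajectory(traj, opt$out)
    },
    "calibrate" = {
      obs <- read_observations(opt$obs)
      env <- read_env(opt$env)
      inputs <- read_plant_inputs(opt$inputs)
      g <- opt$genotype
      res <- calibrate_genotype(
        obs[obs$genotype == g, ], inputs[[g]]$C, inputs[[g]]$WD, env,
        config = moea_config(popSize = as.integer(num(opt$pop, 40)),
                             generations = as.integer(num(opt$gen, 60)),
                             seed = seed),
        nRepeats = as.integer(num(opt$repeats, 10)))
      jsonlite::write_json(list(chosen = as.list(res$chosen),
                                objectives = as.list(res$objectives)),
                           opt$out, auto_unbox = TRUE, digits = NA)
    },
    "analyze" = {
      tab <- utils::read.csv(opt$params)
      act <- as.matrix(tab[, setdiff(names(tab), "genotype")])
      pca <- pca_params(act)
      cl <- hcluster_scores(pca, k = as.integer(num(opt$k, 5)))
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data.frame(genotype = tab$genotype, pca$scores),
                       file.path(opt$out, "scores.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(genotype = tab$genotype,
                                  cluster = cl$labels),
                       file.path(opt$out, "clusters.csv"),
                       row.names = FALSE)
    },
    "design-ideotypes" = {
      base <- plant_inputs()
      env <- make_environment(60)
      prob <- ideotype_problem(chr(opt$class, "small"), base,
                               make_treatment_inputs(base, "WD"), env)
      des <- design_ideotypes(prob,
                              config = moea_config(
                                popSize = as.integer(num(opt$pop, 60)),
                                generations = as.integer(num(opt$gen, 80)),
                                seed = seed),
                              nRepeats = as.integer(num(opt$repeats, 20)))
      utils::write.csv(data.frame(des$X, des$outcomes,
                                  selected = des$selected),
                       opt$out, row.names = FALSE)
    },
    "run-all" = {
      cfg <- if (!is.null(opt$config)) read_config(opt$config) else
        run_config(seed = seed)
      pipeline_run(cfg, opt$out_dir)
    },
    stop("unknown subcommand: ", cmd))
  invisible(NULL)
}
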
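# Ideotype design: search the 11-parameter space for virtual genotypes
# maximizing ripe dry-matter content under control irrigation while
# minimizing the fresh-mass loss under water deficit, inside a fruit-size
# class and under the dm < 10% constraint.

size_class_window <- function(sizeClass) {
  switch(sizeClass,
         large = c(100, 300), medium = c(20, 80), small = c(5, 15),
         stop("unknown size class: ", sizeClass))
}

#' Define an ideotype-design problem
#'
#' @param sizeClass `"large"` (100--300 g), `"medium"` (20--80 g) or
#'   `"small"` (5--15 g), the admissible window for the ripe fresh mass
#'   under control irrigation
#' @param inputsC,inputsWD non-genotypic plant inputs per treatment (the
#'   genotypic `w0`, `s0`, `bssrat` carried by candidate vectors override
#'   the corresponding fields)
#' @param env [env_series()]
#' @param ripe_daa ripeness age used to read the outcome (days)
#' @param lossForm `"plain"` (percent loss) or `"squared"` (squared
#'   relative loss times 100); see the methods vignette for why plain is
#'   the default
#' @param generic [generic_params()]
#' @param dt integration step (h)
#' @export
ideotype_problem <- function(sizeClass = c("small", "medium", "large"),
                             inputsC, inputsWD, env, ripe_daa = 50,
                             lossForm = c("plain", "squared"),
                             generic = generic_params(), dt = 1) {
  sizeClass <- match.arg(sizeClass)
  lossForm <- match.arg(lossForm)
  structure(list(sizeClass = sizeClass, window = size_class_window(sizeClass),
                 inputsC = inputsC, inputsWD = inputsWD, env = env,
                 ripe_daa = ripe_daa, lossForm = lossForm,
                 generic = generic, dt = dt,
                 bounds = table1_bounds("ideotype")),
            class = "ideotype_problem")
}

#' Fresh-mass loss under water deficit
#'
#' `plain` form: `100 * (fwC - fwWD) / fwC` (percent loss).  `squared`
#' form: `100 * ((fwC - fwWD) / fwC)^2`.  The plain form is the default
#' throughout because reported losses of sensitive genotypes (more than
#' half the fresh mass, i.e. around 60 percent) are only consistent with
#' it; the squared variant is kept behind this flag.
#'
#' @param fwC,fwWD ripe fresh mass under control and water deficit (g)
#' @param form `"plain"` or `"squared"`
#' @export
fresh_mass_loss <- function(fwC, fwWD, form = c("plain", "squared")) {
  form <- match.arg(form)
  rel <- (fwC - fwWD) / fwC
  if (form == "squared") 100 * rel^2 else 100 * rel
}

ideotype_genotype <- function(x) {
  genotype_params(phiMax = x[["phiMax"]], Lp = x[["Lp"]], nuM = x[["nuM"]],
                  tstar = x[["tstar"]], tauA = x[["tauA"]],
                  tauS = x[["tauS"]], lp1 = x[["lp1"]], rxp = x[["rxp"]],
                  s0 = x[["s0"]], w0 = x[["w0"]], bssrat = x[["bssrat"]])
}

#' Evaluate one candidate ideotype
#'
#' Simulates the 11-parameter vector under both treatments to ripeness and
#' returns the design outcomes: `dmC` (ripe dry-matter content under
#' control, percent), `loss` (fresh-mass loss under water deficit, in the
#' requested form), `fwC`/`fwWD` (ripe fresh masses, g), and the
#' constraint values (positive = violated): `dmC < 10`, `dmWD < 10`, and
#' `fwC` inside the size-class window.
#'
#' @param x named 11-parameter vector
#' @param problem an [ideotype_problem()]
#' @return named vector `c(dmC, dmWD, loss, fwC, fwWD, g1..g4)`
#' @export
ideotype_objectives <- function(x, problem) {
  g <- ideotype_genotype(x)
  tEnd <- problem$ripe_daa * 24
  sim <- function(inputs) tryCatch(
    simulate_at(g, inputs, problem$env, tEnd, dt = problem$dt,
                generic = problem$generic),
    error = function(e) NULL)
  sC <- sim(problem$inputsC)
  sWD <- sim(problem$inputsWD)
  if (is.null(sC) || is.null(sWD) ||
      !all(is.finite(c(sC$fm_g, sWD$fm_g)))) {
    return(c(dmC = NA, dmWD = NA, loss = NA, fwC = NA, fwWD = NA,
             g1 = 1e6, g2 = 1e6, g3 = 1e6, g4 = 1e6))
  }
  fwC <- sC$fm_g; fwWD <- sWD$fm_g
  dmC <- 100 * sC$s_g / fwC
  dmWD <- 100 * sWD$s_g / fwWD
  loss <- fresh_mass_loss(fwC, fwWD, problem$lossForm)
  c(dmC = dmC, dmWD = dmWD, loss = loss, fwC = fwC, fwWD = fwWD,
    g1 = dmC - 10, g2 = dmWD - 10,
    g3 = problem$window[1] - fwC, g4 = fwC - problem$window[2])
}

#' Run the ideotype design
#'
#' NSGA-II with constraint domination on objectives `(-dmC, loss)`,
#' repeated `nRepeats` times with consecutive seeds; the per-repeat
#' archives are merged and reduced to a single non-dominated set.
#'
#' @param problem an [ideotype_problem()]
#' @param config [moea_config()]
#' @param nRepeats number of independent optimizer runs
#' @return list of class `ideotype_result`: `X` (natural units, named
#'   columns), `F`, outcomes matrix (`dmC`, `dmWD`, `loss`, `fwC`,
#'   `fwWD`), `feasible`, `selected` (the decision filter), `seeds`
#' @export
design_ideotypes <- function(problem, config = moea_config(),
                             nRepeats = 20) {
  bounds <- problem$bounds
  tr <- search_transform(bounds)
  nm <- rownames(bounds)
  evaluate <- function(Z) {
    Xn <- tr$from_search(Z)
    F <- matrix(0, nrow(Z), 2)
    G <- matrix(0, nrow(Z), 4)
    for (i in seq_len(nrow(Z))) {
      x <- Xn[i, ]; names(x) <- nm
      o <- ideotype_objectives(x, problem)
      if (is.na(o[["dmC"]])) {
        F[i, ] <- c(1e6, 1e6)
      } else {
        F[i, ] <- c(-o[["dmC"]], o[["loss"]])
      }
      G[i, ] <- o[c("g1", "g2", "g3", "g4")]
    }
    list(F = F, G = G)
  }
  prob <- list(dim = nrow(bounds), lower = tr$lower, upper = tr$upper,
               evaluate = evaluate)
  seeds <- config$seed + seq_len(nRepeats) - 1L
  Xs <- NULL; Fs <- NULL; cvs <- NULL
  for (r in seq_len(nRepeats)) {
    cfg <- config; cfg$seed <- seeds[r]
    run <- nsga2_run(prob, cfg)
    Xs <- rbind(Xs, run$archive$X)
    Fs <- rbind(Fs, run$archive$F)
    cvs <- c(cvs, run$archive$cv)
  }
  nd <- nondominated_indices(Fs, cvs)
  Xs <- Xs[nd, , drop = FALSE]; Fs <- Fs[nd, , drop = FALSE]
  cvs <- cvs[nd]
  Xnat <- tr$from_search(Xs)
  colnames(Xnat) <- nm
  out <- t(apply(Xnat, 1, function(x) {
    ideotype_objectives(stats::setNames(x, nm), problem)[
      c("dmC", "dmWD", "loss", "fwC", "fwWD")]
  }))
  feasible <- cvs == 0
  structure(list(X = Xnat, F = Fs, outcomes = out, feasible = feasible,
                 selected = feasible & filter_ideotypes(out),
                 sizeClass = problem$sizeClass, lossForm = problem$lossForm,
                 seeds = seeds),
            class = "ideotype_result")
}

#' Decision filter on designed ideotypes
#'
#' Keeps solutions with `dmC >= 8` percent and `loss <= 15` percent
#' (boundaries inclusive).
#'
#' @param outcomes matrix with columns `dmC` and `loss`
#' @return logical vector
#' @export
filter_ideotypes <- function(outcomes) {
  outcomes[, "dmC"] >= 8 & outcomes[, "loss"] <= 15
}
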
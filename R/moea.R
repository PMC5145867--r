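# Self-contained real-coded NSGA-II: constraint-domination, fast
# non-dominated sorting, crowding distance, SBX crossover and polynomial
# mutation, (mu + lambda) elitist loop with binary tournament selection.

#' NSGA-II settings
#'
#' @param popSize population size (even, >= 4)
#' @param generations number of generations
#' @param etaC,pC SBX distribution index and per-pair probability
#' @param etaM,pM polynomial-mutation index and per-variable probability
#'   (`NA` = `1/dimension`, resolved at run time)
#' @param seed RNG seed for one run
#' @export
moea_config <- function(popSize = 100, generations = 200, etaC = 15,
                        pC = 0.9, etaM = 20, pM = NA_real_, seed = 1L) {
  if (popSize < 4 || popSize %% 2 != 0)
    stop("moea_config: popSize must be even and >= 4")
  list(popSize = as.integer(popSize),
       generations = as.integer(generations), etaC = etaC, pC = pC,
       etaM = etaM, pM = pM, seed = as.integer(seed))
}

#' Constraint-domination test
#'
#' Deb's rule: a feasible solution dominates an infeasible one; among
#' infeasible solutions the smaller total violation wins; among feasible
#' solutions ordinary Pareto dominance applies (no worse on every
#' objective, strictly better on at least one).
#'
#' @param fa,fb objective vectors (minimized)
#' @param cva,cvb total constraint violations (0 = feasible)
#' @export
dominates <- function(fa, fb, cva = 0, cvb = 0) {
  if (cva == 0 && cvb > 0) return(TRUE)
  if (cva > 0 && cvb == 0) return(FALSE)
  if (cva > 0 && cvb > 0) return(cva < cvb)
  all(fa <= fb) && any(fa < fb)
}

# n x n logical matrix D[i, j] = i dominates j, vectorized over pairs
domination_matrix <- function(F, cv) {
  n <- nrow(F)
  leq <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(F))) {
    dk <- outer(F[, k], F[, k], "-")
    leq <- leq & (dk <= 0)
    lt <- lt | (dk < 0)
  }
  D <- leq & lt
  if (any(cv > 0)) {
    feas <- cv == 0
    Dc <- outer(cv, cv, "<")
    bothInf <- outer(!feas, !feas, "&")
    D[bothInf] <- Dc[bothInf]
    D[outer(feas, !feas, "&")] <- TRUE
    D[outer(!feas, feas, "&")] <- FALSE
  }
  diag(D) <- FALSE
  D
}

#' Fast non-dominated sorting
#'
#' @param F objective matrix (rows = individuals, minimized)
#' @param cv total constraint violation per individual
#' @return list with `fronts` (list of index vectors, front 1 first) and
#'   `rank` (integer per individual, 1-based)
#' @export
fast_nondominated_sort <- function(F, cv = rep(0, nrow(F))) {
  n <- nrow(F)
  D <- domination_matrix(F, cv)
  nDom <- colSums(D)  # how many dominate each individual
  rank <- integer(n)
  fronts <- list()
  current <- which(nDom == 0)
  level <- 0L
  remaining <- nDom
  while (length(current)) {
    level <- level + 1L
    rank[current] <- level
    fronts[[level]] <- current
    remaining[current] <- NA_integer_
    for (i in current) {
      dom <- which(D[i, ])
      remaining[dom] <- remaining[dom] - 1L
    }
    current <- which(!is.na(remaining) & remaining == 0)
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one front
#'
#' Boundary individuals on each objective get `Inf`; interior individuals
#' accumulate normalized gaps between their neighbours.  Objectives with
#' zero range contribute nothing.
#'
#' @param F objective matrix of the front members
#' @export
crowding_distance <- function(F) {
  n <- nrow(F)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(F))) {
    o <- order(F[, k])
    rng <- F[o[n], k] - F[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], k] - F[o[1:(n - 2)], k]) / rng
  }
  d
}

#' Simulated binary crossover (SBX)
#'
#' @param p1,p2 parent vectors inside the bounds
#' @param etaC distribution index
#' @param pC crossover probability (whole pair)
#' @param lower,upper box bounds
#' @return list of two children, clipped to the bounds
#' @export
sbx_crossover <- function(p1, p2, etaC, pC, lower, upper) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= pC) {
    for (j in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[j] - p2[j]) < 1e-14) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (etaC + 1)) else
        (1 / (2 * (1 - u)))^(1 / (etaC + 1))
      m <- 0.5 * (p1[j] + p2[j])
      h <- 0.5 * abs(p2[j] - p1[j])
      a <- m - beta * h
      b <- m + beta * h
      if (stats::runif(1) < 0.5) { c1[j] <- a; c2[j] <- b }
      else { c1[j] <- b; c2[j] <- a }
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

#' Polynomial mutation
#'
#' @param x vector inside the bounds
#' @param etaM distribution index
#' @param pM per-variable mutation probability
#' @param lower,upper box bounds
#' @export
polynomial_mutation <- function(x, etaM, pM, lower, upper) {
  for (j in seq_along(x)) {
    if (stats::runif(1) > pM) next
    rng <- upper[j] - lower[j]
    if (rng <= 0) next
    u <- stats::runif(1)
    d1 <- (x[j] - lower[j]) / rng
    d2 <- (upper[j] - x[j]) / rng
    if (u < 0.5) {
      dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(etaM + 1))^(1 / (etaM + 1)) - 1
    } else {
      dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(etaM + 1))^
        (1 / (etaM + 1))
    }
    x[j] <- x[j] + dq * rng
  }
  pmin(pmax(x, lower), upper)
}

tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] > crowd[j]) return(i)
  if (crowd[j] > crowd[i]) return(j)
  i
}

#' Run NSGA-II on a box-constrained multi-objective problem
#'
#' `problem` is a list with `dim`, `lower`, `upper` and
#' `evaluate(X)` where `X` is a matrix of rows to evaluate; `evaluate`
#' returns `list(F = objectives matrix, G = constraint matrix or NULL)`
#' (a positive entry of `G` is the violated amount).  Fully reproducible
#' given `config$seed`.
#'
#' @param problem problem definition (see Details)
#' @param config [moea_config()]
#' @return list with the final `X`, `F`, `G`, `rank`, and the `archive`
#'   (rows of rank 1 in the final merged population)
#' @export
nsga2_run <- function(problem, config = moea_config()) {
  set.seed(config$seed)
  n <- config$popSize
  d <- problem$dim
  lo <- problem$lower; up <- problem$upper
  pM <- if (is.na(config$pM)) 1 / d else config$pM
  X <- matrix(stats::runif(n * d, rep(lo, each = n), rep(up, each = n)),
              n, d)
  ev <- problem$evaluate(X)
  F <- ev$F; G <- ev$G
  cv <- if (is.null(G)) rep(0, n) else rowSums(pmax(G, 0))
  srt <- fast_nondominated_sort(F, cv)
  rank <- srt$rank
  crowd <- numeric(n)
  for (fr in srt$fronts) crowd[fr] <- crowding_distance(F[fr, , drop = FALSE])

  for (gen in seq_len(config$generations)) {
    C <- matrix(0, n, d)
    for (i in seq(1, n, by = 2)) {
      a <- tournament_pick(rank, crowd)
      b <- tournament_pick(rank, crowd)
      ch <- sbx_crossover(X[a, ], X[b, ], config$etaC, config$pC, lo, up)
      C[i, ] <- polynomial_mutation(ch[[1]], config$etaM, pM, lo, up)
      C[i + 1, ] <- polynomial_mutation(ch[[2]], config$etaM, pM, lo, up)
    }
    evC <- problem$evaluate(C)
    Xall <- rbind(X, C)
    Fall <- rbind(F, evC$F)
    Gall <- if (is.null(G)) NULL else rbind(G, evC$G)
    cvAll <- if (is.null(Gall)) rep(0, 2 * n) else rowSums(pmax(Gall, 0))
    srt <- fast_nondominated_sort(Fall, cvAll)
    keep <- integer(0)
    crowdAll <- numeric(2 * n)
    for (fr in srt$fronts) {
      crowdAll[fr] <- crowding_distance(Fall[fr, , drop = FALSE])
      if (length(keep) + length(fr) <= n) {
        keep <- c(keep, fr)
      } else {
        slots <- n - length(keep)
        if (slots > 0)
          keep <- c(keep, fr[order(crowdAll[fr], decreasing = TRUE)[
            seq_len(slots)]])
        break
      }
    }
    X <- Xall[keep, , drop = FALSE]
    F <- Fall[keep, , drop = FALSE]
    G <- if (is.null(Gall)) NULL else Gall[keep, , drop = FALSE]
    cv <- cvAll[keep]
    rank <- srt$rank[keep]
    crowd <- crowdAll[keep]
  }
  first <- which(rank == 1)
  list(X = X, F = F, G = G, rank = rank, cv = cv,
       archive = list(X = X[first, , drop = FALSE],
                      F = F[first, , drop = FALSE],
                      G = if (is.null(G)) NULL else
                        G[first, , drop = FALSE],
                      cv = cv[first],
                      seed = config$seed))
}

#' Reduce a set of solutions to its non-dominated subset
#'
#' Used to merge archives across repeated runs before downstream
#' selection.
#'
#' @param F objective matrix
#' @param cv total constraint violation per row
#' @return indices of the non-dominated rows
#' @export
nondominated_indices <- function(F, cv = rep(0, nrow(F))) {
  which(colSums(domination_matrix(F, cv)) == 0)
}

#' Variable-space transformation for calibration searches
#'
#' Parameters whose admissible box spans about two decades or more
#' (`phiMax`, `Lp`, `nuM`, `lp1`) are searched in log10 space, the rest
#' linearly; returns forward/backward maps and the transformed bounds.
#'
#' @param bounds matrix with columns `lower`, `upper` (rownames = names)
#' @param log_params names searched in log10 space when present; for
#'   anonymous bounds the mask falls back to a mechanical two-decades rule
#' @return list with `lower`, `upper` (transformed), `logmask`, and
#'   functions `to_search(x)`, `from_search(z)` operating on vectors or
#'   matrices in natural/search coordinates
#' @export
search_transform <- function(bounds,
                             log_params = c("phiMax", "Lp", "nuM",
                                            "lp1")) {
  if (!is.null(rownames(bounds))) {
    logmask <- rownames(bounds) %in% log_params
    names(logmask) <- rownames(bounds)
  } else {
    logmask <- bounds[, "lower"] > 0 &
      log10(bounds[, "upper"] / bounds[, "lower"]) >= 2 - 1e-9
  }
  lo <- ifelse(logmask, log10(bounds[, "lower"]), bounds[, "lower"])
  up <- ifelse(logmask, log10(bounds[, "upper"]), bounds[, "upper"])
  tf <- function(x, mask, fun) {
    if (is.matrix(x)) {
      x[, mask] <- fun(x[, mask, drop = FALSE])
    } else {
      x[mask] <- fun(x[mask])
    }
    x
  }
  list(lower = lo, upper = up, logmask = logmask,
       to_search = function(x) tf(x, logmask, log10),
       from_search = function(z) tf(z, logmask, function(v) 10^v))
}
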
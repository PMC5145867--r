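# NSGA-II machinery: domination, sorting, crowding, operators, full loop.

test_that("constraint-domination follows Deb's rule", {
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_false(dominates(c(1, 2), c(1, 2)))        # equal: no domination
  expect_true(dominates(c(9, 9), c(1, 1), 0, 0.1)) # feasible beats infeasible
  expect_false(dominates(c(1, 1), c(9, 9), 0.1, 0))
  expect_true(dominates(c(9, 9), c(1, 1), 0.05, 0.1)) # smaller violation
})

test_that("fast sort matches the brute-force oracle on random populations", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:50, 1)
    F <- matrix(runif(2 * n), n, 2)
    cv <- ifelse(runif(n) < 0.3, runif(n), 0)
    srt <- fast_nondominated_sort(F, cv)
    expect_equal(srt$rank, oracle_sort(F, cv))
    expect_setequal(unlist(srt$fronts), seq_len(n))
  }
})

test_that("sorting edge cases: ties, chains", {
  F <- rbind(c(1, 2), c(2, 1), c(3, 3))
  s <- fast_nondominated_sort(F)
  expect_equal(s$fronts[[1]], c(1, 2))
  expect_equal(s$fronts[[2]], 3)
  Fsame <- matrix(1, 5, 2)
  expect_equal(fast_nondominated_sort(Fsame)$rank, rep(1L, 5))
  Fchain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(fast_nondominated_sort(Fchain)$rank, 1:3)
})

test_that("crowding distance: boundaries, hand value, duplicates", {
  expect_equal(crowding_distance(rbind(c(0, 1))), Inf)
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  F <- rbind(c(0, 2), c(1, 1), c(2, 0))
  d <- crowding_distance(F)
  expect_equal(d, c(Inf, 2, Inf))
  # permutation invariance
  p <- c(2, 3, 1)
  expect_equal(crowding_distance(F[p, ]), d[p])
  Fdup <- rbind(c(0, 2), c(1, 1), c(1, 1), c(2, 0))
  dd <- crowding_distance(Fdup)
  expect_true(all(is.finite(dd[2:3])))
})

test_that("SBX and polynomial mutation respect bounds and identities", {
  lo <- c(-1, 0); up <- c(1, 10)
  set.seed(9)
  p1 <- c(0.2, 3); p2 <- c(-0.4, 8)
  # pC = 0: children equal parents
  ch <- sbx_crossover(p1, p2, 15, 0, lo, up)
  expect_equal(ch[[1]], p1)
  expect_equal(ch[[2]], p2)
  expect_equal(polynomial_mutation(p1, 20, 0, lo, up), p1)
  # bounds respected over many operations
  ok <- TRUE
  for (i in 1:2000) {
    ch <- sbx_crossover(p1, p2, 2, 1, lo, up)
    m <- polynomial_mutation(ch[[1]], 5, 1, lo, up)
    ok <- ok && all(m >= lo & m <= up) &&
      all(ch[[2]] >= lo & ch[[2]] <= up)
  }
  expect_true(ok)
  # SBX children symmetric about the parent midpoint
  set.seed(10)
  mids <- replicate(10000, {
    ch <- sbx_crossover(0, 1, 15, 1, -5, 5)
    ch[[1]] + ch[[2]]
  })
  expect_equal(mean(mids), 1, tolerance = 0.01)
})

test_that("NSGA-II solves the convex benchmark and is reproducible", {
  problem <- list(
    dim = 1, lower = -5, upper = 5,
    evaluate = function(X) list(F = cbind(X[, 1]^2, (X[, 1] - 2)^2),
                                G = NULL))
  run <- nsga2_run(problem, moea_config(popSize = 40, generations = 100,
                                        seed = 3))
  x <- run$archive$X[, 1]
  expect_true(all(x > -1e-2 & x < 2 + 1e-2))
  expect_gt(nrow(run$archive$X), 5)
  # archive is mutually non-dominated
  expect_equal(length(nondominated_indices(run$archive$F)),
               nrow(run$archive$F))
  run2 <- nsga2_run(problem, moea_config(popSize = 40, generations = 100,
                                         seed = 3))
  expect_identical(run$archive$X, run2$archive$X)
  # elitism: final archive not dominated by any initial random point
  set.seed(3)
  X0 <- matrix(runif(40, -5, 5), 40, 1)
  F0 <- cbind(X0[, 1]^2, (X0[, 1] - 2)^2)
  for (i in seq_len(nrow(run$archive$F)))
    expect_false(any(apply(F0, 1, function(f)
      dominates(f, run$archive$F[i, ]))))
})

test_that("constrained NSGA-II returns only feasible archive members", {
  # minimize (x1, x2) subject to x1 + x2 >= 1
  problem <- list(
    dim = 2, lower = c(0, 0), upper = c(1, 1),
    evaluate = function(X) list(F = X, G = cbind(1 - X[, 1] - X[, 2])))
  run <- nsga2_run(problem, moea_config(popSize = 40, generations = 60,
                                        seed = 4))
  expect_true(all(run$archive$cv == 0))
  expect_true(all(rowSums(run$archive$X) >= 1 - 1e-9))
  # the feasible Pareto set is the line x1 + x2 = 1
  expect_lt(max(rowSums(run$archive$X)) - 1, 0.05)
})

test_that("search transform: log10 for wide boxes, round trip", {
  b <- table1_bounds("calibration")
  tr <- search_transform(b)
  expect_true(all(tr$logmask[c("phiMax", "Lp", "nuM", "lp1")]))
  expect_false(any(tr$logmask[c("tstar", "tauA", "tauS", "rxp")]))
  x <- b[, "lower"] * 3
  expect_equal(tr$from_search(tr$to_search(x)), x, tolerance = 1e-12)
  Z <- rbind(tr$lower, tr$upper)
  expect_equal(tr$to_search(tr$from_search(Z)), Z, tolerance = 1e-12)
})
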
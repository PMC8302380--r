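test_that("iteration coefficient k follows its closed form", {
  expect_equal(coefficientK(1, 1000, 1), 0.25 * log(1 + 1 / 1000))
  expect_equal(coefficientK(5, 100, 0), 0)
  expect_equal(coefficientK(100, 100, -1), -0.25 * log(100 + 1 / 100))
  expect_error(coefficientK(0, 100, 1), ">= 1")
  expect_error(coefficientK(3, 100, 2), "gamma")
})

test_that("position updates match direct substitution and a scalar-loop oracle", {
  expect_equal(encircleUpdate(0, 1, 0.1, 0.5, 1), 0.95)
  expect_equal(encircleUpdate(c(2, 2), c(2, 2), 0.3, 1, 1), c(2, 2))  # fixed point
  expect_equal(anglePositionUpdate(c(1, 2), c(5, 5), 1, pi / 2),
               c(1, 2))  # cos = 0 leaves position unchanged
  expect_equal(anglePositionUpdate(0, 2, 1, 0), -2)
  expect_equal(successorUpdate(1, 1, 0.7, 1.2, 0.5), 1)  # fixed point at successor
  expect_equal(successorUpdate(0, 1, 1, 1, 1), 0)

  set.seed(21)
  for (i in 1:20) {
    zj <- runif(5, -3, 3); zl <- runif(5, -3, 3); zs <- runif(5, -3, 3)
    k <- runif(1, -1, 1); sw <- runif(1, 0, 2); L <- runif(1, 0, 2)
    phi <- runif(1, 0, 2 * pi)
    enc <- numeric(5); ang <- numeric(5); suc <- numeric(5)
    for (d in 1:5) {
      enc[d] <- zl[d] - k * sw * L * abs(zl[d] - zj[d])
      ang[d] <- zj[d] - sw * cos(phi) * abs(zl[d] - zj[d])
      suc[d] <- zs[d] - k * sw * L * abs(zs[d] - zj[d])
    }
    expect_lt(max(abs(encircleUpdate(zj, zl, k, sw, L) - enc)), 1e-10)
    expect_lt(max(abs(anglePositionUpdate(zj, zl, sw, phi) - ang)), 1e-10)
    expect_lt(max(abs(successorUpdate(zj, zs, k, sw, L) - suc)), 1e-10)
  }
  expect_error(encircleUpdate(1:3, 1:2, 1, 1, 1), "length")
})

test_that("angle update composes wind angle and visual angle", {
  expect_equal(angleUpdate(0, 0, 0), 0)
  expect_equal(angleUpdate(pi, pi / 2, 1), pi + pi / 2 - pi / 8)
  # u = (pi/8) alpha is uniform on [0, pi/8]
  set.seed(5)
  a <- runif(20000)
  u <- angleUpdate(0, 0, a) * -1
  expect_true(all(u >= 0 & u <= pi / 8))
  expect_lt(abs(mean(u) - pi / 16), 0.005)
  expect_lt(abs(max(u) - pi / 8), 0.01)
})

test_that("Levy steps have the Mantegna scale, symmetry and heavy tails", {
  expect_lt(abs(levySigma(1.5) - 0.6966), 5e-4)
  expect_error(levySigma(2.5), "mu")
  set.seed(31)
  d <- levyStep(2e5, 1.5)
  # symmetric around zero: median near 0 (the mean is tail-dominated)
  expect_lt(abs(median(d)), 0.01)
  expect_lt(abs(mean(d > 0) - 0.5), 0.01)
  # tail mass beyond 10 far exceeds the Gaussian prediction at matched sd
  gaussTail <- 2 * pnorm(10, sd = levySigma(1.5), lower.tail = FALSE)
  expect_gt(mean(abs(d) > 10), 10 * gaussTail)
})

test_that("Levy refinement reduces to its closed-form special cases", {
  set.seed(41)
  # identical random member and current position: G term vanishes
  zc <- c(1, 2); zb <- c(0.5, 0.5)
  set.seed(77)
  u <- runif(1, 0, 2); r <- runif(1)
  le <- levyStep(2, 1.5)
  set.seed(77)
  out <- levyRefine(zc, zb, c(3, 3), c(3, 3), 1.5)
  expect_equal(out, zc + zb * le)
  # scalar-loop oracle under a shared seed
  set.seed(55)
  zc <- runif(4); zb <- runif(4); zr <- runif(4); zcur <- runif(4)
  set.seed(99)
  u <- runif(1, 0, 2); r <- runif(1); R <- u * (2 * r - 1)
  le <- levyStep(4, 1.5)
  manual <- numeric(4)
  for (d in 1:4) manual[d] <- zc[d] + (zb[d] - R * abs(zr[d] - zcur[d])) * le[d]
  set.seed(99)
  expect_equal(levyRefine(zc, zb, zr, zcur, 1.5), manual)
})

test_that("greedy selection keeps the fitter position and breaks ties to the candidate", {
  obj <- getBenchmark("sphere", 2)
  expect_equal(greedySelect(c(0, 0), c(1, 1), obj), c(0, 0))
  expect_equal(greedySelect(c(1, 1), c(-1, -1), obj), c(-1, -1))  # tie
  set.seed(61)
  for (i in 1:50) {
    a <- runif(2, -2, 2); b <- runif(2, -2, 2)
    keep <- greedySelect(a, b, obj)
    expect_equal(keep, if (sphere(a) < sphere(b)) a else b)
  }
})

test_that("initialization is in-box, ranked, and deterministic under a seed", {
  obj <- getBenchmark("sphere", 2)
  cfg <- huntConfig(popSize = 5, maxIter = 10)
  set.seed(3)
  p <- initializePopulation(obj, cfg)
  expect_equal(dim(p$positions), c(5L, 2L))
  expect_true(all(p$positions >= obj@lower & p$positions <= obj@upper))
  expect_equal(p$bestFitness, min(p$fitness))
  expect_equal(p$successor, p$positions[order(p$fitness)[2], ])
  set.seed(3)
  p2 <- initializePopulation(obj, cfg)
  expect_identical(p, p2)
  expect_error(huntConfig(popSize = 1), "popSize")
  degenerate <- makeObjective(sphere, 2, 0, 1, vectorized = TRUE)
  degenerate@upper <- 0  # force lower == upper
  expect_error(initializePopulation(degenerate, cfg), "degenerate")
})

test_that("a step preserves feasibility and elitism", {
  obj <- getBenchmark("sphere", 3)
  for (variant in c("dhoa", "bdhoa")) {
    cfg <- huntConfig(variant, popSize = 8, maxIter = 50)
    set.seed(13)
    st <- initializePopulation(obj, cfg)
    for (it in 1:20) {
      prev <- st$bestFitness
      st <- deerHuntStep(st, obj, it, cfg)
      expect_true(all(st$positions >= obj@lower & st$positions <= obj@upper))
      expect_lte(st$bestFitness, prev)
      expect_equal(st$fitness, obj@fun(st$positions))
    }
  }
})

test_that("optimization solves the 2-d sphere, is deterministic, and records a monotone history", {
  obj <- getBenchmark("sphere", 2)
  cfg <- huntConfig("bdhoa", popSize = 10, maxIter = 100, seed = 1)
  res <- deerHunt(obj, cfg)
  expect_lt(bestFitness(res), 1e-6)
  expect_true(all(diff(fitnessHistory(res)) <= 0))
  expect_equal(bestFitness(res), tail(fitnessHistory(res), 1))
  expect_equal(bestFitness(res), sphere(bestPosition(res)))
  res2 <- deerHunt(obj, cfg)
  expect_identical(res, res2)
})

test_that("the Balanced variant dominates plain DHOA on the sphere over paired seeds", {
  obj <- getBenchmark("sphere", 5)
  finals <- sapply(1:20, function(s) {
    c(dhoa = bestFitness(deerHunt(obj, huntConfig("dhoa", 10, 60, seed = s))),
      bdhoa = bestFitness(deerHunt(obj, huntConfig("bdhoa", 10, 60, seed = s))))
  })
  expect_lt(median(finals["bdhoa", ]), median(finals["dhoa", ]))
})

test_that("the study harness reports matched-seed MD and SD per pair", {
  st <- runBenchmarkStudy("sphere", c("dhoa", "bdhoa"), dimension = 3,
                          nRuns = 3, popSize = 8, maxIter = 30, seed = 5)
  expect_equal(nrow(st), 2L)
  expect_true(all(st$MD >= 0) && all(st$SD >= 0))
  # MD recomputable from individual seeded runs (paired seeds)
  obj <- getBenchmark("sphere", 3)
  manual <- mean(sapply(5:7, function(s)
    bestFitness(deerHunt(obj, huntConfig("dhoa", 8, 30, seed = s)))))
  expect_equal(st$MD[st$algorithm == "dhoa"], manual)
  expect_error(runBenchmarkStudy("sphere", nRuns = 1), "nRuns")
})
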
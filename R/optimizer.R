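## Deer Hunting Optimization Algorithm (DHOA) and its Levy-flight Balanced
## variant (BDHOA).  Population of "hunters" moves relative to a leader
## (best solution seen so far) and a successor (second best of the current
## population); the Balanced variant refines each move with a heavy-tailed
## Levy step and keeps it only if it improves the objective.

#' Wrap an arbitrary function as a bounded ObjectiveFunction
#'
#' Convenience constructor for optimizing user functions whose global
#' optimum may be unknown (pass \code{NA}).
#'
#' @param fun function of a numeric vector returning a scalar.  If
#'   \code{vectorized = TRUE} it must also accept an \eqn{n \times G}
#'   matrix and return \eqn{n} values.
#' @param dimension problem dimension.
#' @param lower,upper scalar box bounds.
#' @param name identifier.
#' @param minimumValue,minimizer known optimum, or \code{NA} if unknown.
#' @param vectorized whether \code{fun} already handles matrix input.
#' @return an \code{\linkS4class{ObjectiveFunction}}.
#' @export
makeObjective <- function(fun, dimension, lower, upper, name = "custom",
                          minimumValue = NA_real_, minimizer = NULL,
                          vectorized = FALSE) {
  dimension <- as.integer(dimension)
  if (is.null(minimizer)) minimizer <- rep(NA_real_, dimension)
  f <- if (vectorized) fun else function(z) {
    if (is.matrix(z)) apply(z, 1L, fun) else fun(z)
  }
  new("ObjectiveFunction", name = name, dimension = dimension,
      lower = lower, upper = upper, fun = f,
      minimumValue = minimumValue, minimizer = minimizer)
}

#' Optimizer configuration
#'
#' @param variant \code{"bdhoa"} (Levy-refined, default) or \code{"dhoa"}.
#' @param popSize number of hunters \eqn{n \ge 2}.
#' @param maxIter iteration budget.
#' @param levyIndex Levy stability index \eqn{\mu \in (0, 2]}; default 3/2.
#' @param seed integer seed; \code{NULL} leaves the RNG state untouched.
#' @param swPerHunter draw the wind-speed factor per hunter (default) or
#'   once per iteration.
#' @param successorBoth use the successor position in both occurrences of
#'   the exploration update (default); \code{FALSE} keeps the leader in
#'   the distance term for sensitivity analysis.
#' @return a list of class \code{"huntConfig"}.
#' @seealso \code{\link{deerHunt}}
#' @export
huntConfig <- function(variant = c("bdhoa", "dhoa"), popSize = 30L,
                       maxIter = 500L, levyIndex = 1.5, seed = NULL,
                       swPerHunter = TRUE, successorBoth = TRUE) {
  variant <- match.arg(variant)
  popSize <- as.integer(popSize)
  maxIter <- as.integer(maxIter)
  if (is.na(popSize) || popSize < 2L)
    stop("popSize must be >= 2 (leader and successor must be distinct)")
  if (is.na(maxIter) || maxIter < 0L)
    stop("maxIter must be a non-negative integer")
  if (!is.numeric(levyIndex) || levyIndex <= 0 || levyIndex > 2)
    stop("levyIndex must lie in (0, 2]")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(variant = variant, popSize = popSize, maxIter = maxIter,
                 levyIndex = levyIndex, seed = seed,
                 swPerHunter = isTRUE(swPerHunter),
                 successorBoth = isTRUE(successorBoth)),
            class = "huntConfig")
}

#' Iteration coefficient k
#'
#' \eqn{k = 0.25 \log(j + 1/I_{max}) \gamma} with natural log; \eqn{\gamma}
#' is redrawn in \eqn{[-1, 1]} per hunter per iteration.
#'
#' @param iter current iteration \eqn{j \ge 1}.
#' @param maxIter iteration budget \eqn{I_{max}}.
#' @param gamma numeric in \eqn{[-1, 1]} (vectorized).
#' @return numeric, same length as \code{gamma}.
#' @export
coefficientK <- function(iter, maxIter, gamma) {
  if (iter < 1L) stop("iter must be >= 1")
  if (any(abs(gamma) > 1)) stop("gamma must lie in [-1, 1]")
  0.25 * log(iter + 1 / maxIter) * gamma
}

.checkSameLength <- function(...) {
  lens <- vapply(list(...), length, 1L)
  if (length(unique(lens)) != 1L) stop("position vectors differ in length")
}

#' Encircling (leader-based exploitation) update
#'
#' \eqn{Z_{j+1} = Z_L - k\, S_w\, L\, |Z_L - Z_j|}, coordinate-wise.
#'
#' @param zj current position.
#' @param zl leader position (same length).
#' @param k,sw,L scalar iteration draws.
#' @return updated position vector.
#' @export
encircleUpdate <- function(zj, zl, k, sw, L) {
  .checkSameLength(zj, zl)
  zl - k * sw * L * abs(zl - zj)
}

#' Position-angle update
#'
#' Visual angle \eqn{u = (\pi/8)\alpha}, angle difference \eqn{C = \beta - u},
#' new position angle \eqn{\phi_{j+1} = \phi_j + C}.
#'
#' @param phi current position angle (radians).
#' @param beta wind angle (radians).
#' @param alpha uniform draw in \eqn{[0, 1]}.
#' @return the updated angle \eqn{\phi_{j+1}} (vectorized).
#' @export
angleUpdate <- function(phi, beta, alpha) {
  phi + beta - (pi / 8) * alpha
}

#' Angle-based position update
#'
#' \eqn{Z_{j+1} = Z_j - S_w \cos(\phi_{j+1}) |Z_L - Z_j|}, coordinate-wise.
#'
#' @param zj current position.
#' @param zl leader position.
#' @param sw scalar wind-speed factor in \eqn{[0, 2]}.
#' @param phiNext updated position angle.
#' @return updated position vector.
#' @export
anglePositionUpdate <- function(zj, zl, sw, phiNext) {
  .checkSameLength(zj, zl)
  zj - sw * cos(phiNext) * abs(zl - zj)
}

#' Successor-based exploration update
#'
#' \eqn{Z_{j+1} = Z_s - k\, S_w\, L\, |Z_s - Z_j|}, coordinate-wise (the
#' successor appears in both occurrences by default; see
#' \code{\link{huntConfig}}).
#'
#' @param zj current position.
#' @param zs successor position.
#' @param k,sw,L scalar iteration draws.
#' @param zl leader position, used in the distance term only when
#'   \code{successorBoth = FALSE}.
#' @param successorBoth see \code{\link{huntConfig}}.
#' @return updated position vector.
#' @export
successorUpdate <- function(zj, zs, k, sw, L, zl = zs, successorBoth = TRUE) {
  .checkSameLength(zj, zs)
  ref <- if (successorBoth) zs else zl
  zs - k * sw * L * abs(ref - zj)
}

#' Mantegna scale for Levy-stable steps
#'
#' Closed-form \eqn{\sigma_u} so that \eqn{R/|T|^{1/\mu}} with
#' \eqn{R \sim N(0, \sigma_u^2)}, \eqn{T \sim N(0, 1)} has a symmetric
#' Levy-stable tail with index \eqn{\mu}.
#'
#' @param mu stability index in \eqn{(0, 2]}.
#' @return the scale \eqn{\sigma_u} (about 0.6966 at \eqn{\mu = 3/2}).
#' @export
levySigma <- function(mu) {
  if (mu <= 0 || mu > 2) stop("mu must lie in (0, 2]")
  (gamma(1 + mu) * sin(pi * mu / 2) /
     (gamma((1 + mu) / 2) * mu * 2^((mu - 1) / 2)))^(1 / mu)
}

#' Draw Levy-flight steps
#'
#' Mantegna's method: \eqn{D = R / |T|^{1/\mu}} with
#' \eqn{R \sim N(0, \sigma_u^2)} and \eqn{T \sim N(0, 1)}.
#'
#' @param n number of draws.
#' @param mu stability index in \eqn{(0, 2]}; default 3/2.
#' @return numeric vector of heavy-tailed symmetric steps.
#' @export
levyStep <- function(n, mu = 1.5) {
  sigma <- levySigma(mu)
  stats::rnorm(n, sd = sigma) / abs(stats::rnorm(n))^(1 / mu)
}

#' Levy-flight position refinement (Balanced variant)
#'
#' \eqn{R = u(2r - 1)} with \eqn{u \sim U[0,2]}, \eqn{r \sim U[0,1]};
#' \eqn{G = |Z_{rand} - Z_{cur}|} coordinate-wise; the refined position is
#' \eqn{Z_{cand} + (Z_{best} - R\,G) \cdot Le} with one Levy step per
#' coordinate.
#'
#' @param zCandidate position proposed by the basic update.
#' @param zBest best position seen so far.
#' @param zRandom a population member drawn at random (excluding the
#'   current hunter).
#' @param zCurrent the hunter's pre-update position.
#' @param mu Levy stability index.
#' @return refined position vector (not yet greedily accepted).
#' @export
levyRefine <- function(zCandidate, zBest, zRandom, zCurrent, mu = 1.5) {
  .checkSameLength(zCandidate, zBest, zRandom, zCurrent)
  u <- stats::runif(1, 0, 2)
  r <- stats::runif(1)
  R <- u * (2 * r - 1)
  G <- abs(zRandom - zCurrent)
  zCandidate + (zBest - R * G) * levyStep(length(zCandidate), mu)
}

#' Greedy acceptance of a refined position
#'
#' Keeps the refined position only when strictly fitter (lower objective);
#' ties keep the unrefined candidate.
#'
#' @param zRefined,zCandidate positions to compare.
#' @param objective an \code{\linkS4class{ObjectiveFunction}} or plain
#'   function.
#' @return the selected position.
#' @export
greedySelect <- function(zRefined, zCandidate, objective) {
  f <- if (is(objective, "ObjectiveFunction")) objective@fun else objective
  if (f(zRefined) < f(zCandidate)) zRefined else zCandidate
}

.clipBox <- function(m, lower, upper) {
  m[m < lower] <- lower
  m[m > upper] <- upper
  m
}

#' Initialize a hunter population
#'
#' Draws \code{popSize} positions uniformly in the objective's box,
#' evaluates them, and sets leader (best) and successor (second best).
#'
#' @param objective an \code{\linkS4class{ObjectiveFunction}}.
#' @param config a \code{\link{huntConfig}}.
#' @return a list with elements \code{positions} (n x G matrix),
#'   \code{fitness}, \code{phi} (position angles), \code{bestPosition},
#'   \code{bestFitness}, \code{successor}, \code{evaluations}.
#' @export
initializePopulation <- function(objective, config) {
  stopifnot(is(objective, "ObjectiveFunction"))
  n <- config$popSize
  G <- objective@dimension
  if (!(objective@lower < objective@upper))
    stop("degenerate box: lower must be < upper")
  pos <- matrix(stats::runif(n * G, objective@lower, objective@upper),
                nrow = n, ncol = G)
  fit <- objective@fun(pos)
  ord <- order(fit)
  phi <- pi + 2 * pi * stats::runif(n)   # initial position angles
  list(positions = pos, fitness = fit, phi = phi,
       bestPosition = pos[ord[1L], ], bestFitness = fit[ord[1L]],
       successor = pos[ord[2L], ], evaluations = n)
}

#' One iteration of the (B)DHOA population update
#'
#' For each hunter: draw the iteration randoms; with \eqn{|L| < 1}
#' (exploitation) move relative to the leader — encircling when
#' \eqn{S_w < 1}, angle-based otherwise; with \eqn{|L| \ge 1}
#' (exploration) move relative to the successor.  The Balanced variant
#' then applies the Levy refinement with greedy acceptance.  Positions
#' are clipped to the box, hunters landing on non-finite fitness are
#' redrawn uniformly, and the leader retains the best solution ever seen
#' (elitism).
#'
#' @param state population state from \code{\link{initializePopulation}}
#'   or a previous step.
#' @param objective an \code{\linkS4class{ObjectiveFunction}}.
#' @param iter current iteration number (1-based).
#' @param config a \code{\link{huntConfig}}.
#' @return the updated state list.
#' @export
deerHuntStep <- function(state, objective, iter, config) {
  n <- config$popSize
  G <- objective@dimension
  pos <- state$positions
  lower <- objective@lower; upper <- objective@upper

  alpha <- stats::runif(n)
  beta  <- 2 * pi * alpha                    # wind angle
  delta <- stats::runif(n)
  L     <- 2 * delta
  sw    <- if (config$swPerHunter) stats::runif(n, 0, 2)
           else rep(stats::runif(1, 0, 2), n)
  gam   <- stats::runif(n, -1, 1)
  k     <- coefficientK(iter, config$maxIter, gam)
  phiNext <- angleUpdate(state$phi, beta, alpha)

  leader <- state$bestPosition
  succ   <- state$successor
  dl <- abs(sweep(-pos, 2L, leader, `+`))    # |Z_L - Z_j| per coordinate
  ds <- abs(sweep(-pos, 2L, succ,   `+`))    # |Z_s - Z_j|

  explore <- L >= 1
  encircle <- !explore & sw < 1
  angle    <- !explore & !encircle

  cand <- matrix(0, n, G)
  if (any(encircle)) {
    i <- which(encircle)
    cand[i, ] <- matrix(leader, length(i), G, byrow = TRUE) -
      (k[i] * sw[i] * L[i]) * dl[i, , drop = FALSE]
  }
  if (any(angle)) {
    i <- which(angle)
    cand[i, ] <- pos[i, , drop = FALSE] -
      (sw[i] * cos(phiNext[i])) * dl[i, , drop = FALSE]
  }
  if (any(explore)) {
    i <- which(explore)
    ref <- if (config$successorBoth) ds else dl
    cand[i, ] <- matrix(succ, length(i), G, byrow = TRUE) -
      (k[i] * sw[i] * L[i]) * ref[i, , drop = FALSE]
  }

  cand <- .clipBox(cand, lower, upper)
  fit <- objective@fun(cand)
  evals <- state$evaluations + n

  bad <- !is.finite(fit)
  if (any(bad)) {
    nb <- sum(bad)
    cand[bad, ] <- matrix(stats::runif(nb * G, lower, upper), nb, G)
    fit[bad] <- objective@fun(cand[bad, , drop = FALSE])
    evals <- evals + nb
    message(nb, " hunter(s) redrawn after non-finite fitness")
  }

  if (config$variant == "bdhoa") {
    # random member per hunter, excluding self, from the pre-update population
    others <- sample.int(n - 1L, n, replace = TRUE)
    others <- others + (others >= seq_len(n))
    u <- stats::runif(n, 0, 2)
    r <- stats::runif(n)
    R <- u * (2 * r - 1)
    Gmat <- abs(pos[others, , drop = FALSE] - pos)
    Le <- matrix(levyStep(n * G, config$levyIndex), n, G)
    refined <- cand +
      (matrix(leader, n, G, byrow = TRUE) - R * Gmat) * Le
    refined <- .clipBox(refined, lower, upper)
    rfit <- objective@fun(refined)
    evals <- evals + n
    keep <- is.finite(rfit) & rfit < fit
    if (any(keep)) {
      cand[keep, ] <- refined[keep, , drop = FALSE]
      fit[keep] <- rfit[keep]
    }
  }

  ord <- order(fit)
  bestPos <- state$bestPosition
  bestFit <- state$bestFitness
  if (fit[ord[1L]] < bestFit) {
    bestFit <- fit[ord[1L]]
    bestPos <- cand[ord[1L], ]
  }
  list(positions = cand, fitness = fit, phi = phiNext,
       bestPosition = bestPos, bestFitness = bestFit,
       successor = cand[ord[2L], ], evaluations = evals)
}

#' Run the (Balanced) Deer Hunting Optimization Algorithm
#'
#' Seeded population search over the objective's box.  The best-so-far
#' fitness trajectory is recorded per iteration and is non-increasing.
#'
#' @param objective an \code{\linkS4class{ObjectiveFunction}} (see
#'   \code{\link{getBenchmark}} or \code{\link{makeObjective}}).
#' @param config a \code{\link{huntConfig}}.
#' @return a \code{\linkS4class{HuntResult}}.
#' @examples
#' res <- deerHunt(getBenchmark("sphere", 2),
#'                 huntConfig(popSize = 10, maxIter = 100, seed = 1))
#' bestFitness(res)
#' @export
deerHunt <- function(objective, config = huntConfig()) {
  stopifnot(is(objective, "ObjectiveFunction"), inherits(config, "huntConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- initializePopulation(objective, config)
  history <- numeric(config$maxIter)
  iter <- 0L
  while (iter < config$maxIter) {
    iter <- iter + 1L
    state <- deerHuntStep(state, objective, iter, config)
    history[iter] <- state$bestFitness
  }
  if (config$maxIter == 0L) history <- state$bestFitness
  new("HuntResult",
      bestPosition = state$bestPosition,
      bestFitness  = state$bestFitness,
      history      = history,
      evaluations  = as.integer(state$evaluations),
      config       = unclass(config))
}

#' @rdname HuntResult-accessors
#' @name HuntResult-accessors
#' @title Accessors for HuntResult
#' @param x a \code{\linkS4class{HuntResult}}
#' @return \code{bestFitness}: the best objective value;
#'   \code{bestPosition}: the minimizing position;
#'   \code{fitnessHistory}: per-iteration best-so-far values.
NULL

#' @rdname HuntResult-accessors
#' @export
bestFitness <- function(x) x@bestFitness

#' @rdname HuntResult-accessors
#' @export
bestPosition <- function(x) x@bestPosition

#' @rdname HuntResult-accessors
#' @export
fitnessHistory <- function(x) x@history

#' Multi-run mean/standard-deviation benchmark study
#'
#' Runs each optimizer variant on each benchmark for \code{nRuns}
#' independent seeded runs and reports, per (algorithm, benchmark) pair,
#' the mean deviation MD (mean over runs of the absolute difference
#' between the final best fitness and the known global optimum) and the
#' standard deviation SD of the final best fitness across runs.  Run
#' seeds are paired across variants so comparisons are matched.
#'
#' @param benchmarks character vector of benchmark names
#'   (see \code{\link{benchmarkNames}}).
#' @param variants subset of \code{c("dhoa", "bdhoa")}.
#' @param dimension problem dimension (default 30).
#' @param nRuns number of independent runs per pair (>= 2).
#' @param popSize,maxIter optimizer budget per run.
#' @param seed base seed; run \eqn{i} uses \code{seed + i - 1}.
#' @return a data.frame with columns algorithm, fn, dimension, runs,
#'   MD, SD.
#' @examples
#' \donttest{
#' runBenchmarkStudy("sphere", nRuns = 3, maxIter = 50, seed = 1)
#' }
#' @export
runBenchmarkStudy <- function(benchmarks = benchmarkNames(),
                              variants = c("dhoa", "bdhoa"),
                              dimension = 30L, nRuns = 30L,
                              popSize = 30L, maxIter = 500L, seed = 1L) {
  if (nRuns < 2L) stop("nRuns must be >= 2")
  variants <- match.arg(variants, c("dhoa", "bdhoa"), several.ok = TRUE)
  rows <- list()
  for (bm in benchmarks) {
    objective <- getBenchmark(bm, dimension)
    for (v in variants) {
      best <- vapply(seq_len(nRuns), function(i) {
        cfg <- huntConfig(variant = v, popSize = popSize,
                          maxIter = maxIter, seed = seed + i - 1L)
        bestFitness(deerHunt(objective, cfg))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = v, fn = bm, dimension = dimension, runs = nRuns,
        MD = mean(abs(best - objective@minimumValue)),
        SD = stats::sd(best))
    }
  }
  do.call(rbind, rows)
}
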
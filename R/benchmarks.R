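## Benchmark objective functions for validating the optimizer.
## All four accept a numeric vector or an n x G matrix of row vectors and
## are exact-zero at their known global minimizer.

.asRowMatrix <- function(z, minCols = 1L, what = "z") {
  if (is.matrix(z)) m <- z
  else if (is.numeric(z)) m <- matrix(z, nrow = 1L)
  else stop(what, " must be a numeric vector or matrix")
  if (ncol(m) < minCols)
    stop(what, " must have at least ", minCols, " coordinate(s)")
  if (!all(is.finite(m)))
    stop(what, " contains non-finite values")
  m
}

.scalarOrVector <- function(v, z) if (is.matrix(z)) v else v[1L]

#' Rastrigin benchmark function
#'
#' \deqn{f(z) = 10G + \sum_j (z_j^2 - 10\cos 2\pi z_j)}
#' Highly multimodal; global minimum 0 at the origin.
#'
#' @param z numeric vector of length \eqn{G \ge 1}, or an \eqn{n \times G}
#'   matrix evaluated row-wise.
#' @return numeric value (or vector of values for matrix input).
#' @examples
#' rastrigin(rep(0, 30))   # 0
#' rastrigin(c(0.5, 0.5))  # 40.5
#' @export
rastrigin <- function(z) {
  m <- .asRowMatrix(z)
  v <- 10 * ncol(m) + rowSums(m^2 - 10 * cos(2 * pi * m))
  .scalarOrVector(v, z)
}

#' Rosenbrock benchmark function
#'
#' \deqn{f(z) = \sum_{j=1}^{G-1} [100 (z_{j+1} - z_j^2)^2 + (z_j - 1)^2]}
#' Narrow curved valley; global minimum 0 at \eqn{(1, \ldots, 1)}.
#'
#' @inheritParams rastrigin
#' @return numeric value(s).
#' @examples
#' rosenbrock(rep(1, 30))  # 0
#' rosenbrock(c(-1, 1))    # 4
#' @export
rosenbrock <- function(z) {
  m <- .asRowMatrix(z, minCols = 2L)
  G <- ncol(m)
  a <- m[, -G, drop = FALSE]
  b <- m[, -1L, drop = FALSE]
  v <- rowSums(100 * (b - a^2)^2 + (a - 1)^2)
  .scalarOrVector(v, z)
}

#' Ackley benchmark function
#'
#' \deqn{f(z) = 20 + e - 20 \exp(-0.2\sqrt{\frac1G\sum z_j^2})
#'   - \exp(\frac1G\sum \cos 2\pi z_j)}
#' Nearly flat outer region with a deep central funnel; global minimum 0
#' at the origin.
#'
#' @inheritParams rastrigin
#' @return numeric value(s).
#' @examples
#' ackley(rep(0, 30))  # 0
#' @export
ackley <- function(z) {
  m <- .asRowMatrix(z)
  G <- ncol(m)
  v <- 20 + exp(1) -
    20 * exp(-0.2 * sqrt(rowSums(m^2) / G)) -
    exp(rowSums(cos(2 * pi * m)) / G)
  .scalarOrVector(v, z)
}

#' Sphere benchmark function
#'
#' \deqn{f(z) = \sum_j z_j^2}; unimodal, global minimum 0 at the origin.
#'
#' @inheritParams rastrigin
#' @return numeric value(s).
#' @examples
#' sphere(c(1, 2))  # 5
#' @export
sphere <- function(z) {
  m <- .asRowMatrix(z)
  .scalarOrVector(rowSums(m^2), z)
}

.benchmarkRegistry <- list(
  rastrigin  = list(fun = rastrigin,  lower = -512,   upper = 512),
  rosenbrock = list(fun = rosenbrock, lower = -2.045, upper = 2.045),
  ackley     = list(fun = ackley,     lower = -10,    upper = 10),
  sphere     = list(fun = sphere,     lower = -512,   upper = 512)
)

#' Look up a benchmark objective by name
#'
#' Returns an \code{\linkS4class{ObjectiveFunction}} carrying the standard
#' box constraints (Rastrigin and Sphere on \eqn{[-512, 512]}, Rosenbrock
#' on \eqn{[-2.045, 2.045]}, Ackley on \eqn{[-10, 10]}) and the known
#' global optimum (value 0 in every case).
#'
#' @param name one of \code{"rastrigin"}, \code{"rosenbrock"},
#'   \code{"ackley"}, \code{"sphere"}.
#' @param dimension problem dimension \eqn{G \ge 2}; the comparative study
#'   uses 30 by default.
#' @return an \code{ObjectiveFunction}.
#' @examples
#' getBenchmark("sphere", 30)
#' @export
getBenchmark <- function(name, dimension = 30L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.benchmarkRegistry))
    stop("unknown benchmark '", name, "'; valid names: ",
         paste(names(.benchmarkRegistry), collapse = ", "))
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 2L)
    stop("dimension must be an integer >= 2")
  entry <- .benchmarkRegistry[[name]]
  minimizer <- if (name == "rosenbrock") rep(1, dimension) else rep(0, dimension)
  new("ObjectiveFunction",
      name = name, dimension = dimension,
      lower = entry$lower, upper = entry$upper,
      fun = entry$fun,
      minimumValue = 0, minimizer = minimizer)
}

#' Names of the available benchmark functions
#' @return character vector of registry names.
#' @export
benchmarkNames <- function() names(.benchmarkRegistry)
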
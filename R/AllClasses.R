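#' @import methods
NULL

#' Bounded objective function with a known global optimum
#'
#' An \code{ObjectiveFunction} bundles a real-valued function over a box
#' \eqn{[lower, upper]^G} with the metadata the optimizer and the study
#' harness need: dimension, per-coordinate bounds, and the known global
#' minimum (value and minimizer).  The four classic benchmark surfaces
#' used to validate the optimizer (Rastrigin, Rosenbrock, Ackley, Sphere)
#' are provided through \code{\link{getBenchmark}}.
#'
#' @slot name benchmark identifier.
#' @slot dimension problem dimension \eqn{G} (positive integer).
#' @slot lower,upper scalar per-coordinate box bounds, \code{lower < upper}.
#' @slot fun the objective; maps a numeric \eqn{G}-vector (or an
#'   \eqn{n \times G} matrix of row vectors) to numeric value(s).
#' @slot minimumValue the global minimum value.
#' @slot minimizer a \eqn{G}-vector attaining the minimum.
#'
#' @seealso \code{\link{getBenchmark}}, \code{\link{deerHunt}}
#' @export
setClass("ObjectiveFunction",
  representation(
    name         = "character",
    dimension    = "integer",
    lower        = "numeric",
    upper        = "numeric",
    fun          = "function",
    minimumValue = "numeric",
    minimizer    = "numeric"
  )
)

setValidity("ObjectiveFunction", function(object) {
  msg <- character()
  if (length(object@dimension) != 1L || object@dimension < 1L)
    msg <- c(msg, "dimension must be a single positive integer")
  if (!(length(object@lower) == 1L && length(object@upper) == 1L))
    msg <- c(msg, "lower and upper must be scalars")
  else if (!(is.finite(object@lower) && is.finite(object@upper) &&
             object@lower < object@upper))
    msg <- c(msg, "bounds must be finite with lower < upper")
  if (length(object@minimizer) != object@dimension)
    msg <- c(msg, "minimizer length must equal dimension")
  else if (!anyNA(object@minimizer) && !is.na(object@minimumValue)) {
    at <- object@fun(object@minimizer)
    if (!isTRUE(abs(at - object@minimumValue) <= 1e-12))
      msg <- c(msg, sprintf(
        "fun(minimizer) = %.3e does not equal minimumValue = %.3e",
        at, object@minimumValue))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ObjectiveFunction compact display
#' @param object an \code{ObjectiveFunction}
#' @export
setMethod("show", "ObjectiveFunction", function(object) {
  cat("ObjectiveFunction:", object@name, "\n")
  cat(sprintf("  dimension %d, box [%g, %g], global minimum %g\n",
              object@dimension, object@lower, object@upper,
              object@minimumValue))
})

#' Result of a deer-hunting optimization run
#'
#' Holds the best position and fitness found, the per-iteration
#' best-so-far trajectory (monotonically non-increasing by elitism),
#' the number of objective evaluations spent, and an echo of the
#' configuration so runs are re-derivable.
#'
#' @slot bestPosition numeric \eqn{G}-vector, clipped to the box.
#' @slot bestFitness best objective value found.
#' @slot history best-so-far fitness after each iteration.
#' @slot evaluations total objective evaluations.
#' @slot config the \code{huntConfig()} list used.
#'
#' @seealso \code{\link{deerHunt}}
#' @export
setClass("HuntResult",
  representation(
    bestPosition = "numeric",
    bestFitness  = "numeric",
    history      = "numeric",
    evaluations  = "integer",
    config       = "list"
  )
)

setValidity("HuntResult", function(object) {
  msg <- character()
  h <- object@history
  if (length(h) && any(diff(h) > 1e-12))
    msg <- c(msg, "history must be non-increasing")
  if (length(h) && abs(object@bestFitness - h[length(h)]) > 1e-12)
    msg <- c(msg, "bestFitness must equal last history entry")
  if (length(msg)) msg else TRUE
})

#' @describeIn HuntResult compact display
#' @param object a \code{HuntResult}
#' @export
setMethod("show", "HuntResult", function(object) {
  cat(sprintf("HuntResult (%s): best fitness %.6g after %d iterations (%d evaluations)\n",
              object@config$variant %||% "?", object@bestFitness,
              length(object@history), object@evaluations))
})

#' Trained linear combiner for the four-filter hybrid denoiser
#'
#' The hybrid denoiser passes an image through four parallel noise-removal
#' filters (median, mean, Gaussian, Wiener-type) and fuses their outputs.
#' The fusion stage is a least-squares linear combiner: per-filter weights
#' plus an intercept fitted on noisy/clean training pairs.
#'
#' @slot weights numeric length-4 vector of per-filter weights
#'   (median, mean, gaussian, wiener order).
#' @slot bias scalar intercept.
#' @slot nPairs number of training pairs used.
#' @slot trainMSE mean squared error of the combined output on the
#'   training pixels.
#'
#' @seealso \code{\link{trainCombiner}}, \code{\link{hybridFilter}}
#' @export
setClass("CombinerModel",
  representation(
    weights  = "numeric",
    bias     = "numeric",
    nPairs   = "integer",
    trainMSE = "numeric"
  )
)

setValidity("CombinerModel", function(object) {
  if (length(object@weights) != 4L || any(!is.finite(object@weights)))
    return("weights must be 4 finite reals")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    return("bias must be a finite scalar")
  TRUE
})

#' @describeIn CombinerModel compact display
#' @param object a \code{CombinerModel}
#' @export
setMethod("show", "CombinerModel", function(object) {
  cat("CombinerModel (4-filter least-squares fusion)\n")
  cat("  weights:", paste(sprintf("%.4f", object@weights), collapse = " "),
      sprintf(" bias %.4f\n", object@bias))
  cat(sprintf("  trained on %d pair(s), training MSE %.3e\n",
              object@nPairs, object@trainMSE))
})

#' Fitted independent component analysis model for feature reduction
#'
#' Centering/standardization vectors, the PCA whitening transform and the
#' orthogonal unmixing rotation estimated by the fixed-point (logcosh)
#' ICA iteration.  \code{\link{icaTransform}} maps feature vectors to the
#' \eqn{m} independent coordinates.
#'
#' @slot center per-feature training means.
#' @slot scale per-feature training standard deviations (1 where constant).
#' @slot whitening \eqn{m \times p} whitening matrix (applied to the
#'   standardized features).
#' @slot unmixing \eqn{m \times m} orthogonal rotation.
#' @slot nComponents number of components \eqn{m}.
#' @slot seed RNG seed used for the fit.
#' @slot converged logical; fixed-point iteration reached tolerance.
#'
#' @seealso \code{\link{fitICA}}, \code{\link{icaTransform}}
#' @export
setClass("ICAModel",
  representation(
    center      = "numeric",
    scale       = "numeric",
    whitening   = "matrix",
    unmixing    = "matrix",
    nComponents = "integer",
    seed        = "integer",
    converged   = "logical"
  )
)

setValidity("ICAModel", function(object) {
  m <- object@nComponents
  if (nrow(object@whitening) != m) return("whitening must have m rows")
  if (!all(dim(object@unmixing) == c(m, m))) return("unmixing must be m x m")
  if (length(object@center) != ncol(object@whitening))
    return("center length must equal whitening columns")
  TRUE
})

#' @describeIn ICAModel compact display
#' @param object an \code{ICAModel}
#' @export
setMethod("show", "ICAModel", function(object) {
  cat(sprintf("ICAModel: %d features -> %d components (%s)\n",
              length(object@center), object@nComponents,
              if (object@converged) "converged" else "max sweeps reached"))
})

#' Architecture of the small metaheuristic-trained convolutional network
#'
#' An ordered list of layer specifications — valid (no-padding) stride-1
#' convolutions, ReLU, non-overlapping max pooling, flatten, dense — ending
#' in a softmax over the class scores.  The total parameter count is fixed
#' by the architecture; weights live in a flat vector with a bijective
#' packing (\code{\link{packWeights}} / \code{\link{unpackWeights}}) so a
#' population-based optimizer can search the weight space directly.
#'
#' @slot layers list of layer specs (each a list with a \code{type} field).
#' @slot inputShape integer c(height, width) of the grayscale input.
#' @slot nClasses number of output classes.
#' @slot nParams total trainable parameter count.
#'
#' @seealso \code{\link{cnnArchitecture}}, \code{\link{cnnForward}},
#'   \code{\link{trainCNN}}
#' @export
setClass("CNNArchitecture",
  representation(
    layers     = "list",
    inputShape = "integer",
    nClasses   = "integer",
    nParams    = "integer"
  )
)

#' @describeIn CNNArchitecture compact display
#' @param object a \code{CNNArchitecture}
#' @export
setMethod("show", "CNNArchitecture", function(object) {
  cat(sprintf("CNNArchitecture: %dx%d input, %d classes, %d parameters\n",
              object@inputShape[1], object@inputShape[2],
              object@nClasses, object@nParams))
  for (l in object@layers) {
    cat(" ", switch(l$type,
      conv    = sprintf("conv %dx%d, %d -> %d channels", l$kh, l$kw, l$cin, l$cout),
      relu    = "relu",
      maxpool = sprintf("maxpool %dx%d (stride %d)", l$size, l$size, l$size),
      flatten = "flatten",
      dense   = sprintf("dense %d -> %d", l$nin, l$nout),
      softmax = "softmax",
      l$type), "\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
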
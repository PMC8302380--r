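## Independent component analysis for feature-dimension reduction.
## Per-feature standardization, PCA whitening to m components, then the
## symmetric fixed-point iteration with the logcosh contrast.

.symDecorrelate <- function(W) {
  # W <- (W W^T)^{-1/2} W
  s <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(s$values, 1e-12)
  s$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(s$vectors) %*% W
}

#' Fit an ICA reduction model
#'
#' Centers and standardizes the feature columns, whitens with the top
#' \eqn{m} principal components, and estimates an orthogonal unmixing
#' rotation by the symmetric fixed-point iteration (logcosh
#' non-linearity, tolerance \code{1e-4}, at most 200 sweeps).
#' Deterministic under \code{seed}.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param m number of independent components
#'   (\eqn{m \le \min(n_{samples} - 1, n_{features})}).
#' @param seed integer seed for the random initial rotation.
#' @param tol fixed-point convergence tolerance.
#' @param maxSweeps iteration cap.
#' @param standardize divide each feature by its training standard
#'   deviation before whitening (default TRUE; features of zero variance
#'   are left unscaled).
#' @return an \code{\linkS4class{ICAModel}}.
#' @export
fitICA <- function(X, m = 20L, seed = 1L, tol = 1e-4, maxSweeps = 200L,
                   standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  m <- as.integer(m)
  if (n <= m) stop("need more samples than components (n = ", n, ", m = ", m, ")")
  center <- colMeans(X)
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, p)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, `/`)

  cv <- stats::cov(Xs)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (m > rank)
    stop("m = ", m, " exceeds the data rank (", rank, ")")
  Kmat <- t(eg$vectors[, seq_len(m), drop = FALSE]) / sqrt(eg$values[seq_len(m)])
  Z <- Xs %*% t(Kmat)                     # whitened: cov(Z) = I

  set.seed(seed)
  W <- .symDecorrelate(matrix(stats::rnorm(m * m), m, m))
  converged <- FALSE
  for (s in seq_len(maxSweeps)) {
    WX <- Z %*% t(W)                      # n x m source estimates
    g  <- tanh(WX)
    gp <- 1 - g^2
    Wnew <- (t(g) %*% Z) / n - diag(colMeans(gp), m) %*% W
    Wnew <- .symDecorrelate(Wnew)
    delta <- max(abs(abs(diag(Wnew %*% t(W))) - 1))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  new("ICAModel", center = center, scale = scl,
      whitening = Kmat, unmixing = W,
      nComponents = m, seed = as.integer(seed), converged = converged)
}

#' Project features onto the independent components
#'
#' Applies the training centering/standardization, the whitening
#' transform, and the unmixing rotation.  The training mean maps to the
#' origin; component coordinates are uncorrelated on the training data.
#'
#' @param model an \code{\linkS4class{ICAModel}}.
#' @param X numeric vector (one sample) or matrix (samples in rows).
#' @return matrix of reduced coordinates, \code{nComponents} columns.
#' @export
icaTransform <- function(model, X) {
  if (!is(model, "ICAModel")) stop("model must be an ICAModel")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model@center))
    stop("feature dimension mismatch: got ", ncol(X), ", expected ",
         length(model@center))
  Xs <- sweep(sweep(X, 2L, model@center), 2L, model@scale, `/`)
  Xs %*% t(model@whitening) %*% t(model@unmixing)
}

#' Serialize / restore an ICA model as JSON
#'
#' Matrices are stored row-major with shape metadata.
#'
#' @param model an \code{\linkS4class{ICAModel}}.
#' @param path JSON file path.
#' @return \code{writeICA}: the path, invisibly; \code{readICA}: the model.
#' @export
writeICA <- function(model, path) {
  jsonlite::write_json(list(
    center = model@center, scale = model@scale,
    whitening = list(dim = dim(model@whitening),
                     data = as.vector(t(model@whitening))),
    unmixing = list(dim = dim(model@unmixing),
                    data = as.vector(t(model@unmixing))),
    nComponents = model@nComponents, seed = model@seed,
    converged = model@converged), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeICA
#' @export
readICA <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ICAModel",
      center = as.numeric(x$center), scale = as.numeric(x$scale),
      whitening = matrix(x$whitening$data, x$whitening$dim[1],
                         x$whitening$dim[2], byrow = TRUE),
      unmixing = matrix(x$unmixing$data, x$unmixing$dim[1],
                        x$unmixing$dim[2], byrow = TRUE),
      nComponents = as.integer(x$nComponents), seed = as.integer(x$seed),
      converged = as.logical(x$converged))
}
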
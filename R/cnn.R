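## A small convolutional network evaluated layer-by-layer on image batches:
## valid (no-padding) stride-1 convolutions, ReLU, non-overlapping max
## pooling, flatten, dense, softmax.  Weights live in a flat vector with a
## bijective packing so the BDHOA metaheuristic can search the weight space
## directly (no backpropagation anywhere).

#' Construct a CNN architecture
#'
#' Builds an architecture from a layer list and verifies that consecutive
#' shapes chain.  Convolutions are valid (no padding), stride 1; max
#' pooling is non-overlapping (window = stride), truncating any remainder.
#'
#' Layer specs: \code{list(type = "conv", kh, kw, cout)},
#' \code{list(type = "relu")}, \code{list(type = "maxpool", size)},
#' \code{list(type = "flatten")}, \code{list(type = "dense", nout)};
#' a final softmax is appended automatically.  Input channel counts and
#' dense input sizes are inferred while chaining.
#'
#' @param layers list of layer specs (without softmax).
#' @param inputShape integer c(height, width) of grayscale inputs.
#' @param nClasses number of classes; the last dense layer must end here.
#' @return a \code{\linkS4class{CNNArchitecture}}.
#' @seealso \code{\link{tinyCNN}} for the default small architecture.
#' @export
cnnArchitecture <- function(layers, inputShape, nClasses) {
  inputShape <- as.integer(inputShape)
  nClasses <- as.integer(nClasses)
  h <- inputShape[1]; w <- inputShape[2]; cin <- 1L
  flat <- NA_integer_
  nPar <- 0L
  out <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    l$type <- match.arg(l$type, c("conv", "relu", "maxpool", "flatten", "dense"))
    switch(l$type,
      conv = {
        if (is.na(flat)) {
          if (h < l$kh || w < l$kw)
            stop("layer ", li, " (conv): kernel exceeds input ", h, "x", w)
          l$cin <- cin
          h <- h - l$kh + 1L; w <- w - l$kw + 1L; cin <- as.integer(l$cout)
          nPar <- nPar + l$kh * l$kw * l$cin * l$cout + l$cout
        } else stop("layer ", li, ": conv after flatten")
      },
      relu = {},
      maxpool = {
        if (h < l$size || w < l$size)
          stop("layer ", li, " (maxpool): window exceeds input ", h, "x", w)
        h <- h %/% l$size; w <- w %/% l$size
      },
      flatten = { flat <- h * w * cin },
      dense = {
        if (is.na(flat)) stop("layer ", li, ": dense requires flatten first")
        l$nin <- flat; l$nout <- as.integer(l$nout)
        nPar <- nPar + l$nin * l$nout + l$nout
        flat <- l$nout
      })
    out[[li]] <- l
  }
  if (is.na(flat)) stop("architecture must end in flatten + dense")
  if (flat != nClasses)
    stop("last dense layer has ", flat, " outputs but nClasses = ", nClasses)
  out[[length(out) + 1L]] <- list(type = "softmax")
  new("CNNArchitecture", layers = out, inputShape = inputShape,
      nClasses = nClasses, nParams = as.integer(nPar))
}

#' Default small architecture for metaheuristic training
#'
#' conv 3x3 (\code{channels[1]}) -> ReLU -> maxpool 2x2 -> conv 3x3
#' (\code{channels[2]}) -> ReLU -> maxpool 2x2 -> flatten -> dense ->
#' softmax.  Small enough that population-based weight search is
#' tractable.
#'
#' @param inputShape integer c(height, width); default c(32, 32).
#' @param nClasses number of classes.
#' @param channels output channels of the two convolutions.
#' @return a \code{\linkS4class{CNNArchitecture}}.
#' @export
tinyCNN <- function(inputShape = c(32L, 32L), nClasses, channels = c(4L, 4L)) {
  cnnArchitecture(list(
    list(type = "conv", kh = 3L, kw = 3L, cout = channels[1]),
    list(type = "relu"),
    list(type = "maxpool", size = 2L),
    list(type = "conv", kh = 3L, kw = 3L, cout = channels[2]),
    list(type = "relu"),
    list(type = "maxpool", size = 2L),
    list(type = "flatten"),
    list(type = "dense", nout = nClasses)),
    inputShape = inputShape, nClasses = nClasses)
}

#' Number of trainable parameters
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @return integer parameter count.
#' @export
nParams <- function(arch) arch@nParams

#' Unpack a flat weight vector into per-layer tensors
#'
#' The packing is bijective: convolution kernels are stored as
#' \code{(kh, kw, cin, cout)} arrays in column-major order followed by
#' their biases; dense layers as \code{(nin, nout)} matrices followed by
#' biases; layers in architecture order.
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param w numeric vector of length \code{nParams(arch)}.
#' @return list of per-layer parameter lists.
#' @export
unpackWeights <- function(arch, w) {
  if (length(w) != arch@nParams)
    stop("weight vector has length ", length(w), ", expected ", arch@nParams)
  out <- vector("list", length(arch@layers))
  pos <- 0L
  for (li in seq_along(arch@layers)) {
    l <- arch@layers[[li]]
    if (l$type == "conv") {
      nk <- l$kh * l$kw * l$cin * l$cout
      kern <- array(w[pos + seq_len(nk)], c(l$kh, l$kw, l$cin, l$cout))
      bias <- w[pos + nk + seq_len(l$cout)]
      pos <- pos + nk + l$cout
      out[[li]] <- list(kernel = kern, bias = bias)
    } else if (l$type == "dense") {
      nk <- l$nin * l$nout
      W <- matrix(w[pos + seq_len(nk)], l$nin, l$nout)
      bias <- w[pos + nk + seq_len(l$nout)]
      pos <- pos + nk + l$nout
      out[[li]] <- list(W = W, bias = bias)
    }
  }
  out
}

#' Pack per-layer tensors back into a flat weight vector
#'
#' Inverse of \code{\link{unpackWeights}}; \code{pack(unpack(w))} is
#' exact.
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param params list as returned by \code{\link{unpackWeights}}.
#' @return numeric vector of length \code{nParams(arch)}.
#' @export
packWeights <- function(arch, params) {
  w <- numeric(0)
  for (li in seq_along(arch@layers)) {
    l <- arch@layers[[li]]
    if (l$type == "conv")
      w <- c(w, as.vector(params[[li]]$kernel), params[[li]]$bias)
    else if (l$type == "dense")
      w <- c(w, as.vector(params[[li]]$W), params[[li]]$bias)
  }
  w
}

## images: list of H x W matrices -> batch array (N, H, W, 1)
.batchArray <- function(images, inputShape) {
  N <- length(images)
  a <- array(0, c(N, inputShape[1], inputShape[2], 1L))
  for (i in seq_len(N)) {
    img <- images[[i]]
    if (!all(dim(img) == inputShape))
      stop("image ", i, " has shape ", nrow(img), "x", ncol(img),
           ", expected ", inputShape[1], "x", inputShape[2])
    a[i, , , 1L] <- img
  }
  a
}

.convForward <- function(x, kern, bias) {
  d <- dim(x)  # (N, H, W, Cin)
  kh <- dim(kern)[1]; kw <- dim(kern)[2]; cin <- dim(kern)[3]; cout <- dim(kern)[4]
  OH <- d[2] - kh + 1L; OW <- d[3] - kw + 1L
  cols <- matrix(0, d[1] * OH * OW, kh * kw * cin)
  cidx <- 0L
  for (ci in seq_len(cin)) for (dc in seq_len(kw)) for (dr in seq_len(kh)) {
    cidx <- cidx + 1L
    cols[, cidx] <- x[, dr + 0:(OH - 1L), dc + 0:(OW - 1L), ci]
  }
  # weight matrix rows must follow the same (dr, dc, ci) order: that is the
  # column-major order of the (kh, kw, cin) kernel slices
  Wm <- matrix(kern, kh * kw * cin, cout)
  out <- cols %*% Wm
  out <- sweep(out, 2L, bias, `+`)
  array(out, c(d[1], OH, OW, cout))
}

.maxpoolForward <- function(x, size) {
  d <- dim(x)
  OH <- d[2] %/% size; OW <- d[3] %/% size
  out <- array(-Inf, c(d[1], OH, OW, d[4]))
  for (dr in seq_len(size)) for (dc in seq_len(size)) {
    sl <- x[, dr + size * (0:(OH - 1L)), dc + size * (0:(OW - 1L)), , drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

#' Numerically stable softmax
#'
#' \eqn{z_j = e^{f_j} / \sum_i e^{f_i}}, computed with a max shift.
#' Accepts a vector of logits or a matrix (row-wise).
#'
#' @param f numeric vector or matrix of logits.
#' @return probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(f) {
  if (is.matrix(f)) {
    e <- exp(f - apply(f, 1L, max))
    e / rowSums(e)
  } else {
    e <- exp(f - max(f))
    e / sum(e)
  }
}

#' Forward pass of the network on a batch of images
#'
#' Deterministic layer-by-layer evaluation returning class probabilities
#' and pre-softmax logits.
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param w flat weight vector (length \code{nParams(arch)}).
#' @param images a single H x W matrix or a list of them.
#' @return list with \code{probs} and \code{logits}, each
#'   \eqn{N \times nClasses}.
#' @export
cnnForward <- function(arch, w, images) {
  if (is.matrix(images)) images <- list(images)
  params <- unpackWeights(arch, w)
  x <- .batchArray(images, arch@inputShape)
  flat <- NULL
  for (li in seq_along(arch@layers)) {
    l <- arch@layers[[li]]
    switch(l$type,
      conv    = { x <- .convForward(x, params[[li]]$kernel, params[[li]]$bias) },
      relu    = { if (is.null(flat)) x[x < 0] <- 0 else flat[flat < 0] <- 0 },
      maxpool = { x <- .maxpoolForward(x, l$size) },
      flatten = { flat <- matrix(x, nrow = dim(x)[1]) },
      dense   = {
        flat <- sweep(flat %*% params[[li]]$W, 2L, params[[li]]$bias, `+`)
      },
      softmax = {})
  }
  list(probs = softmax(flat), logits = flat)
}

#' One-hot encoding of integer class labels
#'
#' @param labels integer vector in 1..nClasses.
#' @param nClasses number of classes.
#' @return \eqn{N \times nClasses} matrix of 0/1 rows summing to 1.
#' @export
oneHot <- function(labels, nClasses) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > nClasses)) stop("labels out of range")
  D <- matrix(0, length(labels), nClasses)
  D[cbind(seq_along(labels), labels)] <- 1
  D
}

#' Cross-entropy loss
#'
#' \eqn{CE = \sum_j \sum_i -D_{ji} \log z_{ji}} over samples and classes.
#' Probabilities at a true class are clamped below at \code{1e-12} (with
#' a message) so the loss stays finite.
#'
#' @param probs \eqn{N \times M} predicted probabilities.
#' @param desired \eqn{N \times M} one-hot targets.
#' @return scalar loss.
#' @export
crossEntropyLoss <- function(probs, desired) {
  if (!all(dim(probs) == dim(desired))) stop("shape mismatch")
  p <- probs[desired > 0]
  if (any(p < 1e-12)) {
    message("clamped ", sum(p < 1e-12), " zero probabilities in cross-entropy")
    p[p < 1e-12] <- 1e-12
  }
  -sum(desired[desired > 0] * log(p))
}

#' Cross-entropy with quadratic weight penalty
#'
#' \eqn{CE + (\rho/2) \sum_{k,l} V_{k,l}^2}.
#'
#' @inheritParams crossEntropyLoss
#' @param w flat weight vector.
#' @param rho non-negative penalty coefficient.
#' @return scalar loss.
#' @export
regularizedLoss <- function(probs, desired, w, rho) {
  if (rho < 0) stop("rho must be non-negative")
  crossEntropyLoss(probs, desired) + rho / 2 * sum(w^2)
}

#' Mean squared error loss
#'
#' \eqn{(1/T) \sum_j \sum_i (a_{ji} - b_{ji})^2}; by default \eqn{T} is
#' the total number of summands, making this a per-element mean.
#'
#' @param a,b numeric arrays of identical shape (outputs and targets).
#' @param T normalizer; default \code{length(a)}.
#' @return scalar loss.
#' @export
mseLoss <- function(a, b, T = length(a)) {
  if (!all(dim(a) == dim(b)) || length(a) != length(b))
    stop("shape mismatch between outputs and targets")
  sum((a - b)^2) / T
}

#' Train network weights with the Balanced DHOA
#'
#' Wraps the batch MSE between the softmax outputs and the one-hot
#' targets as a bounded objective on \eqn{[-w_{max}, w_{max}]^P} and
#' minimizes it with \code{\link{deerHunt}} — population search instead
#' of backpropagation.  The parameter count is capped so the search stays
#' tractable.
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param images list of input matrices.
#' @param labels integer labels in 1..nClasses.
#' @param config a \code{\link{huntConfig}}.
#' @param wMax weight box half-width (default 3).
#' @param paramCap refuse architectures with more parameters (default 5000).
#' @return list with \code{weights} (best flat vector), \code{result}
#'   (the \code{\linkS4class{HuntResult}}), and \code{trainAccuracy}.
#' @export
trainCNN <- function(arch, images, labels, config = huntConfig(maxIter = 300L),
                     wMax = 3, paramCap = 5000L) {
  P <- arch@nParams
  if (P > paramCap)
    stop("architecture has ", P, " parameters, above the cap of ", paramCap,
         "; population search is not tractable at this size")
  D <- oneHot(labels, arch@nClasses)
  x <- .batchArray(images, arch@inputShape)   # validate shapes once
  objective <- makeObjective(function(w) {
    out <- cnnForward(arch, w, images)
    mseLoss(out$probs, D)
  }, dimension = P, lower = -wMax, upper = wMax, name = "cnn_mse")
  res <- deerHunt(objective, config)
  pred <- cnnPredict(arch, bestPosition(res), images)
  list(weights = bestPosition(res), result = res,
       trainAccuracy = mean(pred == as.integer(labels)))
}

#' Predict class labels
#'
#' Argmax of the softmax probabilities; ties are broken toward the lowest
#' class index.
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param w flat weight vector.
#' @param images a matrix or list of matrices.
#' @return integer vector of predicted class indices (1-based).
#' @export
cnnPredict <- function(arch, w, images) {
  probs <- cnnForward(arch, w, images)$probs
  apply(probs, 1L, which.max)
}

#' Serialize / restore an architecture plus weights as JSON
#'
#' @param arch a \code{\linkS4class{CNNArchitecture}}.
#' @param w flat weight vector.
#' @param path JSON file path.
#' @return \code{writeCNN}: the path, invisibly; \code{readCNN}: a list
#'   with \code{arch} and \code{weights}.
#' @export
writeCNN <- function(arch, w, path) {
  jsonlite::write_json(list(
    inputShape = arch@inputShape, nClasses = arch@nClasses,
    layers = arch@layers, weights = w), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCNN
#' @export
readCNN <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- if (is.data.frame(x$layers)) {
    lapply(seq_len(nrow(x$layers)), function(i) {
      l <- as.list(x$layers[i, ])
      l[!vapply(l, function(v) is.na(v[1]), TRUE)]
    })
  } else x$layers
  # rebuild through the constructor so shapes are re-validated
  keep <- Filter(function(l) l$type != "softmax", layers)
  keep <- lapply(keep, function(l) l[setdiff(names(l), c("cin", "nin"))])
  arch <- cnnArchitecture(keep, inputShape = as.integer(x$inputShape),
                          nClasses = as.integer(x$nClasses))
  list(arch = arch, weights = as.numeric(x$weights))
}
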
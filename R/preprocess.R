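## Image preparation: min-max intensity normalization, bilinear resizing,
## and a four-filter hybrid denoiser (median / mean / Gaussian / Wiener-type
## local-variance filters in parallel, fused by a trained linear combiner).
## All filters use reflect padding; everything here is deterministic.

.checkImage <- function(img, minSize = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < minSize || ncol(img) < minSize)
    stop("image must be at least ", minSize, "x", minSize)
  if (!all(is.finite(img))) stop("image contains non-finite pixels")
  invisible(img)
}

#' Min-max intensity normalization to [0, 1]
#'
#' \code{(p - min) / (max - min)}; a constant image maps to all zeros.
#' Idempotent on images already spanning [0, 1].
#'
#' @param img numeric matrix of pixel intensities.
#' @return matrix with range [0, 1] (all zeros if constant).
#' @export
minmaxNormalize <- function(img) {
  .checkImage(img)
  rng <- range(img)
  if (rng[1] == rng[2]) return(array(0, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

## reflect-pad by r pixels on every side (edge pixels not duplicated)
.reflectPad <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  if (r >= H || r >= W) stop("padding radius exceeds image extent")
  ri <- c((r + 1L):2L, 1:H, (H - 1L):(H - r))
  ci <- c((r + 1L):2L, 1:W, (W - 1L):(W - r))
  img[ri, ci]
}

## stack of shifted copies covering a (2r+1)^2 neighborhood; returns an
## H*W x (2r+1)^2 matrix of neighborhood values per pixel
.neighborhoods <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  pad <- .reflectPad(img, r)
  k <- 2L * r + 1L
  out <- matrix(0, H * W, k * k)
  col <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    col <- col + 1L
    out[, col] <- pad[dr + (1:H), dc + (1:W)]
  }
  out
}

.medianFilter3 <- function(img) {
  nb <- .neighborhoods(img, 1L)
  matrix(apply(nb, 1L, stats::median), nrow(img), ncol(img))
}

.meanFilter3 <- function(img) {
  nb <- .neighborhoods(img, 1L)
  matrix(rowMeans(nb), nrow(img), ncol(img))
}

.gaussianKernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

.gaussianFilter <- function(img, sigma = 1) {
  k <- .gaussianKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  pad <- .reflectPad(img, r)
  # separable convolution: rows then columns
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * pad[(i - 1L) + (1:H), ]
  out <- matrix(0, H, W)
  for (i in seq_along(k))
    out <- out + k[i] * tmp[, (i - 1L) + (1:W)]
  out
}

## Wiener-type adaptive filter: local 3x3 mean/variance; shrink toward the
## local mean by the estimated noise-to-signal ratio (noise level = mean of
## the local variances across the image).
.wienerFilter3 <- function(img) {
  nb <- .neighborhoods(img, 1L)
  mu <- rowMeans(nb)
  vr <- rowMeans(nb^2) - mu^2
  vr[vr < 0] <- 0
  nu <- mean(vr)
  gain <- ifelse(vr > nu, (vr - nu) / vr, 0)
  matrix(mu + gain * (as.vector(img) - mu), nrow(img), ncol(img))
}

#' Four-filter denoising bank
#'
#' Passes the image in parallel through a 3x3 median filter, a 3x3 mean
#' filter, a Gaussian filter (\eqn{\sigma = 1}), and a Wiener-type local
#' variance filter (3x3 statistics, image-wide noise estimate).  All use
#' reflect padding.
#'
#' @param img numeric matrix in [0, 1] (see \code{\link{minmaxNormalize}}).
#' @return named list of four matrices: \code{median}, \code{mean},
#'   \code{gaussian}, \code{wiener}.
#' @export
filterBank <- function(img) {
  .checkImage(img, minSize = 3L)
  list(median   = .medianFilter3(img),
       mean     = .meanFilter3(img),
       gaussian = .gaussianFilter(img, 1),
       wiener   = .wienerFilter3(img))
}

#' Train the linear combiner of the hybrid denoiser
#'
#' Fits least-squares weights (plus intercept) over the four filter
#' outputs, minimizing the mean squared error to the clean image across
#' all pixels of all training pairs.
#'
#' @param pairs list of pairs; each element is a list with components
#'   \code{noisy} and \code{clean}, same-shape numeric matrices.
#' @return a \code{\linkS4class{CombinerModel}}.
#' @seealso \code{\link{hybridFilter}}
#' @export
trainCombiner <- function(pairs) {
  if (!length(pairs)) stop("at least one noisy/clean pair is required")
  X <- NULL; y <- NULL
  for (p in pairs) {
    if (!all(dim(p$noisy) == dim(p$clean)))
      stop("noisy and clean images in a pair must have the same shape")
    fb <- filterBank(p$noisy)
    X <- rbind(X, cbind(as.vector(fb$median), as.vector(fb$mean),
                        as.vector(fb$gaussian), as.vector(fb$wiener)))
    y <- c(y, as.vector(p$clean))
  }
  fit <- stats::lm.fit(cbind(1, X), y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0   # collinear filter outputs (e.g. constant images)
  new("CombinerModel",
      weights = unname(coefs[2:5]), bias = unname(coefs[1]),
      nPairs = length(pairs), trainMSE = mean(fit$residuals^2))
}

#' Apply the hybrid four-filter denoiser
#'
#' Runs the filter bank and combines the four outputs with the trained
#' weights; the result is clipped to [0, 1].
#'
#' @param img numeric matrix in [0, 1].
#' @param model a \code{\linkS4class{CombinerModel}} from
#'   \code{\link{trainCombiner}}.
#' @return denoised matrix in [0, 1].
#' @export
hybridFilter <- function(img, model) {
  if (!is(model, "CombinerModel")) stop("model must be a trained CombinerModel")
  fb <- filterBank(img)
  out <- model@bias +
    model@weights[1] * fb$median + model@weights[2] * fb$mean +
    model@weights[3] * fb$gaussian + model@weights[4] * fb$wiener
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Bilinear image resize
#'
#' Resamples with bilinear interpolation (edge-clamped, pixel-center
#' aligned).  Returns the input unchanged when the target equals the
#' current shape.
#'
#' @param img numeric matrix.
#' @param targetHW integer c(height, width); default c(250, 250).
#' @return resized matrix.
#' @export
resizeBilinear <- function(img, targetHW = c(250L, 250L)) {
  .checkImage(img)
  th <- as.integer(targetHW[1]); tw <- as.integer(targetHW[2])
  if (is.na(th) || is.na(tw) || th < 1L || tw < 1L)
    stop("target size must be positive")
  H <- nrow(img); W <- ncol(img)
  if (th == H && tw == W) return(img)
  sy <- if (th == 1L) rep(1, 1) else 1 + (seq_len(th) - 1) * (H - 1) / (th - 1)
  sx <- if (tw == 1L) rep(1, 1) else 1 + (seq_len(tw) - 1) * (W - 1) / (tw - 1)
  y0 <- pmin(floor(sy), H - 1L); y1 <- y0 + 1; wy <- sy - y0
  x0 <- pmin(floor(sx), W - 1L); x1 <- x0 + 1; wx <- sx - x0
  if (H == 1L) { y0 <- y1 <- rep(1, th); wy <- rep(0, th) }
  if (W == 1L) { x0 <- x1 <- rep(1, tw); wx <- rep(0, tw) }
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a + sweep(b - a, 2L, wx, `*`)
  bot <- c_ + sweep(d - c_, 2L, wx, `*`)
  top + sweep(bot - top, 1L, wy, `*`)
}

#' Read a grayscale image (PNG or TIFF)
#'
#' Multi-channel images are averaged to one channel; values are in [0, 1].
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a
}

#' Write a grayscale image (PNG or TIFF)
#'
#' @param img numeric matrix; values are clipped to [0, 1].
#' @param path output path ending in .png, .tif or .tiff.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  .checkImage(img)
  img[img < 0] <- 0; img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Serialize / restore a combiner model as JSON
#'
#' @param model a \code{\linkS4class{CombinerModel}}.
#' @param path JSON file path.
#' @return \code{writeCombiner}: the path, invisibly;
#'   \code{readCombiner}: the restored model.
#' @export
writeCombiner <- function(model, path) {
  jsonlite::write_json(list(weights = model@weights, bias = model@bias,
                            nPairs = model@nPairs, trainMSE = model@trainMSE),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCombiner
#' @export
readCombiner <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CombinerModel", weights = as.numeric(x$weights),
      bias = as.numeric(x$bias), nPairs = as.integer(x$nPairs),
      trainMSE = as.numeric(x$trainMSE))
}
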
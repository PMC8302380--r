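## Texture descriptors: gray-level quantization, directional co-occurrence
## matrices (GLCM), the 13 classic Haralick statistics averaged over the
## four standard directions, and 8-neighbor local binary pattern (LBP)
## histograms.  These feed the feature-path classifier after ICA reduction.

#' Quantize a [0,1] image to discrete gray levels
#'
#' \code{floor(p * levels)} capped at \code{levels - 1}, so 0 maps to level
#' 0 and 1 to the top level.
#'
#' @param img numeric matrix with values in [0, 1].
#' @param levels number of gray levels (default 16).
#' @return integer matrix with values in [0, levels - 1].
#' @export
quantizeGray <- function(img, levels = 16L) {
  .checkImage(img)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("levels must be an integer >= 2")
  if (min(img) < 0 || max(img) > 1) stop("image must lie in [0, 1]")
  q <- floor(img * levels)
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  attr(q, "levels") <- levels
  q
}

## row/col offsets per direction, distance d: the reference pixel at (r, c)
## pairs with (r + dr, c + dc).  0 degrees is horizontal; 45/90/135 go up.
.glcmOffset <- function(direction, distance) {
  switch(as.character(direction),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("direction must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray-level pairs at the given direction and
#' pixel distance.  With \code{symmetric = TRUE} the transpose is added
#' (each pair counted in both orders); with \code{normalize = TRUE} the
#' counts are divided by their total so entries sum to 1.
#'
#' @param qimg quantized image from \code{\link{quantizeGray}}.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param distance positive integer pixel offset (default 1).
#' @param symmetric add the transposed counts (default TRUE).
#' @param normalize divide by the total count (default TRUE).
#' @param levels number of gray levels; taken from the quantized image
#'   attribute when present.
#' @return levels x levels matrix.
#' @export
glcm <- function(qimg, direction = 0, distance = 1L, symmetric = TRUE,
                 normalize = TRUE, levels = attr(qimg, "levels")) {
  if (is.null(levels)) levels <- max(qimg) + 1L
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1")
  if (distance >= nrow(qimg) || distance >= ncol(qimg))
    stop("distance must be smaller than the image extent")
  off <- .glcmOffset(direction, distance)
  H <- nrow(qimg); W <- ncol(qimg)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  a <- qimg[r1, c1, drop = FALSE]
  b <- qimg[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

#' The four standard directional GLCMs
#'
#' @inheritParams glcm
#' @return named list of matrices for directions 0, 45, 90, 135.
#' @export
glcmAllDirections <- function(qimg, distance = 1L, symmetric = TRUE,
                              normalize = TRUE) {
  dirs <- c(0, 45, 90, 135)
  out <- lapply(dirs, function(d)
    glcm(qimg, d, distance, symmetric, normalize))
  names(out) <- paste0("d", dirs)
  out
}

.haralickNames <- c(
  "energy", "contrast", "correlation", "variance", "homogeneity",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2")

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

## the 13 classic second-order statistics of one normalized GLCM
.haralickOne <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized (entries sum to 1)")
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)          # row index
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))

  # diagonal-band sums: p_{x+y} over k = 2..2Ng, p_{x-y} over k = 0..Ng-1
  smn <- tapply(as.vector(P), as.vector(i + j), sum)
  pxy_sum <- numeric(2 * Ng - 1); names(pxy_sum) <- as.character(2:(2 * Ng))
  pxy_sum[names(smn)] <- smn
  dmn <- tapply(as.vector(P), as.vector(abs(i - j)), sum)
  pxy_dif <- numeric(Ng); names(pxy_dif) <- as.character(0:(Ng - 1))
  pxy_dif[names(dmn)] <- dmn

  energy <- sum(P^2)
  kdiff <- 0:(Ng - 1)
  contrast <- sum(kdiff^2 * pxy_dif)
  correlation <- if (sx * sy > 1e-12)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  ksum <- 2:(2 * Ng)
  sum_average <- sum(ksum * pxy_sum)
  sum_variance <- sum((ksum - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(.xlogx(pxy_sum))
  entropy <- -sum(.xlogx(P))
  dif_average <- sum(kdiff * pxy_dif)
  difference_variance <- sum((kdiff - dif_average)^2 * pxy_dif)
  difference_entropy <- -sum(.xlogx(pxy_dif))

  hx <- -sum(.xlogx(px)); hy <- -sum(.xlogx(py))
  pq <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pq > 0, log(pq), 0))
  hxy2 <- -sum(.xlogx(pq))
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- sqrt(max(arg, 0))

  stats::setNames(c(energy, contrast, correlation, variance, homogeneity,
                    sum_average, sum_variance, sum_entropy, entropy,
                    difference_variance, difference_entropy, imc1, imc2),
                  .haralickNames)
}

#' Haralick texture statistics averaged over four directions
#'
#' Computes the 13 classic second-order statistics (energy / angular
#' second moment, contrast, correlation, variance, homogeneity / inverse
#' difference moment, sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, and the two information
#' measures of correlation) from each normalized directional GLCM and
#' returns the per-statistic mean over directions.  Natural logarithms;
#' \eqn{0 \log 0 = 0}; correlation and IMC1 are defined as 0 for
#' degenerate (zero-variance) marginals.
#'
#' @param glcms list of normalized GLCMs, e.g. from
#'   \code{\link{glcmAllDirections}}.
#' @return named numeric vector of 13 statistics.
#' @export
haralickFeatures <- function(glcms) {
  if (!length(glcms)) stop("at least one GLCM is required")
  per <- vapply(glcms, .haralickOne, numeric(13))
  rowMeans(per)
}

## clockwise 3x3 neighbor order starting at the top-left, as (row, col)
## offsets from the center; bit weights are MSB-first in this order
.lbpOffsets <- matrix(c(-1L, -1L,  -1L, 0L,  -1L, 1L,  0L, 1L,
                        1L, 1L,   1L, 0L,   1L, -1L,  0L, -1L),
                      ncol = 2L, byrow = TRUE)

#' Local binary pattern code of a 3x3 patch
#'
#' Each of the 8 neighbors is compared with the center: a neighbor greater
#' than or equal to the center contributes bit 1, a strictly smaller one
#' bit 0.  Bits are read clockwise from the top-left neighbor, most
#' significant first, yielding a code in [0, 255].
#'
#' @param patch 3x3 numeric matrix.
#' @return integer code in [0, 255].
#' @examples
#' lbpCode(matrix(1, 3, 3))  # 255: every difference is zero
#' @export
lbpCode <- function(patch) {
  if (!is.matrix(patch) || !all(dim(patch) == c(3L, 3L)))
    stop("patch must be a 3x3 matrix")
  center <- patch[2L, 2L]
  bits <- vapply(seq_len(8L), function(b) {
    nb <- patch[2L + .lbpOffsets[b, 1L], 2L + .lbpOffsets[b, 2L]]
    as.integer(nb >= center)
  }, 1L)
  sum(bits * 2L^(7:0))
}

#' Normalized 256-bin LBP histogram
#'
#' Computes the LBP code for every interior pixel and returns the
#' normalized 256-bin histogram (sums to 1).
#'
#' @param img numeric matrix, at least 3x3.
#' @return numeric vector of length 256, names \code{lbp0 ... lbp255}.
#' @export
lbpHistogram <- function(img) {
  .checkImage(img, minSize = 3L)
  H <- nrow(img); W <- ncol(img)
  center <- img[2:(H - 1L), 2:(W - 1L)]
  codes <- matrix(0L, H - 2L, W - 2L)
  for (b in seq_len(8L)) {
    dr <- .lbpOffsets[b, 1L]; dc <- .lbpOffsets[b, 2L]
    nb <- img[(2:(H - 1L)) + dr, (2:(W - 1L)) + dc]
    codes <- codes + (nb >= center) * 2L^(8L - b)
  }
  h <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  stats::setNames(h / sum(h), paste0("lbp", 0:255))
}

#' Full texture feature vector of an image
#'
#' Concatenates the 256-bin LBP histogram with the 13 direction-averaged
#' Haralick statistics (length 269), in that order, with names preserved.
#'
#' @param img numeric matrix in [0, 1].
#' @param levels GLCM gray levels (default 16).
#' @param distance GLCM pixel distance (default 1).
#' @return named numeric vector of length 269.
#' @export
extractTextureFeatures <- function(img, levels = 16L, distance = 1L) {
  q <- quantizeGray(img, levels)
  har <- haralickFeatures(glcmAllDirections(q, distance))
  c(lbpHistogram(img), har)
}

#' Feature matrix for a list of images
#'
#' @param images list of numeric matrices in [0, 1].
#' @inheritParams extractTextureFeatures
#' @return n x 269 matrix, one row per image.
#' @export
featureMatrix <- function(images, levels = 16L, distance = 1L) {
  t(vapply(images, extractTextureFeatures, numeric(269),
           levels = levels, distance = distance))
}
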
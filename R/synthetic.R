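## Seeded generator of MR-like grayscale test images: a smooth correlated
## background (blurred white noise) and, for tumor classes, an elliptical
## lesion carrying an oriented sinusoidal texture whose parameters differ
## per subtype, blended with a soft edge.  Class separability in GLCM
## contrast is guaranteed by construction, which keeps the feature-path
## tests non-vacuous.

#' Default texture specifications for the four image classes
#'
#' The three tumor-like subtypes differ pairwise both in texture and in
#' mean lesion enhancement (different lesion types enhance differently in
#' contrast-enhanced MR): the angiosarcoma-like lesion is bright and
#' high-frequency (strong GLCM contrast), the inflammatory-like lesion
#' mid-bright and low-frequency (smooth, low contrast), and the DCIS-like
#' lesion darker, mid-frequency, with extra local noise.  The healthy
#' class has no lesion.
#'
#' @return named list of specs (class, lesion flag, background
#'   correlation, lesion axes range as a fraction of image size,
#'   frequency in cycles/pixel, amplitude, mean lesion intensity, local
#'   noise SD).
#' @export
textureSpecs <- function() {
  list(
    healthy = list(class = "healthy", lesion = FALSE, bgSmooth = 2,
                   axesFrac = c(0.12, 0.22), freq = 0, amp = 0, base = 0,
                   noiseSD = 0),
    angiosarcoma = list(class = "angiosarcoma", lesion = TRUE, bgSmooth = 2,
                        axesFrac = c(0.14, 0.24), freq = 0.45, amp = 0.30,
                        base = 0.80, noiseSD = 0.04),
    inflammatory = list(class = "inflammatory", lesion = TRUE, bgSmooth = 2,
                        axesFrac = c(0.14, 0.24), freq = 0.06, amp = 0.30,
                        base = 0.62, noiseSD = 0.04),
    dcis = list(class = "dcis", lesion = TRUE, bgSmooth = 2,
                axesFrac = c(0.14, 0.24), freq = 0.22, amp = 0.22,
                base = 0.45, noiseSD = 0.14))
}

#' Generate one synthetic image
#'
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param spec one element of \code{\link{textureSpecs}} (or a
#'   like-shaped list).
#' @param size image side length in pixels (square output).
#' @return list with \code{image} (size x size matrix in [0, 1]),
#'   \code{label} (list with \code{status} and \code{subtype}), and
#'   \code{mask} (soft lesion membership in [0, 1], all zero when
#'   healthy).
#' @export
makeImage <- function(spec, size = 64L) {
  size <- as.integer(size)
  if (size < 16L) stop("size must be at least 16")
  bg <- matrix(stats::rnorm(size * size), size, size)
  bg <- .gaussianFilter(bg, spec$bgSmooth)
  bg <- 0.2 + 0.4 * minmaxNormalize(bg)

  mask <- matrix(0, size, size)
  if (isTRUE(spec$lesion)) {
    ax <- stats::runif(2, spec$axesFrac[1], spec$axesFrac[2]) * size
    if (max(ax) * 2 > size) stop("lesion larger than image")
    cx <- stats::runif(1, 0.35, 0.65) * size
    cy <- stats::runif(1, 0.35, 0.65) * size
    rot <- stats::runif(1, 0, pi)
    ori <- stats::runif(1, 0, pi)
    xy <- expand.grid(y = seq_len(size), x = seq_len(size))
    dx <- xy$x - cx; dy <- xy$y - cy
    u <- (dx * cos(rot) + dy * sin(rot)) / ax[1]
    v <- (-dx * sin(rot) + dy * cos(rot)) / ax[2]
    d <- u^2 + v^2
    mask <- matrix(1 / (1 + exp((d - 1) / 0.08)), size, size)
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * spec$freq * (xy$x * cos(ori) + xy$y * sin(ori)) + phase)
    tex <- spec$base + spec$amp * matrix(wave, size, size) +
      matrix(stats::rnorm(size * size, sd = spec$noiseSD), size, size)
    img <- bg * (1 - mask) + tex * mask
  } else {
    img <- bg
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  status <- if (isTRUE(spec$lesion)) "tumor" else "healthy"
  subtype <- if (status == "tumor") spec$class else NA_character_
  list(image = img, label = list(status = status, subtype = subtype),
       mask = mask)
}

#' Generate a stratified synthetic dataset
#'
#' Each image gets its own child seed drawn under the base seed, so the
#' dataset is reproducible bit-exactly from \code{(classCounts, size,
#' seed)}.
#'
#' @param classCounts named integer vector of per-class counts; names
#'   must be a subset of \code{names(textureSpecs())}.
#' @param size image side length (default 64).
#' @param seed integer base seed.
#' @param specs texture specifications (default \code{\link{textureSpecs}}).
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (data.frame with columns class, status, subtype), \code{masks},
#'   \code{seed}, \code{size}.
#' @export
makeDataset <- function(classCounts = c(healthy = 50L, angiosarcoma = 50L,
                                        inflammatory = 50L, dcis = 50L),
                        size = 64L, seed = 42L, specs = textureSpecs()) {
  if (any(classCounts <= 0)) stop("class counts must be positive")
  unknown <- setdiff(names(classCounts), names(specs))
  if (length(unknown)) stop("unknown class(es): ", paste(unknown, collapse = ", "))
  total <- sum(classCounts)
  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, total)
  images <- vector("list", total)
  masks <- vector("list", total)
  cls <- character(total)
  idx <- 0L
  for (cn in names(classCounts)) {
    for (i in seq_len(classCounts[[cn]])) {
      idx <- idx + 1L
      set.seed(childSeeds[idx])
      made <- makeImage(specs[[cn]], size)
      images[[idx]] <- made$image
      masks[[idx]] <- made$mask
      cls[idx] <- cn
    }
  }
  labels <- data.frame(
    class = cls,
    status = ifelse(cls == "healthy", "healthy", "tumor"),
    subtype = ifelse(cls == "healthy", NA_character_, cls),
    stringsAsFactors = FALSE)
  list(images = images, labels = labels, masks = masks,
       seed = seed, size = size, classCounts = classCounts)
}

#' Corrupt an image with synthetic noise
#'
#' Gaussian additive noise (SD = strength), salt-and-pepper (pixel
#' corruption probability = strength, half set to 1, half to 0), or a
#' Rician-like magnitude corruption
#' \eqn{\sqrt{(p + n_1)^2 + n_2^2}} with \eqn{n_i \sim N(0, strength^2)}.
#' The result is clipped to [0, 1]; the input is untouched.  Uses the
#' current RNG state.
#'
#' @param img numeric matrix in [0, 1].
#' @param kind \code{"gaussian"}, \code{"salt_pepper"}, or
#'   \code{"rician_like"}.
#' @param strength non-negative noise level.
#' @return corrupted copy of the image.
#' @export
addNoise <- function(img, kind = c("gaussian", "salt_pepper", "rician_like"),
                     strength = 0.1) {
  kind <- match.arg(kind)
  .checkImage(img)
  if (strength < 0) stop("strength must be non-negative")
  if (strength == 0) return(img)
  out <- switch(kind,
    gaussian = img + matrix(stats::rnorm(length(img), sd = strength),
                            nrow(img), ncol(img)),
    salt_pepper = {
      o <- img
      hit <- stats::runif(length(img)) < strength
      val <- stats::runif(length(img)) < 0.5
      o[hit & val] <- 1
      o[hit & !val] <- 0
      o
    },
    rician_like = sqrt((img + matrix(stats::rnorm(length(img), sd = strength),
                                     nrow(img), ncol(img)))^2 +
                       matrix(stats::rnorm(length(img), sd = strength),
                              nrow(img), ncol(img))^2))
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes one PNG per image under a subdirectory per class, plus a
#' \code{labels.csv} (columns file, class, status, subtype) — the dataset
#' layout consumed by the pipeline entry point.
#'
#' @param dataset result of \code{\link{makeDataset}}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$images)
  files <- character(n)
  for (i in seq_len(n)) {
    cls <- dataset$labels$class[i]
    sub <- file.path(dir, cls)
    dir.create(sub, showWarnings = FALSE)
    files[i] <- file.path(cls, sprintf("img%04d.png", i))
    writeGrayImage(dataset$images[[i]], file.path(dir, files[i]))
  }
  utils::write.csv(cbind(file = files, dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory containing \code{labels.csv}.
#' @return list with \code{images} and \code{labels} as in
#'   \code{\link{makeDataset}}.
#' @export
readDataset <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  images <- lapply(labels$file, function(f) readGrayImage(file.path(dir, f)))
  list(images = images, labels = labels[, c("class", "status", "subtype")])
}
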
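## End-to-end diagnosis system: texture-feature path (ICA + nearest
## centroid), CNN path (BDHOA-trained), OR-rule decision fusion on the
## binary tumor/healthy call, and confusion-matrix evaluation with
## one-vs-rest precision / sensitivity / specificity.

#' Fit the feature-path classifier
#'
#' Default is nearest centroid in the reduced (ICA) feature space —
#' deterministic and hyperparameter-free.  \code{method = "knn"} uses
#' 3-nearest-neighbours instead (requires the \pkg{class} package).
#'
#' @param X numeric matrix of reduced features, samples in rows.
#' @param labels class labels (character or factor), at least 2 classes.
#' @param method \code{"centroid"} (default) or \code{"knn"}.
#' @return classifier model list (class \code{"featureClassifier"}).
#' @export
fitFeatureClassifier <- function(X, labels, method = c("centroid", "knn")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain at least 2 classes")
  X <- as.matrix(X)
  model <- list(method = method, classes = sort(unique(labels)))
  if (method == "centroid") {
    model$centroids <- do.call(rbind, lapply(model$classes, function(cl)
      colMeans(X[labels == cl, , drop = FALSE])))
    rownames(model$centroids) <- model$classes
  } else {
    if (!requireNamespace("class", quietly = TRUE))
      stop("method 'knn' requires the 'class' package")
    model$X <- X
    model$labels <- labels
    model$k <- 3L
  }
  structure(model, class = "featureClassifier")
}

#' Predict with the feature-path classifier
#'
#' @param model a \code{"featureClassifier"} from
#'   \code{\link{fitFeatureClassifier}}.
#' @param X numeric matrix (samples in rows) or a single vector.
#' @return character vector of predicted class labels.
#' @export
predictFeatureClassifier <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (model$method == "centroid") {
    d2 <- outer(rowSums(X^2), rowSums(model$centroids^2), `+`) -
      2 * X %*% t(model$centroids)
    model$classes[apply(d2, 1L, which.min)]
  } else {
    as.character(class::knn(model$X, X, model$labels, k = model$k))
  }
}

#' OR-rule decision fusion on the binary tumor/healthy call
#'
#' A sample is called \code{"tumor"} if either path calls it tumor; only
#' a double-healthy call yields \code{"healthy"}.  Monotone in "tumor",
#' so fused sensitivity never drops below the CNN path alone.
#'
#' @param cnnStatus,featureStatus character vectors with values
#'   \code{"tumor"} or \code{"healthy"} (vectorized).
#' @return fused status vector.
#' @export
fuseDecisions <- function(cnnStatus, featureStatus) {
  ok <- c("tumor", "healthy")
  if (!all(cnnStatus %in% ok) || !all(featureStatus %in% ok))
    stop("statuses must be 'tumor' or 'healthy'")
  ifelse(cnnStatus == "tumor" | featureStatus == "tumor", "tumor", "healthy")
}

#' Confusion matrix with a fixed class order
#'
#' Rows are actual classes, columns predicted.
#'
#' @param actual,predicted label vectors of equal length.
#' @param classOrder character vector fixing row/column order; every
#'   label must appear here.
#' @return integer matrix with dimnames.
#' @export
confusionMatrix <- function(actual, predicted,
                            classOrder = sort(unique(c(actual, predicted)))) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  bad <- setdiff(unique(c(actual, predicted)), classOrder)
  if (length(bad))
    stop("label(s) outside classOrder: ", paste(bad, collapse = ", "))
  af <- factor(actual, levels = classOrder)
  pf <- factor(predicted, levels = classOrder)
  cm <- table(actual = af, predicted = pf)
  matrix(as.integer(cm), nrow(cm), ncol(cm),
         dimnames = list(actual = classOrder, predicted = classOrder))
}

#' One-vs-rest classification metrics from a confusion matrix
#'
#' Per class: TP/FP/FN/TN from the one-vs-rest reduction, then
#' precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), all in percent; overall accuracy = 100 * trace / total.
#' Zero denominators yield \code{NA} with the \code{undefined} flag set,
#' never a silent 0.
#'
#' @param cm square counts matrix (rows actual, columns predicted).
#' @param printedSpecificity audit flag: use the variant TN/(TP+FP)
#'   instead of the standard TN/(TN+FP).  Default \code{FALSE}.
#' @return list with \code{accuracy} (percent), \code{perClass}
#'   (data.frame: class, TP, FP, FN, TN, precision, sensitivity,
#'   specificity, undefined), and \code{total}.
#' @export
classMetrics <- function(cm, printedSpecificity = FALSE) {
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  classes <- rownames(cm)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    TP <- cm[i, i]
    FP <- sum(cm[-i, i])
    FN <- sum(cm[i, -i])
    TN <- total - TP - FP - FN
    specDen <- if (printedSpecificity) TP + FP else TN + FP
    r <- data.frame(class = classes[i], TP = TP, FP = FP, FN = FN, TN = TN,
                    precision = pct(TP, TP + FP),
                    sensitivity = pct(TP, TP + FN),
                    specificity = if (specDen > 0) 100 * TN / specDen else NA_real_)
    r$undefined <- anyNA(r[, c("precision", "sensitivity", "specificity")])
    r
  })
  perClass <- do.call(rbind, rows)
  list(accuracy = 100 * sum(diag(cm)) / total, perClass = perClass,
       total = total)
}

.statusOf <- function(class) ifelse(class == "healthy", "healthy", "tumor")

#' Run the full synthetic classification experiment
#'
#' Stratified seeded train/test split, feature path (texture features ->
#' ICA -> nearest centroid), CNN path (resized inputs, BDHOA-trained
#' small network), and the fused hybrid: binary OR-rule fusion of the
#' tumor/healthy calls, with the CNN's most probable tumor subtype
#' assigned to samples fused to "tumor".  Reports accuracy, confusion
#' matrix and metrics for all three configurations.
#'
#' @param dataset list with \code{images} and \code{labels} (see
#'   \code{\link{makeDataset}} / \code{\link{readDataset}}).
#' @param seed integer seed controlling the split and CNN training.
#' @param trainFrac training fraction per class (default 0.7).
#' @param icaComponents reduced feature dimension (default 20).
#' @param cnnInput CNN input shape; images are anti-alias blurred
#'   (Gaussian, \code{cnnBlur}) and bilinearly resized to it.
#' @param cnnIter,cnnPop BDHOA budget for CNN weight training.
#' @param cnnBlur anti-aliasing blur sigma applied before the resize
#'   (0 disables).
#' @param cnnWMax weight box half-width for the CNN search.
#' @param cnnChannels convolution channels of the small network.
#' @param featureMethod passed to \code{\link{fitFeatureClassifier}}.
#' @return list with per-configuration results (\code{feature},
#'   \code{cnn}, \code{hybrid}: each has \code{accuracy}, \code{cm},
#'   \code{metrics}), the fitted models, and the test index.
#' @export
runExperiment <- function(dataset, seed = 42L, trainFrac = 0.7,
                          icaComponents = 20L, cnnInput = c(8L, 8L),
                          cnnIter = 2000L, cnnPop = 30L, cnnBlur = 2,
                          cnnWMax = 1, cnnChannels = c(2L, 2L),
                          featureMethod = "centroid") {
  labels <- dataset$labels
  classes <- sort(unique(labels$class))
  counts <- table(labels$class)
  if (any(counts < 4L))
    stop("every class needs at least 4 samples; got ",
         paste(names(counts)[counts < 4L], collapse = ", "),
         " below that - generate more images per class")
  set.seed(seed)
  trainIdx <- integer(0)
  for (cl in classes) {
    ids <- which(labels$class == cl)
    trainIdx <- c(trainIdx, sample(ids, max(2L, round(trainFrac * length(ids)))))
  }
  testIdx <- setdiff(seq_along(dataset$images), trainIdx)

  norm <- lapply(dataset$images, minmaxNormalize)

  ## feature path: texture features -> ICA -> classifier over all classes
  Xtrain <- featureMatrix(norm[trainIdx])
  ica <- fitICA(Xtrain, m = min(icaComponents, nrow(Xtrain) - 1L),
                seed = seed)
  Rtrain <- icaTransform(ica, Xtrain)
  fcls <- fitFeatureClassifier(Rtrain, labels$class[trainIdx],
                               method = featureMethod)
  Xtest <- featureMatrix(norm[testIdx])
  featPred <- predictFeatureClassifier(fcls, icaTransform(ica, Xtest))

  ## CNN path: anti-alias, resize, train weights by BDHOA
  blurred <- if (cnnBlur > 0) lapply(norm, .gaussianFilter, sigma = cnnBlur)
             else norm
  small <- lapply(blurred, resizeBilinear, targetHW = cnnInput)
  arch <- if (min(cnnInput) >= 16L)
    tinyCNN(inputShape = cnnInput, nClasses = length(classes),
            channels = cnnChannels)
  else
    cnnArchitecture(list(
      list(type = "conv", kh = 3L, kw = 3L, cout = cnnChannels[1]),
      list(type = "relu"),
      list(type = "maxpool", size = 2L),
      list(type = "flatten"),
      list(type = "dense", nout = length(classes))),
      inputShape = cnnInput, nClasses = length(classes))
  classIdx <- function(cl) match(cl, classes)
  fit <- trainCNN(arch, small[trainIdx], classIdx(labels$class[trainIdx]),
                  config = huntConfig(variant = "bdhoa", popSize = cnnPop,
                                      maxIter = cnnIter, seed = seed),
                  wMax = cnnWMax)
  probsTest <- cnnForward(arch, fit$weights, small[testIdx])$probs
  cnnPred <- classes[apply(probsTest, 1L, which.max)]

  ## hybrid: OR-rule fusion of binary status; subtype from the CNN
  actual <- labels$class[testIdx]
  fused <- fuseDecisions(.statusOf(cnnPred), .statusOf(featPred))
  tumorClasses <- setdiff(classes, "healthy")
  tcols <- match(tumorClasses, classes)
  hybridPred <- ifelse(fused == "healthy", "healthy",
    tumorClasses[apply(probsTest[, tcols, drop = FALSE], 1L, which.max)])

  report <- function(pred) {
    cm <- confusionMatrix(actual, pred, classOrder = classes)
    list(accuracy = 100 * mean(pred == actual), cm = cm,
         metrics = classMetrics(cm))
  }
  list(feature = report(featPred), cnn = report(cnnPred),
       hybrid = report(hybridPred),
       models = list(ica = ica, featureClassifier = fcls, arch = arch,
                     weights = fit$weights),
       classes = classes, testIdx = testIdx, seed = seed)
}
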
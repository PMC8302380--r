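test_that("weight packing is a bijection and the parameter count is exact", {
  arch <- tinyCNN(c(16, 16), 3)
  # conv1: 3*3*1*4+4; conv2: 3*3*4*4+4; dense: 16*3+3
  expect_equal(nParams(arch), 40L + 148L + 51L)
  set.seed(91)
  w <- rnorm(nParams(arch))
  expect_identical(packWeights(arch, unpackWeights(arch, w)), w)
  expect_error(unpackWeights(arch, w[-1]), "length")
  expect_error(cnnArchitecture(list(list(type = "dense", nout = 2)),
                               c(8, 8), 2), "flatten")
})

test_that("softmax is stable, shift-invariant and exact on known logits", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(softmax(log(1:3)), (1:3) / 6)
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))  # no overflow
  m <- softmax(matrix(c(0, log(3), 0, 0), 2, byrow = TRUE))
  expect_equal(rowSums(m), c(1, 1))
  expect_equal(m[1, ], c(0.25, 0.75))
})

test_that("the forward pass matches a naive scalar-loop oracle on a small net", {
  arch <- cnnArchitecture(list(
    list(type = "conv", kh = 2L, kw = 2L, cout = 2L),
    list(type = "relu"),
    list(type = "maxpool", size = 2L),
    list(type = "flatten"),
    list(type = "dense", nout = 3L)), c(6, 6), 3)
  set.seed(97)
  w <- rnorm(nParams(arch), sd = 0.7)
  img <- matrix(runif(36), 6, 6)
  out <- cnnForward(arch, w, img)

  p <- unpackWeights(arch, w)
  kern <- p[[1]]$kernel; kb <- p[[1]]$bias
  conv <- array(0, c(5, 5, 2))
  for (co in 1:2) for (r in 1:5) for (cc in 1:5) {
    acc <- kb[co]
    for (dr in 1:2) for (dc in 1:2)
      acc <- acc + img[r + dr - 1, cc + dc - 1] * kern[dr, dc, 1, co]
    conv[r, cc, co] <- max(acc, 0)   # ReLU
  }
  pool <- array(0, c(2, 2, 2))
  for (co in 1:2) for (r in 1:2) for (cc in 1:2)
    pool[r, cc, co] <- max(conv[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc), co])
  flat <- as.vector(pool)   # (h, w, c) column-major, matching the packing
  logits <- as.vector(t(p[[5]]$W) %*% flat + p[[5]]$bias)
  expect_lt(max(abs(out$logits - logits)), 1e-8)
  expect_equal(out$probs[1, ], softmax(logits), tolerance = 1e-8)
})

test_that("degenerate weight settings give closed-form outputs", {
  arch <- tinyCNN(c(12, 12), 4)
  imgs <- list(seededImage(101, 12, 12), seededImage(102, 12, 12))
  out <- cnnForward(arch, rep(0, nParams(arch)), imgs)
  expect_equal(out$probs, matrix(0.25, 2, 4))
  expect_equal(cnnPredict(arch, rep(0, nParams(arch)), imgs), c(1L, 1L))
  expect_error(cnnForward(arch, rep(0, nParams(arch)),
                          matrix(0, 8, 8)), "shape")
})

test_that("loss functions match their definitions", {
  D <- oneHot(c(1, 2), 2)
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(suppressMessages(crossEntropyLoss(perfect, D)), 0)
  uniform <- matrix(0.5, 1, 2)
  expect_equal(crossEntropyLoss(uniform, oneHot(1, 2)), log(2))
  # scalar-sum oracle on a fixed batch
  set.seed(103)
  P <- t(apply(matrix(runif(12), 3, 4), 1, function(r) r / sum(r)))
  D3 <- oneHot(c(2, 4, 1), 4)
  manual <- 0
  for (i in 1:3) for (j in 1:4) if (D3[i, j] > 0) manual <- manual - log(P[i, j])
  expect_equal(crossEntropyLoss(P, D3), manual)
  expect_message(crossEntropyLoss(matrix(c(0, 1), 1), oneHot(1, 2)), "clamped")

  expect_equal(regularizedLoss(uniform, oneHot(1, 2), rep(0, 5), 2), log(2))
  expect_equal(regularizedLoss(perfect, D, c(1, 1, 1), 2),
               suppressMessages(crossEntropyLoss(perfect, D)) + 3)
  expect_error(regularizedLoss(perfect, D, 1, -1), "non-negative")

  expect_equal(mseLoss(matrix(1, 2, 3), matrix(1, 2, 3)), 0)
  expect_equal(mseLoss(matrix(2, 2, 3), matrix(1, 2, 3), T = 6), 1)
  a <- matrix(runif(6), 2); b <- matrix(runif(6), 2)
  manual <- 0
  for (i in 1:2) for (j in 1:3) manual <- manual + (a[i, j] - b[i, j])^2
  expect_equal(mseLoss(a, b), manual / 6)
  expect_error(mseLoss(matrix(1, 2, 2), matrix(1, 2, 3)), "mismatch")
})

test_that("BDHOA training fits the separable blob toy set and refuses oversized nets", {
  toy <- toyBlobSet()
  arch <- cnnArchitecture(list(
    list(type = "conv", kh = 3L, kw = 3L, cout = 2L),
    list(type = "relu"),
    list(type = "maxpool", size = 2L),
    list(type = "flatten"),
    list(type = "dense", nout = 2L)), c(8, 8), 2)
  fit <- trainCNN(arch, toy$images, toy$labels,
                  huntConfig(popSize = 20, maxIter = 300, seed = 5))
  expect_equal(fit$trainAccuracy, 1)
  h <- fitnessHistory(fit$result)
  expect_true(all(diff(h) <= 0))
  expect_lt(bestFitness(fit$result), h[1])
  # zero-iteration training returns the best of the initial population
  fit0 <- trainCNN(arch, toy$images, toy$labels,
                   huntConfig(popSize = 10, maxIter = 0, seed = 5))
  expect_length(fit0$weights, nParams(arch))
  big <- tinyCNN(c(32, 32), 4)
  expect_error(trainCNN(big, toy$images, toy$labels, paramCap = 100L), "cap")
})

test_that("architectures and weights round-trip through JSON", {
  arch <- tinyCNN(c(12, 12), 3)
  set.seed(107)
  w <- rnorm(nParams(arch))
  tmp <- withr::local_tempfile(fileext = ".json")
  writeCNN(arch, w, tmp)
  back <- readCNN(tmp)
  expect_equal(back$arch@nParams, arch@nParams)
  img <- seededImage(109, 12, 12)
  expect_equal(cnnForward(back$arch, back$weights, img)$probs,
               cnnForward(arch, w, img)$probs)
})
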
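test_that("min-max normalization maps to [0,1], handles constants, and is idempotent", {
  expect_equal(minmaxNormalize(matrix(c(2, 6, 4, 8), 2)),
               matrix(c(0, 2 / 3, 1 / 3, 1), 2))
  expect_equal(minmaxNormalize(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  n1 <- minmaxNormalize(img)
  expect_equal(minmaxNormalize(n1), n1)
  expect_error(minmaxNormalize(matrix(c(1, NA), 1)), "non-finite")
})

test_that("all four filters preserve constant images and the median removes salt", {
  cst <- matrix(0.4, 12, 12)
  fb <- filterBank(cst)
  for (nm in names(fb)) expect_equal(fb[[nm]], cst, tolerance = 1e-12)
  salt <- matrix(0, 9, 9)
  salt[5, 5] <- 1
  expect_equal(filterBank(salt)$median[5, 5], 0)
  expect_error(filterBank(matrix(0, 2, 2)), "at least")
})

test_that("filter outputs match naive per-pixel oracles on a seeded noisy image", {
  img <- seededImage(17, 12, 12)
  fb <- filterBank(img)
  # median and mean: direct 3x3 neighborhood statistics with reflect padding
  for (r in c(1, 2, 6, 12)) for (cc in c(1, 7, 12)) {
    nb <- oracleNeighborhood(img, r, cc)
    expect_equal(fb$median[r, cc], median(nb))
    expect_equal(fb$mean[r, cc], mean(nb))
  }
  # Gaussian: separable kernel applied by explicit loops
  k <- exp(-((-3):3)^2 / 2); k <- k / sum(k)
  pad <- img[c(4:2, 1:12, 11:9), c(4:2, 1:12, 11:9)]
  manual <- matrix(0, 12, 12)
  for (r in 1:12) for (cc in 1:12) {
    acc <- 0
    for (i in 1:7) for (j in 1:7)
      acc <- acc + k[i] * k[j] * pad[r + i - 1, cc + j - 1]
    manual[r, cc] <- acc
  }
  expect_equal(fb$gaussian, manual, tolerance = 1e-12)
  # Wiener-type: local mean/variance shrinkage with image-wide noise level
  mus <- matrix(0, 12, 12); vrs <- matrix(0, 12, 12)
  for (r in 1:12) for (cc in 1:12) {
    nb <- oracleNeighborhood(img, r, cc)
    mus[r, cc] <- mean(nb)
    vrs[r, cc] <- mean(nb^2) - mean(nb)^2
  }
  nu <- mean(vrs)
  manualW <- mus + ifelse(vrs > nu, (vrs - nu) / vrs, 0) * (img - mus)
  expect_equal(fb$wiener, manualW, tolerance = 1e-10)
})

test_that("the combiner recovers a single-filter target and achieves ~0 MSE on clean pairs", {
  img <- seededImage(23, 16, 16)
  target <- filterBank(img)$gaussian
  model <- trainCombiner(list(list(noisy = img, clean = target)))
  expect_lt(abs(model@weights[3] - 1), 1e-6)
  expect_lt(max(abs(model@weights[-3])), 1e-6)
  expect_lt(model@trainMSE, 1e-20)
  # zero-noise pairs: the combined output reproduces the clean image up to
  # the residual blur of the filters themselves (tiny relative to variance)
  smooth <- filterBank(seededImage(29, 16, 16))$gaussian
  m2 <- trainCombiner(list(list(noisy = smooth, clean = smooth)))
  expect_lt(m2@trainMSE, stats::var(as.vector(smooth)) / 10)
  expect_error(trainCombiner(list(list(noisy = img, clean = img[1:8, ]))),
               "same shape")
  expect_error(trainCombiner(list()), "pair")
})

test_that("the hybrid filter reduces to a single filter under unit weights and denoises", {
  img <- seededImage(31, 16, 16)
  m <- new("CombinerModel", weights = c(1, 0, 0, 0), bias = 0,
           nPairs = 1L, trainMSE = 0)
  expect_equal(hybridFilter(img, m), filterBank(img)$median)
  cst <- matrix(0.5, 16, 16)
  mAvg <- new("CombinerModel", weights = rep(0.25, 4), bias = 0,
              nPairs = 1L, trainMSE = 0)
  expect_equal(hybridFilter(cst, mAvg), cst)
  expect_error(hybridFilter(img, "nope"), "CombinerModel")
})

test_that("denoising improves MSE over the corrupted image for gaussian and salt-and-pepper noise", {
  set.seed(47)
  clean <- lapply(1:3, function(i) makeImage(textureSpecs()$inflammatory, 48)$image)
  for (kind in c("gaussian", "salt_pepper")) {
    strength <- if (kind == "gaussian") 0.1 else 0.05
    set.seed(53)
    noisy <- lapply(clean, addNoise, kind = kind, strength = strength)
    pairs <- Map(function(n, c) list(noisy = n, clean = c),
                 noisy[1:2], clean[1:2])
    model <- trainCombiner(pairs)
    out <- hybridFilter(noisy[[3]], model)
    mseNoisy <- mean((noisy[[3]] - clean[[3]])^2)
    mseDen <- mean((out - clean[[3]])^2)
    expect_lt(mseDen, mseNoisy)
    # held-out PSNR of the combination is at least the best single filter's
    fb <- filterBank(noisy[[3]])
    bestSingle <- min(vapply(fb, function(f) mean((f - clean[[3]])^2), 0))
    expect_lt(mseDen, bestSingle * 1.05)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("bilinear resize is exact on identity and constants and hits the target shape", {
  img <- seededImage(37, 20, 20)
  expect_identical(resizeBilinear(img, c(20, 20)), img)
  expect_equal(resizeBilinear(matrix(0.3, 10, 10), c(7, 13)),
               matrix(0.3, 7, 13))
  big <- seededImage(41, 64, 64)
  expect_equal(dim(resizeBilinear(big, c(25, 25))), c(25L, 25L))
  # a linear ramp resamples exactly under bilinear interpolation
  ramp <- outer(seq(0, 1, length.out = 11), rep(1, 5))
  out <- resizeBilinear(ramp, c(6, 5))
  expect_equal(out[, 1], seq(0, 1, length.out = 6))
  expect_error(resizeBilinear(img, c(0, 5)), "positive")
})

test_that("images and combiner models round-trip through disk formats", {
  img <- seededImage(43, 16, 16)
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "a.png")
  writeGrayImage(img, p1)
  back <- readGrayImage(p1)
  expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization only
  p2 <- file.path(tmp, "a.tiff")
  writeGrayImage(img, p2)
  expect_lt(max(abs(readGrayImage(p2) - img)), 1 / 255)
  model <- trainCombiner(list(list(noisy = img, clean = img)))
  pj <- file.path(tmp, "model.json")
  writeCombiner(model, pj)
  m2 <- readCombiner(pj)
  expect_equal(m2@weights, model@weights)
  expect_equal(m2@bias, model@bias)
})
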
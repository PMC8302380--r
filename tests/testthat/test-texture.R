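test_that("gray-level quantization respects boundaries and level caps", {
  expect_equal(quantizeGray(matrix(c(0, 1), 1), 16)[1, ], c(0L, 15L))
  expect_true(all(quantizeGray(matrix(0.5, 4, 4), 16) == 8L))
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  q <- quantizeGray(img, 7)
  expect_true(all(q >= 0 & q <= 6))
  expect_true(all(q == floor(pmin(img * 7, 6))))
  expect_error(quantizeGray(img, 1), "levels")
  expect_error(quantizeGray(img * 2), "0, 1")
})

test_that("GLCM matches hand enumeration and a brute-force pair-counting oracle", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2)   # rows: (0,0) / (1,1)
  attr(q, "levels") <- 2L
  g <- glcm(q, 0, 1, symmetric = TRUE, normalize = TRUE)
  expect_equal(g, matrix(c(0.5, 0, 0, 0.5), 2))
  cst <- quantizeGray(matrix(0.5, 6, 6), 16)
  gc <- glcm(cst, 45)
  expect_equal(sum(gc), 1)
  expect_equal(gc[9, 9], 1)  # all mass on the diagonal cell of level 8
  set.seed(19)
  for (i in 1:3) {
    img <- matrix(runif(256), 16, 16)
    qq <- quantizeGray(img, 8)
    for (d in c(0, 45, 90, 135)) {
      expect_equal(glcm(qq, d), oracleGLCM(qq, d, levels = 8L))
      expect_equal(glcm(qq, d, symmetric = FALSE, normalize = FALSE),
                   oracleGLCM(qq, d, symmetric = FALSE, normalize = FALSE,
                              levels = 8L))
    }
  }
  expect_error(glcm(q, 30), "direction")
  expect_error(glcm(q, 0, distance = 5), "extent")
})

test_that("Haralick statistics match the textbook scalar oracle and closed forms", {
  cst <- quantizeGray(matrix(0.5, 8, 8), 16)
  h <- haralickFeatures(glcmAllDirections(cst))
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["entropy"]), 0)
  # checkerboard: horizontal GLCM is [[0,.5],[.5,0]] so contrast is 1
  cb <- matrix(rep(c(0L, 1L), 8), 4, 4)
  cb[, c(2, 4)] <- 1L - cb[, c(2, 4)]
  attr(cb, "levels") <- 2L
  expect_equal(glcm(cb, 0), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(unname(haralickFeatures(list(glcm(cb, 0)))["contrast"]), 1)
  set.seed(23)
  for (i in 1:3) {
    qq <- quantizeGray(matrix(runif(256), 16, 16), 8)
    glcms <- glcmAllDirections(qq)
    mine <- haralickFeatures(glcms)
    oracle <- rowMeans(vapply(glcms, oracleHaralick, numeric(13)))
    expect_lt(max(abs(mine - oracle)), 1e-10)
  }
  expect_error(haralickFeatures(list(matrix(2, 2, 2))), "normalized")
})

test_that("LBP codes follow the clockwise >= convention", {
  expect_equal(lbpCode(matrix(1, 3, 3)), 255L)
  center1 <- matrix(0, 3, 3); center1[2, 2] <- 1
  expect_equal(lbpCode(center1), 0L)
  # enumerate the 8 comparisons by hand for an asymmetric patch
  patch <- matrix(c(5, 4, 3, 4, 4, 4, 3, 4, 5), 3, byrow = TRUE)
  # clockwise from top-left: 5,4,3 | 4 | 5,4,3 | 4 vs center 4
  bits <- c(1, 1, 0, 1, 1, 1, 0, 1)
  expect_equal(lbpCode(patch), sum(bits * 2^(7:0)))
  expect_error(lbpCode(matrix(1, 2, 2)), "3x3")
})

test_that("LBP histograms are normalized and match the per-pixel oracle", {
  cst <- matrix(0.7, 8, 8)
  h <- lbpHistogram(cst)
  expect_equal(unname(h["lbp255"]), 1)
  set.seed(29)
  img <- matrix(runif(144), 12, 12)
  h2 <- lbpHistogram(img)
  expect_equal(sum(h2), 1)
  expect_equal(unname(h2), oracleLBPHist(img))
  expect_error(lbpHistogram(matrix(1, 2, 2)), "at least")
})

test_that("the concatenated feature vector is 269-long, named and deterministic", {
  img <- seededImage(35, 16, 16)
  fv <- extractTextureFeatures(img)
  expect_length(fv, 269)
  expect_equal(names(fv)[1], "lbp0")
  expect_equal(names(fv)[269], "imc2")
  expect_identical(fv, extractTextureFeatures(img))
  cst <- matrix(0.5, 16, 16)
  fvc <- extractTextureFeatures(cst)
  expect_equal(unname(fvc["energy"]), 1)
  expect_equal(unname(fvc["lbp255"]), 1)
  X <- featureMatrix(list(img, cst))
  expect_equal(dim(X), c(2L, 269L))
  expect_equal(X[2, ], fvc)
})

test_that("rotating an image by 90 degrees permutes directional GLCMs and preserves averaged Haralick features", {
  set.seed(59)
  img <- matrix(runif(400), 20, 20)
  rot <- t(img)[ncol(img):1, ]   # 90-degree rotation
  q <- quantizeGray(img, 8); qr <- quantizeGray(rot, 8)
  h1 <- haralickFeatures(glcmAllDirections(q))
  h2 <- haralickFeatures(glcmAllDirections(qr))
  expect_lt(max(abs(h1 - h2)), 1e-10)
})
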
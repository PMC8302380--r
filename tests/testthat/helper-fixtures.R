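# Shared fixtures: all built in code, seeded.

seededImage <- function(seed, H = 16L, W = H) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

# brute-force per-pixel 3x3 neighborhood with reflect padding, as an
# independent oracle for the filter bank
oracleNeighborhood <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  vals <- numeric(9)
  k <- 0
  for (dc in -1:1) for (dr in -1:1) {
    rr <- r + dr; cc <- c + dc
    if (rr < 1) rr <- 2 - rr
    if (rr > H) rr <- 2 * H - rr
    if (cc < 1) cc <- 2 - cc
    if (cc > W) cc <- 2 * W - cc
    k <- k + 1
    vals[k] <- img[rr, cc]
  }
  vals
}

# independent scalar-loop GLCM oracle (counts, then optional sym/normalize)
oracleGLCM <- function(q, direction, distance = 1L, symmetric = TRUE,
                       normalize = TRUE, levels = attr(q, "levels")) {
  off <- switch(as.character(direction),
    "0" = c(0, distance), "45" = c(-distance, distance),
    "90" = c(-distance, 0), "135" = c(-distance, -distance))
  H <- nrow(q); W <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (r in 1:H) for (cc in 1:W) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W)
      counts[q[r, cc] + 1, q[r2, c2] + 1] <- counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# textbook scalar-loop Haralick oracle for one normalized GLCM
oracleHaralick <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
  sx <- sqrt(sum(((1:Ng) - mux)^2 * px)); sy <- sqrt(sum(((1:Ng) - muy)^2 * py))
  psum <- numeric(2 * Ng); pdif <- numeric(Ng)   # psum[k] = p_{x+y}(k), k in 2..2Ng
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  xlx <- function(p) if (p > 0) p * log(p) else 0
  energy <- sum(P^2)
  contrast <- 0; for (k in 0:(Ng - 1)) contrast <- contrast + k^2 * pdif[k + 1]
  corr <- 0
  if (sx * sy > 1e-12) {
    s <- 0; for (i in 1:Ng) for (j in 1:Ng) s <- s + i * j * P[i, j]
    corr <- (s - mux * muy) / (sx * sy)
  }
  variance <- 0; for (i in 1:Ng) for (j in 1:Ng) variance <- variance + (i - mux)^2 * P[i, j]
  hom <- 0; for (i in 1:Ng) for (j in 1:Ng) hom <- hom + P[i, j] / (1 + (i - j)^2)
  sa <- 0; for (k in 2:(2 * Ng)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * Ng)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * Ng)) se <- se - xlx(psum[k])
  ent <- 0; for (i in 1:Ng) for (j in 1:Ng) ent <- ent - xlx(P[i, j])
  da <- 0; for (k in 0:(Ng - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(Ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(Ng - 1)) de <- de - xlx(pdif[k + 1])
  hx <- -sum(sapply(px, xlx)); hy <- -sum(sapply(py, xlx))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pq <- px[i] * py[j]
    if (pq > 0) hxy1 <- hxy1 - P[i, j] * log(pq)
    hxy2 <- hxy2 - xlx(pq)
  }
  imc1 <- if (max(hx, hy) > 1e-12) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(energy = energy, contrast = contrast, correlation = corr,
    variance = variance, homogeneity = hom, sum_average = sa,
    sum_variance = sv, sum_entropy = se, entropy = ent,
    difference_variance = dv, difference_entropy = de,
    imc1 = imc1, imc2 = imc2)
}

# per-pixel scalar LBP oracle
oracleLBPHist <- function(img) {
  H <- nrow(img); W <- ncol(img)
  h <- numeric(256)
  for (r in 2:(H - 1)) for (cc in 2:(W - 1)) {
    code <- lbpCode(img[(r - 1):(r + 1), (cc - 1):(cc + 1)])
    h[code + 1] <- h[code + 1] + 1
  }
  h / sum(h)
}

# tiny separable two-class image set: bright central blob vs none
toyBlobSet <- function(n = 16L, seed = 7L) {
  set.seed(seed)
  mk <- function(blob) {
    m <- matrix(runif(64, 0, 0.2), 8, 8)
    if (blob) m[3:6, 3:6] <- m[3:6, 3:6] + 0.7
    m
  }
  list(images = c(lapply(seq_len(n / 2), function(i) mk(TRUE)),
                  lapply(seq_len(n / 2), function(i) mk(FALSE))),
       labels = rep(1:2, each = n / 2))
}
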
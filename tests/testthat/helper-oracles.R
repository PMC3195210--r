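# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (and EBImage): erosion as an explicit pixel-set
# loop, varimax as a planar-angle grid search.

## one 3x3-square erosion by direct neighbourhood inspection; pixels
## outside the image count as background
bruteErodeOnce <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0L) next
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || mask[ii, jj] == 0L)
        keep <- FALSE
    }
    if (keep) out[i, j] <- 1L
  }
  out
}

bruteErosionWidth <- function(mask) {
  iters <- 0L
  while (any(mask == 1L)) {
    mask <- bruteErodeOnce(mask)
    iters <- iters + 1L
  }
  2L * iters
}

## varimax criterion of a loadings matrix (column variance of squared
## loadings, summed) after Kaiser row-normalization
vmxCriterion <- function(L, rowNormalize = TRUE) {
  if (rowNormalize) {
    sc <- sqrt(rowSums(L^2))
    L <- L / sc
  }
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}

planarRotation <- function(k, i, j, theta) {
  R <- diag(k)
  R[i, i] <- cos(theta); R[j, j] <- cos(theta)
  R[i, j] <- -sin(theta); R[j, i] <- sin(theta)
  R
}

## maximize the (row-normalized) varimax criterion by cyclic grid searches
## over planar rotation angles
gridSearchVarimax <- function(L, gridStep = 0.002, maxSweeps = 50) {
  sc <- sqrt(rowSums(L^2))
  Ln <- L / sc
  k <- ncol(Ln)
  crit <- vmxCriterion(Ln, rowNormalize = FALSE)
  angles <- seq(0, pi / 2, by = gridStep)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      crits <- vapply(angles, function(a)
        vmxCriterion(Ln %*% planarRotation(k, i, j, a),
                     rowNormalize = FALSE), numeric(1))
      best <- which.max(crits)
      if (crits[best] > crit + 1e-12) {
        Ln <- Ln %*% planarRotation(k, i, j, angles[best])
        crit <- crits[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(criterion = crit, loadings = Ln * sc)
}

## random small binary masks: mixture of structured shapes and salt fields
randomMask <- function(maxDim = 32L) {
  H <- sample(3:maxDim, 1); W <- sample(3:maxDim, 1)
  type <- sample(c("bar", "blob", "salt", "disk"), 1)
  m <- matrix(0L, H, W)
  if (type == "bar") {
    h <- sample(seq_len(H), 1); w <- sample(seq_len(W), 1)
    r0 <- sample(seq_len(H - h + 1), 1); c0 <- sample(seq_len(W - w + 1), 1)
    m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1L
  } else if (type == "disk") {
    r <- sample(1:(min(H, W) %/% 2), 1)
    cy <- sample(r:(H - r + 1), 1); cx <- sample(r:(W - r + 1), 1)
    for (i in 1:H) for (j in 1:W)
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  } else if (type == "blob") {
    m[] <- as.integer(matrix(runif(H * W) < 0.6, H, W))
  } else {
    m[] <- as.integer(matrix(runif(H * W) < 0.2, H, W))
  }
  if (!any(m == 1L)) m[sample(H, 1), sample(W, 1)] <- 1L
  m
}

maskF1 <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  2 * tp / (2 * tp + fp + fn)
}

## uniform-colour rectangular test image
uniformImage <- function(rgb, H = 16L, W = 16L) {
  img <- array(0L, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

## shared synthetic dataset cache so expensive fixtures are built once
.fixtures <- new.env(parent = emptyenv())
cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}
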
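## Independent oracle implementations used to validate the package's
## vectorised code paths. These deliberately use naive loops and never call
## the functions they check.

## Naive per-descriptor coding + pooling + normalisation, double loop.
oracleEncode <- function(X, C, coding, pooling, norm = "L1",
                         sigma = 0.7, epsilon = 1e-12) {
  N <- nrow(X); M <- nrow(C)
  A <- matrix(0, N, M)
  for (j in seq_len(N)) {
    d <- numeric(M)
    for (m in seq_len(M)) d[m] <- sqrt(sum((X[j, ] - C[m, ])^2))
    if (coding == "hard") {
      A[j, which.min(d)] <- 1
    } else if (coding == "semisoft") {
      m0 <- which.min(d)
      A[j, m0] <- 1 / (d[m0] + epsilon)
    } else {
      k <- exp(-d^2 / (2 * sigma^2))
      if (sum(k) == 0) {
        A[j, which.min(d)] <- 1            # underflow fallback: hard
      } else {
        A[j, ] <- k / sum(k)
      }
    }
  }
  z <- numeric(M)
  for (m in seq_len(M))
    z[m] <- if (pooling == "sum") sum(A[, m]) else max(A[, m])
  if (norm == "L1") z <- z / sum(z)
  if (norm == "L2") z <- z / sqrt(sum(z^2))
  z
}

## O(n^2) tie-corrected Mann-Whitney AUC by pair counting.
oraclePairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## Rasterised disk area (pixel-by-pixel membership test).
oracleDiskArea <- function(H, W, cx, cy, r) {
  n <- 0L
  for (y in 0:(H - 1)) for (x in 0:(W - 1))
    if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1L
  n
}

## Brute-force dense-grid enumeration under the stated convention:
## points at (i*r, j*r), 0-based, strictly inside bounds.
oracleDenseCount <- function(H, W, r) {
  n <- 0L
  i <- 1L
  while (i * r < W) {
    j <- 1L
    while (j * r < H) { n <- n + 1L; j <- j + 1L }
    i <- i + 1L
  }
  n
}

## Tiny toy codebook helper for mid-level tests.
toyCodebook <- function(mat, ...) {
  Codebook(as.matrix(mat), ...)
}

## A bright disk image on black background (FOV fixtures).
diskImage <- function(H = 480, W = 640, cx = (W - 1) / 2, cy = (H - 1) / 2,
                      r = 200, value = 200) {
  px <- array(0, dim = c(H, W, 3))
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  disk <- d2 <= r^2
  for (c in 1:3) px[, , c] <- value * disk
  FundusImage(px, imageId = "disk")
}
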
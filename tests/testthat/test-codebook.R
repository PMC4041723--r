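mkDset <- function(X, x, y, id = "img1") {
  DescriptorSet(X, data.frame(x = x, y = y, radius = 5, source = "sparse"),
                imageId = id)
}

test_that("descriptor partitioning follows the point-in-region rule", {
  X <- matrix(rnorm(10), 5, 2)
  ## circle of radius 10 at (50,50); keypoints at the stated positions
  dset <- mkDset(X, x = c(50, 55, 100, 50, 0), y = c(50, 50, 100, 62, 0))
  rg <- regionAnnotation("img1", "HE", list(type = "circle", cx = 50, cy = 50, r = 10))
  p <- partitionDescriptors(dset, list(rg))
  expect_equal(nrow(p$lesionPool), 2)   # (50,50) and (55,50); (50,62) is 12 away
  expect_equal(nrow(p$normalPool), 3)
  expect_equal(rbind(p$lesionPool, p$normalPool)[order(c(1, 2, 3, 4, 5)), ],
               rbind(X[1:2, ], X[3:5, ]))
})

test_that("healthy images put everything in the normal pool and a covering circle takes all", {
  X <- matrix(rnorm(12), 6, 2)
  dset <- mkDset(X, x = 1:6 * 10, y = 1:6 * 10)
  p0 <- partitionDescriptors(dset, list())
  expect_equal(nrow(p0$lesionPool), 0)
  expect_equal(p0$normalPool, X)
  big <- regionAnnotation("img1", "HE", list(type = "circle", cx = 35, cy = 35, r = 1000))
  p1 <- partitionDescriptors(dset, list(big))
  expect_equal(nrow(p1$lesionPool), 6)
  expect_equal(nrow(p1$normalPool), 0)
})

test_that("polygon regions use the even-odd rule", {
  X <- matrix(0, 3, 2)
  dset <- mkDset(X, x = c(5, 15, 25), y = c(5, 5, 5))
  ## square [0,10] x [0,10]
  rg <- regionAnnotation("img1", "D",
                         list(type = "polygon", px = c(0, 10, 10, 0),
                              py = c(0, 0, 10, 10)))
  p <- partitionDescriptors(dset, list(rg))
  expect_equal(nrow(p$lesionPool), 1)
})

test_that("regions from another image are rejected", {
  dset <- mkDset(matrix(0, 1, 2), 1, 1, id = "imgA")
  rg <- regionAnnotation("imgB", "HE", list(type = "circle", cx = 1, cy = 1, r = 5))
  expect_error(partitionDescriptors(dset, list(rg)), "imgA")
})

test_that("class-aware learning concatenates lesion-first with 2k codewords", {
  set.seed(1)
  L <- matrix(rnorm(300 * 4), 300, 4) + 5
  N <- matrix(rnorm(300 * 4), 300, 4) - 5
  cb <- learnClassAwareCodebook(L, N, kHalf = 50L, seed = 3L, lesionLabel = "HE")
  expect_equal(nrow(codewords(cb)), 100)
  expect_equal(halfSize(cb), 50L)
  expect_equal(provenance(cb), rep(c("lesion", "normal"), each = 50))
  ## lesion half sits near +5, normal half near -5
  expect_true(all(rowMeans(codewords(cb)[1:50, ]) > 0))
  expect_true(all(rowMeans(codewords(cb)[51:100, ]) < 0))
})

test_that("a pool of exactly kHalf distinct points is a k-means fixed point", {
  set.seed(2)
  P <- matrix(runif(20 * 3), 20, 3) * 10
  cb <- learnClassAwareCodebook(P, matrix(runif(60), 20, 3), kHalf = 20L,
                                seed = 9L)
  got <- codewords(cb)[1:20, ]
  expect_equal(got[order(got[, 1]), ], P[order(P[, 1]), ], tolerance = 1e-12)
})

test_that("codebook learning is deterministic given the seed", {
  set.seed(4)
  L <- matrix(rnorm(200), 50, 4)
  N <- matrix(rnorm(200), 50, 4)
  cb1 <- learnClassAwareCodebook(L, N, kHalf = 10L, seed = 5L)
  cb2 <- learnClassAwareCodebook(L, N, kHalf = 10L, seed = 5L)
  expect_identical(codewords(cb1), codewords(cb2))
  expect_identical(codebookId(cb1), codebookId(cb2))
})

test_that("undersized pools give an explicit error naming the pool", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(learnClassAwareCodebook(X, X, kHalf = 20L), "lesion pool")
  big <- matrix(rnorm(200), 50, 4)
  expect_error(learnClassAwareCodebook(big, X, kHalf = 20L), "normal pool")
})

test_that("within-cluster sum of squares is non-increasing over iterations", {
  set.seed(6)
  X <- matrix(rnorm(400), 100, 4)
  km <- fundusBoVW:::.kmeansLloyd(X, 8, maxIter = 50, seed = 11L)
  expect_true(all(diff(km$wssTrace) <= 1e-9))
})

test_that("per-class centroids recover well-separated modes", {
  set.seed(7)
  modesL <- matrix(c(0, 0, 8, 8), 2, 2, byrow = TRUE)
  modesN <- matrix(c(0, 8, 8, 0), 2, 2, byrow = TRUE)
  drawFrom <- function(modes, n) {
    pick <- sample(nrow(modes), n, replace = TRUE)
    modes[pick, ] + matrix(rnorm(2 * n, sd = 0.15), n, 2)
  }
  L <- drawFrom(modesL, 400); N <- drawFrom(modesN, 400)
  cb <- learnClassAwareCodebook(L, N, kHalf = 2L, seed = 13L)
  interMode <- 8 * sqrt(2)
  nearestModeDist <- function(C, modes)
    apply(C, 1, function(r) min(sqrt(colSums((t(modes) - r)^2))))
  expect_true(all(nearestModeDist(codewords(cb)[1:2, ], modesL) < interMode / 4))
  expect_true(all(nearestModeDist(codewords(cb)[3:4, ], modesN) < interMode / 4))
})

test_that("codebook serialization round-trips provenance and order", {
  set.seed(8)
  cb <- learnClassAwareCodebook(matrix(rnorm(120), 30, 4),
                                matrix(rnorm(120), 30, 4), kHalf = 5L,
                                seed = 21L, lesionLabel = "CS")
  path <- file.path(tempdir(), "cb.csv")
  writeCodebook(cb, path)
  cb2 <- readCodebook(path)
  expect_equal(codewords(cb2), codewords(cb), tolerance = 1e-12)
  expect_identical(provenance(cb2), provenance(cb))
  expect_identical(codebookId(cb2), codebookId(cb))
  expect_identical(halfSize(cb2), halfSize(cb))
  expect_identical(cb2@lesionLabel, "CS")
})

test_that("region annotations round-trip through JSON lines", {
  anns <- list(
    regionAnnotation("a", "HE", list(type = "circle", cx = 5, cy = 6, r = 7)),
    regionAnnotation("b", "RL", list(type = "polygon", px = c(0, 4, 4),
                                     py = c(0, 0, 4))))
  path <- file.path(tempdir(), "ann.jsonl")
  writeRegionAnnotations(anns, path)
  back <- readRegionAnnotations(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$shape$cx, 5)
  expect_equal(back[[2]]$lesionLabel, "RL")
  expect_equal(back[[2]]$shape$px, c(0, 4, 4))
})
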
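fullMask <- function(H, W) new("FovMask", mask = matrix(TRUE, H, W),
                               insideCount = as.integer(H * W))
emptyMask <- function(H, W) new("FovMask", mask = matrix(FALSE, H, W),
                                insideCount = 0L)

test_that("dense grid at radius 128 on a full 480x640 mask enumerates 12 points", {
  kp <- sampleDense(fullMask(480, 640), radii = 128)
  expect_equal(nrow(kp), 12)
  expect_setequal(unique(kp$x), c(128, 256, 384, 512))
  expect_setequal(unique(kp$y), c(128, 256, 384))
  expect_true(all(kp$radius == 128))
  expect_true(all(kp$source == "dense"))
})

test_that("dense grid counts equal brute-force enumeration over all radii", {
  radii <- c(12, 19, 31, 50, 80, 128)
  kp <- sampleDense(fullMask(480, 640), radii = radii)
  expected <- sum(vapply(radii, function(r) oracleDenseCount(480, 640, r), 0L))
  expect_equal(nrow(kp), expected)
  ## per-radius counts also match
  for (r in radii)
    expect_equal(sum(kp$radius == r), oracleDenseCount(480, 640, r))
})

test_that("dense sampling of an empty mask returns no keypoints", {
  kp <- sampleDense(emptyMask(200, 200), radii = c(12, 19))
  expect_equal(nrow(kp), 0)
})

test_that("dense sampling respects the FOV mask and is deterministic", {
  img <- diskImage()
  mk <- computeFovMask(img, 0.08)
  kp <- sampleDense(mk, radii = c(31, 50))
  expect_true(all(insideFov(mk, kp$x, kp$y)))
  expect_identical(kp, sampleDense(mk, radii = c(31, 50)))
})

test_that("a uniform image yields no sparse keypoints", {
  img <- FundusImage(array(120, dim = c(128, 128, 3)))
  mk <- new("FovMask", mask = matrix(TRUE, 128, 128), insideCount = 128L * 128L)
  kp <- detectSparse(img, mk, dohBackend())
  expect_equal(nrow(kp), 0)
})

test_that("detectSparse without a registered backend is a configuration error", {
  img <- diskImage()
  mk <- computeFovMask(img)
  expect_error(detectSparse(img, mk, backend = NULL), "backend")
})

test_that("planted high-contrast blobs are recovered near their centres", {
  set.seed(31)
  H <- 300; W <- 400
  px <- array(35, dim = c(H, W, 3))
  centers <- cbind(x = runif(10, 60, W - 60), y = runif(10, 60, H - 60))
  blobR <- 6
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  for (i in 1:10) {
    g <- exp(-outer((ys - centers[i, "y"])^2, (xs - centers[i, "x"])^2, "+") /
               (2 * (blobR / 1.5)^2))
    for (c in 1:3) px[, , c] <- pmin(255, px[, , c] + 180 * g)
  }
  img <- FundusImage(px, "blobs")
  mk <- new("FovMask", mask = matrix(TRUE, H, W),
            insideCount = as.integer(H * W))
  kp <- detectSparse(img, mk, dohBackend(threshold = 1e-5))
  expect_gt(nrow(kp), 0)
  for (i in 1:10) {
    d <- sqrt((kp$x - centers[i, "x"])^2 + (kp$y - centers[i, "y"])^2)
    expect_lt(min(d), 1.5 * blobR)
  }
})

test_that("tuning brings the batch-mean keypoint count near the target", {
  cfg <- fundusConfigA(seed = 77)
  imgs <- lapply(1:20, function(i)
    generateFundusImage(cfg, seed = i, imageId = paste0("tune", i))$image)
  ex <- extractSparseFeatures(imgs, targetCount = 400)
  counts <- vapply(ex$features, function(f) nrow(descriptors(f)), 0)
  expect_gte(mean(counts), 300)
  expect_lte(mean(counts), 500)
  ## every kept keypoint lies inside its image's FOV mask
  for (i in seq_along(imgs)) {
    kp <- keypoints(ex$features[[i]])
    expect_true(all(insideFov(ex$masks[[i]], kp$x, kp$y)))
  }
})

test_that("descriptors are 128-d, deterministic, and empty input is handled", {
  img <- diskImage()
  empty <- describeKeypoints(img, data.frame(x = numeric(0), y = numeric(0),
                                             radius = numeric(0),
                                             source = character(0)))
  expect_equal(nrow(descriptors(empty)), 0)
  expect_equal(ncol(descriptors(empty)), 128)
  kp <- data.frame(x = c(320, 200), y = c(240, 300), radius = c(20, 12),
                   source = "sparse")
  d1 <- describeKeypoints(img, kp)
  d2 <- describeKeypoints(img, kp)
  expect_equal(ncol(descriptors(d1)), 128)
  expect_identical(descriptors(d1), descriptors(d2))
  expect_equal(nrow(descriptors(d1)), nrow(keypoints(d1)))
})

test_that("keypoints whose support leaves the image are dropped with a message", {
  img <- diskImage()
  kp <- data.frame(x = c(320, 3), y = c(240, 3), radius = c(20, 50),
                   source = "sparse")
  expect_message(d <- describeKeypoints(img, kp), "dropped 1")
  expect_equal(nrow(descriptors(d)), 1)
  expect_equal(keypoints(d)$x, 320)
})
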
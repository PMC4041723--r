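## Score vectors where every component separates referral from non-referral.
separableScores <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  S <- matrix(rnorm(n * 6, sd = 0.3), n, 6) + 3 * y
  colnames(S) <- tolower(detectorOrder)
  list(S = S, y = y)
}

test_that("minmax calibration maps the training range onto [0, 1]", {
  S <- matrix(c(-2, 0, 2), 3, 1)[, rep(1, 6)]
  cal <- fitScoreCalibration(S, "minmax")
  out <- applyScoreCalibration(cal, S)
  expect_equal(out[1, 1], 0)
  expect_equal(out[3, 1], 1)
  expect_equal(out[2, 1], 0.5)
  ## applying stored parameters to new data is the same affine map
  out2 <- applyScoreCalibration(cal, matrix(1, 1, 6))
  expect_equal(out2[1, 1], 0.75)
})

test_that("sigmoid calibration squashes into (0, 1) monotonically", {
  set.seed(2)
  S <- matrix(rnorm(60), 10, 6)
  cal <- fitScoreCalibration(S, "sigmoid")
  out <- applyScoreCalibration(cal, S)
  expect_true(all(out > 0 & out < 1))
  o <- order(S[, 1])
  expect_true(all(diff(out[o, 1]) >= 0))
})

test_that("trainMeta enforces six components", {
  s <- separableScores()
  expect_error(trainMeta(s$S[, 1:5], s$y), "exactly 6")
  m <- trainMeta(s$S, s$y, CGrid = c(1, 10), gammaGrid = c(0.1, 1))
  expect_s4_class(m, "DetectorModel")
  expect_equal(m@lesionLabel, "referral")
  expect_equal(auc(rocCurve(scoreImage(m, s$S), s$y)), 1)
})

test_that("duplicate training rows leave the decision ordering unchanged", {
  s <- separableScores(seed = 3)
  m1 <- trainMeta(s$S, s$y, CGrid = 10, gammaGrid = 0.1)
  m2 <- trainMeta(rbind(s$S, s$S), c(s$y, s$y), CGrid = 10, gammaGrid = 0.1)
  probe <- separableScores(seed = 4)$S
  sc1 <- scoreImage(m1, probe); sc2 <- scoreImage(m2, probe)
  ## near-identical rankings (deep-in-class probes may swap within solver
  ## precision) and identical induced classification
  expect_gt(cor(sc1, sc2, method = "spearman"), 0.995)
  expect_equal(sc1 > 0, sc2 > 0)
})

test_that("5x2cv returns exactly 10 fold AUCs, deterministic in the seed", {
  s <- separableScores(n = 40, seed = 5)
  r1 <- fiveByTwoCv(s$S, s$y, seed = 3, CGrid = c(1, 10),
                    gammaGrid = c(0.1, 1), nFolds = 3)
  r2 <- fiveByTwoCv(s$S, s$y, seed = 3, CGrid = c(1, 10),
                    gammaGrid = c(0.1, 1), nFolds = 3)
  expect_length(foldAucs(r1), 10)
  expect_identical(foldAucs(r1), foldAucs(r2))
  expect_equal(auc(r1), mean(foldAucs(r1)))
  ## perfectly separable scores give mean AUC 1
  expect_equal(auc(r1), 1)
})

test_that("5x2cv halves are stratified within one example of the global rate", {
  set.seed(6)
  y <- rep(c(1, 0), times = c(17, 23))
  idx1 <- fundusBoVW:::.halfSplit(y, seed = 11)
  y1 <- y[idx1]; y2 <- y[-idx1]
  expect_lte(abs(sum(y1) - sum(y2)), 1)
  expect_lte(abs(length(y1) - length(y2)), 2)
})

test_that("too few examples per class is an error", {
  s <- separableScores(n = 12, seed = 7)
  expect_error(fiveByTwoCv(s$S, s$y, seed = 1), "at least 10")
})

test_that("buildScoreVectors produces ordered six-component rows", {
  set.seed(8)
  cw <- matrix(rnorm(40), 20, 2)
  cb <- Codebook(cw, lesionLabel = "HE", seed = 1L,
                 provenance = rep(c("lesion", "normal"), each = 10))
  mkVec <- function(shift) encodeImage(matrix(rnorm(10 * 2) + shift, 10, 2),
                                       cb, coding = "semisoft")
  vecs <- lapply(c(rep(2, 10), rep(-2, 10)), mkVec)
  y <- rep(c(1, 0), each = 10)
  X <- do.call(rbind, lapply(vecs, bovw))
  det <- trainDetector(X, y, lesionLabel = "HE", codebook = cb,
                       treatment = c(featureMode = "sparse", coding = "semisoft",
                                     pooling = "max", norm = "L1"),
                       CGrid = 10, gammaGrid = 0.5, nFolds = 3)
  detectors <- setNames(rep(list(det), 6), detectorOrder)
  dsets <- lapply(1:3, function(i)
    DescriptorSet(matrix(rnorm(10 * 2), 10, 2),
                  data.frame(x = 1:10, y = 1:10, radius = 5, source = "sparse"),
                  imageId = paste0("img", i)))
  sv <- buildScoreVectors(dsets, detectors)
  expect_equal(names(sv), c("imageId", "he", "sh", "dh", "rl", "cs", "d"))
  expect_equal(nrow(sv), 3)
  expect_true(all(is.finite(as.matrix(sv[, -1]))))
  ## missing detector -> error
  expect_error(buildScoreVectors(dsets, detectors[1:5]), "missing detector")
})
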
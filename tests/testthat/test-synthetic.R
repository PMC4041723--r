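test_that("generation is bit-identical for a fixed (config, seed)", {
  cfg <- fundusConfigA(seed = 42)
  a <- generateFundusImage(cfg, seed = 5)
  b <- generateFundusImage(cfg, seed = 5)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$labels, b$labels)
  d1 <- generateFundusDataset(fundusConfig(width = 128L, height = 128L,
                                           seed = 3L), 4)
  d2 <- generateFundusDataset(fundusConfig(width = 128L, height = 128L,
                                           seed = 3L), 4)
  expect_identical(lapply(datasetImages(d1), pixels),
                   lapply(datasetImages(d2), pixels))
})

test_that("an all-zero lesion mix yields healthy images only", {
  cfg <- fundusConfig(width = 160L, height = 120L,
                      lesionMix = setNames(rep(0, 6),
                                           c("HE", "SH", "DH", "RL", "CS", "D")),
                      seed = 7L)
  ds <- generateFundusDataset(cfg, 10)
  expect_equal(sum(datasetLabels(ds)$referral), 0)
  expect_length(datasetAnnotations(ds), 0)
})

test_that("a forced label plants exactly the requested number of regions", {
  cfg <- fundusConfig(width = 320L, height = 240L,
                      lesionMix = c(HE = 1, SH = 0, DH = 0, RL = 0, CS = 0, D = 0),
                      regionsPerPositive = c(3L, 3L), seed = 9L)
  one <- generateFundusImage(cfg, seed = 2)
  expect_equal(one$labels[["HE"]], 1L)
  expect_equal(length(one$regions), 3)
  expect_true(all(vapply(one$regions, function(r) r$lesionLabel, "") == "HE"))
  expect_equal(one$referral, 1L)
})

test_that("label prevalences stay within the binomial range", {
  cfg <- fundusConfig(width = 128L, height = 96L,
                      lesionMix = c(HE = 0.4, SH = 0, DH = 0, RL = 0, CS = 0,
                                    D = 0), seed = 123L)
  ds <- generateFundusDataset(cfg, 200)
  nHE <- sum(datasetLabels(ds)$he)
  expect_gte(nHE, 60)   # 0.4 * 200 +/- ~2 sd
  expect_lte(nHE, 100)
})

test_that("referral is the OR over planted lesion labels", {
  ds <- generateFundusDataset(fundusConfig(width = 160L, height = 120L,
                                           seed = 31L), 30)
  lab <- datasetLabels(ds)
  expect_equal(lab$referral,
               as.integer(lab$he | lab$sh | lab$dh | lab$rl | lab$cs | lab$d))
})

test_that("annotated regions stay inside the field of view", {
  cfg <- fundusConfigA(seed = 55)
  ds <- generateFundusDataset(cfg, 6)
  Rfov <- cfg@fovRadiusFraction * min(cfg@width, cfg@height)
  cx <- (cfg@width - 1) / 2; cy <- (cfg@height - 1) / 2
  for (rg in datasetAnnotations(ds)) {
    s <- rg$shape
    d <- sqrt((s$cx - cx)^2 + (s$cy - cy)^2)
    expect_lte(d + s$r, Rfov + 1e-6)
  }
})

test_that("planted lesion pixels contrast with the local background above the noise", {
  cfg <- fundusConfig(width = 320L, height = 240L, noiseStd = 0.02,
                      lesionMix = c(HE = 1, SH = 0, DH = 0, RL = 0, CS = 0, D = 0),
                      regionsPerPositive = c(2L, 2L), seed = 77L)
  one <- generateFundusImage(cfg, seed = 4)
  g <- grayMatrix(one$image)
  for (rg in one$regions) {
    inst <- rg$instances
    peak <- g[round(inst$y[1]) + 1, round(inst$x[1]) + 1]
    ring <- g[round(rg$shape$cy) + 1,
              max(1, round(rg$shape$cx - rg$shape$r)) + 1]
    expect_gt(abs(peak - ring), 3 * cfg@noiseStd)
  }
})

test_that("datasets round-trip to disk as PNG + JSONL + CSV", {
  ds <- generateFundusDataset(fundusConfig(width = 96L, height = 96L,
                                           seed = 12L), 2)
  dir <- file.path(tempdir(), "synthds")
  writeFundusDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "annotations.jsonl")))
  img <- readFundusImage(file.path(dir, paste0(imageId(datasetImages(ds)[[1]]),
                                               ".png")))
  expect_equal(pixels(img), pixels(datasetImages(ds)[[1]]), tolerance = 1)
})
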
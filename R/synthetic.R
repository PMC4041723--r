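## Seeded generator of fundus-like images: circular field of view on a dark
## background, low-frequency illumination, vessel-like curvilinear
## structures, an optic-disc-like bright disk, and planted lesions with
## label-specific Gaussian-profile appearance priors:
##   HE  clusters of small sharp bright yellow blobs
##   D   clusters of medium softer pale-orange blobs (drusen)
##   SH  flame-shaped bundles of parallel dark red streaks (superficial
##       hemorrhages)
##   DH  large round dark red blots (deep hemorrhages)
##   RL  tiny dark red dots (microaneurysm-like red lesions)
##   CS  large faint fuzzy pale patches (cotton-wool spots)
## Every planted lesion is covered by an annotated circle; referral is the OR
## over planted labels. All geometry scales with the image resolution so two
## configurations with different resolution/illumination emulate a
## cross-dataset protocol.

#' Synthetic fundus generator configuration
#'
#' @param width,height image size in pixels.
#' @param fovRadiusFraction field-of-view radius as a fraction of
#'   `min(width, height)`.
#' @param illuminationGain background illumination gain.
#' @param noiseStd additive Gaussian noise std on the 0--1 scale.
#' @param vesselCount number of vessel-like structures.
#' @param lesionMix named per-label planting probabilities (HE, SH, DH, RL,
#'   CS, D).
#' @param regionsPerPositive integer range of annotated regions per planted
#'   label (default 2--5, the typical number of marked regions per affected
#'   patient image).
#' @param seed master seed; a dataset is fully reproducible from
#'   (config, seed).
#' @return A [FundusConfig-class].
#' @export
fundusConfig <- function(width = 640L, height = 480L, fovRadiusFraction = 0.46,
                         illuminationGain = 1.0, noiseStd = 0.02,
                         vesselCount = 7L,
                         lesionMix = c(HE = 0.2, SH = 0.2, DH = 0.2,
                                       RL = 0.2, CS = 0.2, D = 0.2),
                         regionsPerPositive = c(2L, 5L), seed = 1L) {
  new("FundusConfig", width = as.integer(width), height = as.integer(height),
      fovRadiusFraction = fovRadiusFraction,
      illuminationGain = illuminationGain, noiseStd = noiseStd,
      vesselCount = as.integer(vesselCount), lesionMix = lesionMix,
      regionsPerPositive = as.integer(regionsPerPositive),
      seed = as.integer(seed))
}

#' Standard generator configurations emulating two acquisition setups
#'
#' Configuration "A" produces 640 x 480 images (a one-megapixel mydriatic
#' camera setting); configuration "B" produces 867 x 575 images with a
#' brighter illumination field and slightly stronger noise (a different
#' retinograph). Training on one and testing on the other emulates the
#' cross-dataset protocol.
#'
#' @param seed master seed.
#' @param ... overrides passed to [fundusConfig()].
#' @return A [FundusConfig-class].
#' @export
fundusConfigA <- function(seed = 1L, ...) {
  fundusConfig(width = 640L, height = 480L, illuminationGain = 1.0,
               noiseStd = 0.02, seed = seed, ...)
}

#' @rdname fundusConfigA
#' @export
fundusConfigB <- function(seed = 1L, ...) {
  fundusConfig(width = 867L, height = 575L, illuminationGain = 1.2,
               noiseStd = 0.025, seed = seed, ...)
}

## blend an elliptical Gaussian blob into the channel list (in place via
## the compiled stamper; the channel matrices are owned by the generator)
.stampBlob <- function(ch, cx, cy, sx, sy, theta, amp, color) {
  cppStampBlob(ch[[1]], ch[[2]], ch[[3]], cx, cy, sx, sy, theta, amp, color)
  ch
}

## Label-specific appearance priors, separated along orthogonal structural
## axes so the visual classes are distinguishable by construction:
## polarity (bright HE/D/CS vs dark SH/DH/RL), scale (tiny RL < small HE <
## medium D < large DH/SH/CS), sharpness/contrast (sharp HE vs faint fuzzy
## CS) and shape (round vs elongated SH). Every lesion is a multi-blob
## composite, emulating the clustered/granular look of real lesions.
.lesionPriors <- function(sf) {
  list(
    HE = list(nb = c(8, 12), sx = c(1.2, 2.0) * sf, aspect = 1, amp = c(0.65, 0.85),
              color = c(0.99, 0.93, 0.50), rr = c(11, 16) * sf),
    SH = list(nb = c(5, 7), sx = c(5.5, 7.5) * sf, aspect = c(0.25, 0.35),
              amp = c(0.75, 0.9), streaks = TRUE,
              color = c(0.22, 0.05, 0.05), rr = c(15, 21) * sf),
    DH = list(nb = c(4, 5), sx = c(4, 5) * sf, aspect = 1, amp = c(0.75, 0.9),
              color = c(0.18, 0.04, 0.04), rr = c(16, 22) * sf),
    RL = list(nb = c(6, 10), sx = c(0.9, 1.5) * sf, aspect = 1, amp = c(0.7, 0.9),
              color = c(0.25, 0.06, 0.06), rr = c(9, 14) * sf),
    CS = list(nb = c(5, 6), sx = c(5, 6.5) * sf, aspect = 1, amp = c(0.45, 0.55),
              color = c(0.93, 0.90, 0.82), rr = c(20, 26) * sf),
    D  = list(nb = c(6, 10), sx = c(2.6, 3.6) * sf, aspect = 1, amp = c(0.55, 0.7),
              color = c(0.97, 0.87, 0.68), rr = c(14, 20) * sf))
}

## draw one image under the *current* RNG state
.generateOne <- function(config, imageId, datasetTag) {
  W <- config@width; H <- config@height
  sf <- min(W, H) / 480
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Rfov <- config@fovRadiusFraction * min(W, H)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  dx <- outer(rep(1, H), xs - cx); dy <- outer(ys - cy, rep(1, W))
  dist2 <- dx^2 + dy^2
  fov <- dist2 <= Rfov^2
  ## illumination field
  ax <- runif(1, -1, 1); ay <- runif(1, -1, 1)
  field <- config@illuminationGain *
    (0.82 + 0.12 * ax * dx / W + 0.12 * ay * dy / H) *
    (1 - 0.30 * pmin(dist2 / Rfov^2, 1))
  base <- c(0.72, 0.38, 0.16)
  ch <- lapply(1:3, function(c) base[c] * field * fov + 0.02 * !fov)
  ## optic-disc-like bright disk
  discAng <- runif(1, 0, 2 * pi)
  discR <- 0.09 * min(W, H)
  dcx <- cx + 0.55 * Rfov * cos(discAng); dcy <- cy + 0.55 * Rfov * sin(discAng)
  ch <- .stampBlob(ch, dcx, dcy, discR / 1.8, discR / 1.8, 0, 0.55,
                   c(0.98, 0.85, 0.55))
  ## vessels: random curvilinear walks from the disc with decreasing width,
  ## accumulated into one alpha mask (max rule) and blended once
  A <- matrix(0, H, W)
  for (v in seq_len(config@vesselCount)) {
    ang0 <- runif(1, 0, 2 * pi)
    w0 <- runif(1, 2.4, 3.6) * sf
    nStep <- round(runif(1, 120, 220) * sf)
    angs <- ang0 + cumsum(rnorm(nStep, 0, 0.07))
    px <- dcx + 2 * cumsum(cos(angs))
    py <- dcy + 2 * cumsum(sin(angs))
    out <- which((px - cx)^2 + (py - cy)^2 > (0.95 * Rfov)^2)
    keep <- if (length(out)) seq_len(out[1] - 1) else seq_len(nStep)
    if (!length(keep)) next
    wv <- w0 * (1 - 0.6 * keep / nStep)
    cppMaxDisks(A, px[keep], py[keep], wv / 1.4, 0.8)
  }
  vcol <- c(0.30, 0.08, 0.05)
  for (c in 1:3) ch[[c]] <- ch[[c]] * (1 - A) + vcol[c] * A
  ## lesions
  priors <- .lesionPriors(sf)
  labels <- setNames(integer(6), names(config@lesionMix))
  regions <- list()
  for (lab in names(config@lesionMix)) {
    if (runif(1) >= config@lesionMix[[lab]]) next
    labels[lab] <- 1L
    rp <- config@regionsPerPositive
    nReg <- if (rp[1] == rp[2]) rp[1] else sample(rp[1]:rp[2], 1)
    pr <- priors[[lab]]
    for (g in seq_len(nReg)) {
      sx <- runif(1, pr$sx[1], pr$sx[2])
      rr <- if (is.null(pr$rr)) 2.2 * sx else runif(1, pr$rr[1], pr$rr[2])
      ang <- runif(1, 0, 2 * pi)
      dmax <- max(Rfov - rr - 3 * sf, 1)
      d <- sqrt(runif(1)) * dmax
      gx <- cx + d * cos(ang); gy <- cy + d * sin(ang)
      nb <- if (pr$nb[1] == pr$nb[2]) pr$nb[1] else sample(pr$nb[1]:pr$nb[2], 1)
      inst <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0))
      if (isTRUE(pr$streaks)) {
        ## flame-shaped striated composite: parallel thin streaks sharing
        ## one orientation, offset along the perpendicular
        thR <- runif(1, 0, pi)
        ux <- -sin(thR); uy <- cos(thR)
        for (b in seq_len(nb)) {
          bsx <- runif(1, pr$sx[1], pr$sx[2])
          bsy <- bsx * runif(1, pr$aspect[1], pr$aspect[2])
          off <- (b - (nb + 1) / 2) * 2.8 * bsy + rnorm(1, 0, 0.5 * sf)
          ox <- off * ux + rnorm(1, 0, sf); oy <- off * uy + rnorm(1, 0, sf)
          amp <- runif(1, pr$amp[1], pr$amp[2])
          ch <- .stampBlob(ch, gx + ox, gy + oy, bsx, bsy, thR, amp, pr$color)
          inst <- rbind(inst, data.frame(x = gx + ox, y = gy + oy, sigma = bsx))
        }
      } else {
        for (b in seq_len(nb)) {
          bsx <- runif(1, pr$sx[1], pr$sx[2])
          asp <- if (length(pr$aspect) == 1) pr$aspect else runif(1, pr$aspect[1], pr$aspect[2])
          bsy <- bsx * asp
          ## spread composite blobs uniformly over the region disk so that
          ## instances stay resolvable rather than merging at the centre
          maxOff <- max(rr - 2.5 * bsx, 0)
          offR <- if (nb == 1) 0 else maxOff * sqrt(runif(1))
          offTh <- runif(1, 0, 2 * pi)
          ox <- offR * cos(offTh); oy <- offR * sin(offTh)
          amp <- runif(1, pr$amp[1], pr$amp[2])
          th <- runif(1, 0, pi)
          ch <- .stampBlob(ch, gx + ox, gy + oy, bsx, bsy, th, amp, pr$color)
          inst <- rbind(inst, data.frame(x = gx + ox, y = gy + oy, sigma = bsx))
        }
      }
      rg <- regionAnnotation(imageId, lab,
                             list(type = "circle", cx = gx, cy = gy, r = rr))
      rg$instances <- inst
      regions <- c(regions, list(rg))
    }
  }
  ## noise, clip, quantise
  px <- array(0L, dim = c(H, W, 3))
  for (c in 1:3) {
    m <- ch[[c]] + matrix(rnorm(H * W, 0, config@noiseStd), H, W)
    px[, , c] <- as.integer(round(255 * pmin(pmax(m, 0), 1)))
  }
  img <- FundusImage(px, imageId = imageId, datasetTag = datasetTag)
  list(image = img, regions = regions, labels = labels,
       referral = as.integer(any(labels == 1L)))
}

#' Generate one synthetic fundus image
#'
#' @param config a [FundusConfig-class].
#' @param seed seed for this image (defaults to the config seed).
#' @param imageId,datasetTag identifiers for the produced image.
#' @return list with `image` ([FundusImage-class]), `regions` (annotation
#'   list, each carrying an `instances` data.frame of planted blob centres as
#'   ground truth), `labels` (named 0/1 vector) and `referral`.
#' @export
generateFundusImage <- function(config, seed = config@seed, imageId = "synth-1",
                                datasetTag = "synth") {
  withr::with_seed(as.integer(seed), .generateOne(config, imageId, datasetTag))
}

#' Generate a synthetic fundus dataset
#'
#' Draws `n` images sequentially under the config's master seed: per-label
#' presence is Bernoulli with the `lesionMix` probabilities, every planted
#' label gets 2--5 (configurable) annotated circular regions, and the
#' referral label is the OR over planted labels. Bit-identical for a fixed
#' (config, n).
#'
#' @param config a [FundusConfig-class].
#' @param n number of images.
#' @param datasetTag tag recorded on every image.
#' @return A [SyntheticDataset-class].
#' @export
generateFundusDataset <- function(config, n, datasetTag = "synth") {
  stopifnot(n >= 1)
  withr::with_seed(config@seed, {
    images <- vector("list", n)
    annotations <- list()
    lab <- matrix(0L, n, 6, dimnames = list(NULL, names(config@lesionMix)))
    referral <- integer(n)
    ids <- sprintf("%s-%04d", datasetTag, seq_len(n))
    for (i in seq_len(n)) {
      one <- .generateOne(config, ids[i], datasetTag)
      images[[i]] <- one$image
      annotations <- c(annotations, one$regions)
      lab[i, ] <- one$labels
      referral[i] <- one$referral
    }
    labels <- data.frame(imageId = ids,
                         he = lab[, "HE"], sh = lab[, "SH"], dh = lab[, "DH"],
                         rl = lab[, "RL"], cs = lab[, "CS"], d = lab[, "D"],
                         referral = referral, stringsAsFactors = FALSE)
    new("SyntheticDataset", images = images, annotations = annotations,
        labels = labels, config = config)
  })
}

#' Write a synthetic dataset to disk
#'
#' PNG images, JSON-lines region annotations and a CSV label manifest.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFundusDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (img in datasetImages(dataset))
    writeFundusImage(img, file.path(dir, paste0(imageId(img), ".png")))
  writeRegionAnnotations(datasetAnnotations(dataset),
                         file.path(dir, "annotations.jsonl"))
  write.csv(datasetLabels(dataset), file.path(dir, "labels.csv"),
            row.names = FALSE)
  invisible(dir)
}
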
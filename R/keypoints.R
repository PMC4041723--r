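## Keypoints are plain data.frames with columns x, y, radius, source
## (and, for sparse detections, strength). Coordinates are 0-based,
## x = column, y = row.

.emptyKeypoints <- function() {
  data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Dense multi-scale grid sampling of patch keypoints
#'
#' For each radius `r` the grid points sit at `x = r, 2r, 3r, ...` and
#' `y = r, 2r, 3r, ...` (0-based, strictly inside the image bounds), i.e. the
#' radius serves both as the patch scale and as the horizontal/vertical
#' sampling step. Points outside the FOV mask are discarded; the union over
#' all radii is returned.
#'
#' @param mask a [FovMask-class].
#' @param radii positive patch radii in pixels; the default covers small
#'   lesions such as superficial hemorrhages up to very large structures.
#' @return Keypoint data.frame with `source = "dense"`.
#' @export
sampleDense <- function(mask, radii = c(12, 19, 31, 50, 80, 128)) {
  stopifnot(is(mask, "FovMask"), length(radii) > 0, all(radii > 0))
  m <- fovMask(mask)
  H <- nrow(m); W <- ncol(m)
  out <- lapply(radii, function(r) {
    xs <- seq(r, W - 1, by = r)
    ys <- seq(r, H - 1, by = r)
    if (!length(xs) || !length(ys)) return(NULL)
    g <- expand.grid(x = xs, y = ys)
    keep <- m[cbind(g$y + 1L, g$x + 1L)]
    if (!any(keep)) return(NULL)
    data.frame(x = g$x[keep], y = g$y[keep], radius = r, source = "dense",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .emptyKeypoints() else out
}

## ---- sparse backend -----------------------------------------------------

.backendEnv <- new.env(parent = emptyenv())

#' Determinant-of-Hessian sparse keypoint backend
#'
#' The sparse detector is pluggable; the built-in backend finds blob-like
#' salient regions as scale-space maxima of the scale-normalised determinant
#' of the Hessian (computed from Gaussian-smoothed second derivatives), the
#' same quantity thresholded by SURF-family detectors. Descriptors are
#' upright extended 128-d SURF-style vectors (see [describeKeypoints()]).
#'
#' With `upsample = TRUE` the detector emulates operation on twice the image
#' resolution by shifting the scale pyramid one octave down (all analysis
#' scales halved), so that structures half the usual minimum size are
#' detectable without resampling the image.
#'
#' @param threshold response threshold on the scale-normalised determinant of
#'   the Hessian; tune it against a target keypoint count with
#'   [tuneSparseBackend()].
#' @param nScales number of pyramid levels.
#' @param baseSigma smallest analysis scale (before the upsample shift).
#' @param scaleRatio geometric ratio between consecutive scales.
#' @param upsample logical; operate at twice the effective resolution.
#' @param radiusFactor keypoint radius reported as `radiusFactor * sigma`.
#' @param id backend identifier recorded in serialized artifacts.
#' @return A `sparseBackend` object (list).
#' @export
dohBackend <- function(threshold = 1e-6, nScales = 8L, baseSigma = 1.7,
                       scaleRatio = 1.5, upsample = TRUE, radiusFactor = 5,
                       id = "doh-surf128-v1") {
  structure(list(threshold = threshold, nScales = as.integer(nScales),
                 baseSigma = baseSigma, scaleRatio = scaleRatio,
                 upsample = upsample, radiusFactor = radiusFactor, id = id),
            class = "sparseBackend")
}

#' @rdname dohBackend
#' @param backend a `sparseBackend` to register as the session default used
#'   by [detectSparse()] when no backend is passed explicitly.
#' @export
setSparseBackend <- function(backend) {
  stopifnot(inherits(backend, "sparseBackend"))
  assign("backend", backend, envir = .backendEnv)
  invisible(backend)
}

#' @rdname dohBackend
#' @export
getSparseBackend <- function() {
  if (!exists("backend", envir = .backendEnv)) NULL
  else get("backend", envir = .backendEnv)
}

.backendSigmas <- function(backend) {
  s <- backend$baseSigma * backend$scaleRatio^(seq_len(backend$nScales) - 1)
  if (isTRUE(backend$upsample)) s / 2 else s
}

.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## All candidate scale-space maxima (threshold 0) of one image. Levels with
## sigma >= 4 are computed on a half-resolution octave (with sigma halved;
## the scale-normalised determinant of the Hessian is invariant under that
## rescaling) and the response upsampled back to the full grid.
.dohCandidates <- function(gray, backend) {
  sigmas <- .backendSigmas(backend)
  H <- nrow(gray); W <- ncol(gray)
  half <- NULL
  dohPlane <- function(img, sg) {
    k <- .gaussKernel(sg)
    sm <- cppConvSep(img, k, k)
    lxx <- cppConvSep(sm, c(1, -2, 1), 1)
    lyy <- cppConvSep(sm, 1, c(1, -2, 1))
    lxy <- cppConvSep(sm, c(-0.5, 0, 0.5), c(-0.5, 0, 0.5))
    sg^4 * (lxx * lyy - lxy^2)
  }
  planes <- lapply(sigmas, function(sg) {
    if (sg < 4) return(dohPlane(gray, sg))
    if (is.null(half))
      half <<- cppResize(gray, as.integer(ceiling(H / 2)),
                         as.integer(ceiling(W / 2)))
    cppResize(dohPlane(half, sg / 2), H, W)
  })
  ## tiny absolute floor on the scale-normalised response: orders of
  ## magnitude below any tuned operating threshold, it only prunes the
  ## near-zero background from the neighbourhood scan
  cand <- cppScaleSpaceMaxima(planes, 1e-9)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      source = character(0), strength = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(x = cand[, "x"], y = cand[, "y"],
             radius = backend$radiusFactor * sigmas[cand[, "scaleIndex"]],
             source = "sparse", strength = cand[, "strength"],
             stringsAsFactors = FALSE)
}

#' Tune the sparse detector sensitivity against a target keypoint count
#'
#' Detector sensitivity is pre-tuned so that the *batch mean* number of
#' keypoints per image (counted after FOV filtering) matches a target --
#' 400 points of interest per image by default. The response threshold is
#' found by bisection against the batch-mean count over the cached candidate
#' responses, in at most `maxIter` iterations.
#'
#' @param images list of [FundusImage-class].
#' @param masks list of [FovMask-class] matching `images`.
#' @param targetCount target mean number of keypoints per image.
#' @param backend backend to tune (default a fresh [dohBackend()]).
#' @param maxIter bisection iterations.
#' @return The tuned backend, with `threshold` set.
#' @export
tuneSparseBackend <- function(images, masks, targetCount = 400,
                              backend = dohBackend(), maxIter = 12L) {
  stopifnot(length(images) == length(masks), targetCount > 0)
  strengths <- mapply(function(im, mk) {
    cand <- .dohCandidates(grayMatrix(im), backend)
    cand$strength[insideFov(mk, cand$x, cand$y)]
  }, images, masks, SIMPLIFY = FALSE)
  all <- unlist(strengths)
  n <- length(images)
  if (!length(all)) stop("no candidate keypoints found in the tuning batch")
  meanCount <- function(t) sum(all > t) / n
  lo <- 0; hi <- max(all)
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    if (meanCount(mid) > targetCount) lo <- mid else hi <- mid
  }
  thr <- (lo + hi) / 2
  if (meanCount(thr) < targetCount) thr <- lo
  backend$threshold <- thr
  backend
}

#' Detect sparse interest points in a fundus image
#'
#' Runs the registered (or supplied) blob-detection backend and keeps
#' scale-space maxima whose response exceeds the backend threshold and whose
#' centre lies inside the FOV mask. A uniform image yields no keypoints.
#'
#' @param image a [FundusImage-class].
#' @param mask a [FovMask-class].
#' @param backend a `sparseBackend`; defaults to the registered one.
#' @return Keypoint data.frame with columns `x`, `y`, `radius`, `source`,
#'   `strength`.
#' @export
detectSparse <- function(image, mask, backend = getSparseBackend()) {
  if (is.null(backend))
    stop("no sparse backend registered; call setSparseBackend() or pass one")
  stopifnot(is(image, "FundusImage"), is(mask, "FovMask"))
  cand <- .dohCandidates(grayMatrix(image), backend)
  keep <- cand$strength > backend$threshold & insideFov(mask, cand$x, cand$y)
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Compute 128-d descriptors for a set of keypoints
#'
#' Each keypoint is described by an upright extended SURF-style 128-d vector
#' (4 x 4 subregions, 8 extended gradient statistics each, Gaussian-weighted,
#' L2-normalised) sampled from the slightly smoothed grayscale image on a
#' 20 x 20 grid with step `radius / 10`, so the descriptor window spans the
#' patch diameter. Keypoints whose support disk leaves the image are dropped
#' with a message.
#'
#' @param image a [FundusImage-class].
#' @param keypoints keypoint data.frame (columns `x`, `y`, `radius`, `source`).
#' @param smoothSigma Gaussian pre-smoothing scale for gradient estimation.
#' @return A [DescriptorSet-class]; row order matches the kept keypoints.
#' @export
describeKeypoints <- function(image, keypoints, smoothSigma = 1.0) {
  stopifnot(is(image, "FundusImage"))
  .describeFromGray(grayMatrix(image), keypoints, imageId(image), smoothSigma)
}

.describeFromGray <- function(g, keypoints, imgId, smoothSigma = 1.0) {
  H <- nrow(g); W <- ncol(g)
  if (nrow(keypoints) == 0)
    return(DescriptorSet(matrix(0, 0, 128), .emptyKeypoints(), imgId))
  ok <- keypoints$x - keypoints$radius >= -1 &
        keypoints$x + keypoints$radius <= W &
        keypoints$y - keypoints$radius >= -1 &
        keypoints$y + keypoints$radius <= H &
        keypoints$radius > 0
  if (any(!ok))
    message(sprintf("describeKeypoints: dropped %d keypoint(s) whose support leaves the image",
                    sum(!ok)))
  kp <- keypoints[ok, , drop = FALSE]
  rownames(kp) <- NULL
  if (nrow(kp) == 0)
    return(DescriptorSet(matrix(0, 0, 128), .emptyKeypoints(), imgId))
  k <- .gaussKernel(smoothSigma)
  sm <- cppConvSep(g, k, k)
  desc <- cppSurfDescribe(sm, kp$x, kp$y, kp$radius / 10)
  DescriptorSet(desc, kp, imgId)
}

#' Extract sparse descriptors for every image of a batch
#'
#' Convenience wrapper: computes FOV masks, tunes the backend on the batch
#' when an untuned backend is given, detects and describes.
#'
#' @param images list of [FundusImage-class].
#' @param backend a tuned `sparseBackend`, or `NULL` to tune a fresh
#'   [dohBackend()] on this batch.
#' @param targetCount target mean keypoints per image for tuning.
#' @param fovThreshold FOV gray threshold.
#' @param keepMasks retain the FOV masks in the result (set `FALSE` for
#'   large batches to cap memory).
#' @return list with elements `features` (list of [DescriptorSet-class]),
#'   `masks` (or `NULL`), and the tuned `backend`.
#' @export
extractSparseFeatures <- function(images, backend = NULL, targetCount = 400,
                                  fovThreshold = 0.08, keepMasks = TRUE) {
  tune <- is.null(backend)
  be <- if (tune) dohBackend() else backend
  n <- length(images)
  masks <- vector("list", n)
  feats <- vector("list", n)
  if (tune) {
    ## pass 1: cache all candidate responses; bisect the threshold against
    ## the batch-mean count; pass 2: filter and describe
    cands <- vector("list", n)
    for (i in seq_len(n)) {
      g <- grayMatrix(images[[i]])
      mk <- .fovMaskFromGray(g, fovThreshold)
      cand <- .dohCandidates(g, be)
      cands[[i]] <- cand[insideFov(mk, cand$x, cand$y), , drop = FALSE]
      masks[[i]] <- mk
    }
    all <- unlist(lapply(cands, `[[`, "strength"))
    if (!length(all)) stop("no candidate keypoints found in the tuning batch")
    lo <- 0; hi <- max(all)
    for (i in seq_len(12L)) {
      mid <- (lo + hi) / 2
      if (sum(all > mid) / n > targetCount) lo <- mid else hi <- mid
    }
    thr <- (lo + hi) / 2
    if (sum(all > thr) / n < targetCount) thr <- lo
    be$threshold <- thr
    for (i in seq_len(n)) {
      kp <- cands[[i]][cands[[i]]$strength > thr, , drop = FALSE]
      rownames(kp) <- NULL
      feats[[i]] <- .describeFromGray(grayMatrix(images[[i]]), kp,
                                      imageId(images[[i]]))
    }
  } else {
    for (i in seq_len(n)) {
      g <- grayMatrix(images[[i]])
      mk <- .fovMaskFromGray(g, fovThreshold)
      cand <- .dohCandidates(g, be)
      keep <- cand$strength > be$threshold & insideFov(mk, cand$x, cand$y)
      kp <- cand[keep, , drop = FALSE]
      rownames(kp) <- NULL
      feats[[i]] <- .describeFromGray(g, kp, imageId(images[[i]]))
      masks[[i]] <- mk
    }
  }
  list(features = feats, masks = if (keepMasks) masks else NULL,
       backend = be)
}
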
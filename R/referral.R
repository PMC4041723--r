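## Referral vs non-referral meta-classification: the six per-lesion detector
## scores form the feature vector of a second-layer RBF-SVM. Detector order
## is fixed: HE, SH, DH, RL, CS, D.

#' Fixed lesion-detector order of the referral score vector
#'
#' The six per-lesion detectors always appear in this order in score vectors
#' and score tables: hard exudates, superficial hemorrhages, deep
#' hemorrhages, red lesions, cotton-wool spots, drusen.
#'
#' @format character vector of length 6.
#' @export
detectorOrder <- c("HE", "SH", "DH", "RL", "CS", "D")

#' Fit a per-detector score calibration
#'
#' The operational point of each detector is fixed on training images only:
#' calibration parameters are fitted on the training score matrix and then
#' applied unchanged to test scores. `minmax` maps the training score range
#' of each detector affinely to `[0, 1]` (a normalized "probability of
#' presence"); `sigmoid` applies a logistic squashing centred on the training
#' mean with the training standard deviation as scale; `none` is the
#' identity.
#'
#' @param scores numeric matrix of raw detector scores (images x detectors).
#' @param method `"none"`, `"minmax"` or `"sigmoid"`.
#' @return A `scoreCalibration` object.
#' @export
fitScoreCalibration <- function(scores, method = c("minmax", "sigmoid", "none")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  params <- switch(method,
    none = NULL,
    minmax = list(lo = apply(scores, 2, min), hi = apply(scores, 2, max)),
    sigmoid = list(mu = colMeans(scores), s = apply(scores, 2, sd)))
  structure(list(method = method, params = params), class = "scoreCalibration")
}

#' @rdname fitScoreCalibration
#' @param calibration a fitted `scoreCalibration`.
#' @export
applyScoreCalibration <- function(calibration, scores) {
  stopifnot(inherits(calibration, "scoreCalibration"))
  scores <- as.matrix(scores)
  p <- calibration$params
  switch(calibration$method,
    none = scores,
    minmax = {
      rng <- pmax(p$hi - p$lo, 1e-12)
      sweep(sweep(scores, 2, p$lo), 2, rng, "/")
    },
    sigmoid = {
      s <- pmax(p$s, 1e-12)
      1 / (1 + exp(-sweep(sweep(scores, 2, p$mu), 2, s, "/")))
    })
}

#' Build per-image score vectors from the six lesion detectors
#'
#' For each image the six detectors (in the fixed order HE, SH, DH, RL, CS,
#' D, all sharing one treatment) score the image's descriptors; the ordered,
#' optionally calibrated scores form the meta-classification feature vector.
#'
#' @param dsets list of [DescriptorSet-class], one per image.
#' @param detectors named list of six [DetectorModel-class], names
#'   `detectorOrder`.
#' @param calibration a fitted `scoreCalibration`, or `NULL` for raw scores.
#' @param params [codingParams()] used for encoding.
#' @return data.frame with `imageId` and columns `he, sh, dh, rl, cs, d`.
#' @export
buildScoreVectors <- function(dsets, detectors, calibration = NULL,
                              params = codingParams()) {
  if (!all(detectorOrder %in% names(detectors)))
    stop("missing detector(s): need ", paste(detectorOrder, collapse = ", "))
  tr <- vapply(detectors[detectorOrder], function(d) paste(d@treatment, collapse = "/"), "")
  if (length(unique(tr)) != 1)
    stop("all six detectors must share the same treatment")
  S <- vapply(detectorOrder, function(lab) {
    vapply(dsets, function(d) scoreDescriptors(detectors[[lab]], d, params), 0)
  }, numeric(length(dsets)))
  S <- matrix(S, ncol = 6, dimnames = list(NULL, tolower(detectorOrder)))
  if (!is.null(calibration)) S <- applyScoreCalibration(calibration, S)
  ids <- vapply(dsets, imageId, "")
  data.frame(imageId = ids, S, stringsAsFactors = FALSE)
}

#' Train the referral meta-classifier
#'
#' An RBF-SVM on the six-component calibrated score vectors, grid-searched
#' exactly like the per-lesion detectors.
#'
#' @param scores numeric matrix `n x 6` of (calibrated) detector scores.
#' @param labels binary referral labels.
#' @param ... passed to [trainDetector()] (grids, folds, seed).
#' @return A [DetectorModel-class] with `lesionLabel = "referral"`.
#' @export
trainMeta <- function(scores, labels, ...) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 6)
    stop("score vectors must have exactly 6 components (HE, SH, DH, RL, CS, D)")
  trainDetector(scores, labels, lesionLabel = "referral", codebook = NULL,
                treatment = c(featureMode = "scores", coding = "none",
                              pooling = "none", norm = "none"), ...)
}

## Stratified half split; each half's positive count within one of half the
## total. Deterministic given seed.
.halfSplit <- function(y, seed) {
  withr::with_seed(as.integer(seed), {
    idx1 <- integer(0)
    for (cl in unique(y)) {
      pool <- which(y == cl)
      pool <- sample(pool)
      idx1 <- c(idx1, pool[seq_len(floor(length(pool) / 2 + runif(1) * (length(pool) %% 2)))])
    }
    idx1
  })
}

#' 5x2-fold cross-validated referral evaluation
#'
#' Five seeded stratified half-splits of the score vectors; for each split
#' the meta-classifier pipeline (score calibration, grid search, RBF-SVM) is
#' trained on one half and its AUC measured on the other, in both directions,
#' yielding 10 fold AUCs. Calibration parameters are always fitted on the
#' training half only.
#'
#' @param scores numeric matrix `n x 6` of raw detector scores.
#' @param labels binary referral labels (need at least 10 per class).
#' @param seed master seed for the five splits.
#' @param calibration `"minmax"`, `"sigmoid"` or `"none"`.
#' @param CGrid,gammaGrid,nFolds grid-search settings for the meta-SVM.
#' @return A [CvResult-class] with 10 fold AUCs.
#' @export
fiveByTwoCv <- function(scores, labels, seed = 1L,
                        calibration = c("minmax", "sigmoid", "none"),
                        CGrid = .defaultCGrid(), gammaGrid = .defaultGammaGrid(),
                        nFolds = 5L) {
  calibration <- match.arg(calibration)
  scores <- as.matrix(scores)
  if (ncol(scores) != 6) stop("score vectors must have exactly 6 components")
  y <- as.integer(as.logical(labels))
  if (min(table(y)) < 10)
    stop("need at least 10 examples per referral class")
  n <- nrow(scores)
  aucs <- numeric(0)
  for (rep in seq_len(5)) {
    splitSeed <- as.integer(seed) * 100L + rep
    for (attempt in seq_len(20)) {
      idx1 <- .halfSplit(y, splitSeed + 1000L * (attempt - 1L))
      idx2 <- setdiff(seq_len(n), idx1)
      if (length(unique(y[idx1])) == 2 && length(unique(y[idx2])) == 2) break
      message("fiveByTwoCv: resampling a split with a missing class")
    }
    for (halves in list(c(1, 2), c(2, 1))) {
      tr <- if (halves[1] == 1) idx1 else idx2
      te <- if (halves[1] == 1) idx2 else idx1
      cal <- fitScoreCalibration(scores[tr, , drop = FALSE], calibration)
      Xtr <- applyScoreCalibration(cal, scores[tr, , drop = FALSE])
      Xte <- applyScoreCalibration(cal, scores[te, , drop = FALSE])
      model <- trainMeta(Xtr, y[tr], CGrid = CGrid, gammaGrid = gammaGrid,
                         nFolds = nFolds, seed = splitSeed)
      sc <- scoreImage(model, Xte)
      aucs <- c(aucs, aucScore(sc, y[te]))
    }
  }
  new("CvResult", foldAucs = aucs, meanAuc = mean(aucs), stdAuc = sd(aucs),
      seed = as.integer(seed))
}
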
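## End-to-end orchestration: sparse features -> class-aware codebooks ->
## per-lesion detectors under several coding/pooling treatments ->
## cross-configuration evaluation and referral fusion.

#' Binary label vector for one lesion
#'
#' Red lesions are a general annotation encompassing superficial and deep
#' hemorrhages besides microaneurysms, so the RL label (and the RL training
#' region set) is the union of the SH, DH and RL annotations; every other
#' lesion maps to its own column.
#'
#' @param labels dataset label data.frame (columns `he, sh, dh, rl, cs, d`).
#' @param lesion lesion label.
#' @return integer 0/1 vector.
#' @export
lesionLabelVector <- function(labels, lesion) {
  if (lesion == "RL")
    as.integer(labels$rl | labels$sh | labels$dh)
  else
    as.integer(labels[[tolower(lesion)]])
}

#' Annotated regions relevant to one lesion in one image
#'
#' @param annotations list of [regionAnnotation()] objects.
#' @param imgId image id.
#' @param lesion lesion label; `"RL"` merges SH, DH and RL regions.
#' @return list of regions.
#' @export
regionsForLesion <- function(annotations, imgId, lesion) {
  labs <- if (lesion == "RL") c("SH", "DH", "RL") else lesion
  Filter(function(a) a$imageId == imgId && a$lesionLabel %in% labs,
         annotations)
}

#' Learn a class-aware codebook for one lesion from a feature batch
#'
#' Partitions every image's descriptors by the lesion's annotated regions,
#' pools the lesion and normal descriptors over the batch and runs the
#' per-class k-means. Descriptors from regions of *other* lesion types fall
#' in the normal pool (anything outside the target lesion's regions is
#' "normal").
#'
#' @param features list of [DescriptorSet-class].
#' @param annotations annotation list for the same images.
#' @param lesion lesion label.
#' @param kHalf half codebook size (default 250 for sparse features).
#' @param seed k-means seed.
#' @param normalCap,lesionCap per-pool subsampling caps before clustering.
#' @param featureMode recorded feature mode.
#' @return A [Codebook-class].
#' @export
buildLesionCodebook <- function(features, annotations, lesion, kHalf = 250L,
                                seed = 1L, normalCap = 20000L,
                                lesionCap = 100000L, featureMode = "sparse") {
  pools <- lapply(features, function(d) {
    partitionDescriptors(d, regionsForLesion(annotations, imageId(d), lesion))
  })
  lesionPool <- do.call(rbind, lapply(pools, `[[`, "lesionPool"))
  normalPool <- do.call(rbind, lapply(pools, `[[`, "normalPool"))
  normalPool <- if (nrow(normalPool) > normalCap)
    normalPool[withr::with_seed(as.integer(seed) + 7L,
                                sample.int(nrow(normalPool), normalCap)), ,
               drop = FALSE] else normalPool
  learnClassAwareCodebook(lesionPool, normalPool, kHalf = kHalf, seed = seed,
                          featureMode = featureMode, lesionLabel = lesion,
                          subsampleCap = lesionCap)
}

#' Encode a feature batch against a codebook
#'
#' @param features list of [DescriptorSet-class].
#' @param cb a [Codebook-class].
#' @param coding,pooling,norm,params treatment (see [encodeImage()]).
#' @return numeric matrix, one image per row.
#' @export
encodeFeatureSet <- function(features, cb, coding, pooling = NULL,
                             norm = "L1", params = codingParams()) {
  t(vapply(features, function(d)
    bovw(encodeImage(d, cb, coding = coding, pooling = pooling, norm = norm,
                     params = params)),
    numeric(nrow(codewords(cb)))))
}

#' Prepare study inputs from a dataset, releasing image memory
#'
#' Extracts sparse features from a dataset and keeps only what the study
#' needs (features, labels, annotations, backend), so the caller can drop
#' the dataset object -- and with it the pixel arrays -- before running the
#' next stage. Useful for keeping large two-configuration studies within a
#' modest memory budget.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param backend tuned `sparseBackend`, or `NULL` to tune on this dataset.
#' @param targetCount sparse keypoint budget per image.
#' @return list with `features`, `labels`, `annotations`, `backend`.
#' @export
prepareStudyInputs <- function(dataset, backend = NULL, targetCount = 400) {
  ex <- extractSparseFeatures(datasetImages(dataset), backend = backend,
                              targetCount = targetCount, keepMasks = FALSE)
  list(features = ex$features, labels = datasetLabels(dataset),
       annotations = datasetAnnotations(dataset), backend = ex$backend)
}

.asStudyInputs <- function(x, backend = NULL, targetCount = 400) {
  if (is.list(x) && !is.null(x$features)) return(x)
  prepareStudyInputs(x, backend = backend, targetCount = targetCount)
}

#' Cross-configuration lesion detection and referral study
#'
#' Runs the full sparse-feature pipeline on two synthetic datasets emulating
#' a cross-dataset protocol: tunes the keypoint backend and learns the
#' class-aware codebooks on the training configuration only, trains one
#' detector per requested lesion and treatment, and measures test AUC on the
#' held-out configuration. Optionally evaluates the referral
#' meta-classification: the six semi-soft/max detectors score every test
#' image and the resulting score vectors are evaluated under 5x2-fold
#' cross-validation.
#'
#' The soft-coding sigma is derived from the training descriptor population
#' (see [sigmaFromDescriptors()]).
#'
#' @param train,test [SyntheticDataset-class] objects, or prepared inputs
#'   from [prepareStudyInputs()] (preferred for large studies: the image
#'   arrays can then be released before the study runs).
#' @param lesions lesions whose per-treatment test AUC is reported.
#' @param treatments list of `c(coding, pooling)` pairs.
#' @param referral evaluate referral fusion with all six detectors.
#' @param targetCount sparse keypoint budget per image.
#' @param kHalf half codebook size.
#' @param normalCap normal-pool descriptor cap for codebook learning.
#' @param seed master seed.
#' @return list with `aucs` (lesion x treatment matrix, percent),
#'   `referral` ([CvResult-class] or `NULL`), `sigma`, `backend`.
#' @export
runCrossDatasetStudy <- function(train, test, lesions = c("HE", "RL"),
                                 treatments = list(c("hard", "sum"),
                                                   c("soft", "max"),
                                                   c("semisoft", "max")),
                                 referral = TRUE, targetCount = 400,
                                 kHalf = 250L, normalCap = 20000L,
                                 seed = 1L) {
  exTr <- .asStudyInputs(train, targetCount = targetCount)
  exTe <- .asStudyInputs(test, backend = exTr$backend,
                         targetCount = targetCount)
  sigma <- sigmaFromDescriptors(exTr$features, seed = seed)
  params <- codingParams(sigma = sigma)
  labTr <- exTr$labels; labTe <- exTe$labels
  annTr <- exTr$annotations

  trNames <- vapply(treatments, function(t) paste(t, collapse = "-"), "")
  aucCols <- seq_along(treatments)
  ## the referral meta-classifier consumes the semi-soft/max detectors
  if (referral && !any(vapply(treatments, function(t) t[1] == "semisoft", TRUE)))
    treatments <- c(treatments, list(c("semisoft", "max")))
  allLesions <- if (referral) detectorOrder else lesions
  books <- lapply(setNames(allLesions, allLesions), function(les)
    buildLesionCodebook(exTr$features, annTr, les, kHalf = kHalf, seed = seed,
                        normalCap = normalCap))

  aucs <- matrix(NA_real_, length(lesions), length(aucCols),
                 dimnames = list(lesions, trNames))
  semisoftDetectors <- list()
  refScores <- matrix(NA_real_, length(exTe$features), 6,
                      dimnames = list(NULL, tolower(detectorOrder)))
  for (les in allLesions) {
    yTr <- lesionLabelVector(labTr, les)
    yTe <- lesionLabelVector(labTe, les)
    cb <- books[[les]]
    for (ti in seq_along(treatments)) {
      tr <- treatments[[ti]]
      isSemisoft <- tr[1] == "semisoft"
      wanted <- les %in% lesions && ti <= length(aucCols)
      if (!wanted && !(referral && isSemisoft)) next
      Xtr <- encodeFeatureSet(exTr$features, cb, coding = tr[1],
                              pooling = tr[2], params = params)
      model <- trainDetector(Xtr, yTr, lesionLabel = les, codebook = cb,
                             treatment = c(featureMode = "sparse",
                                           coding = tr[1], pooling = tr[2],
                                           norm = "L1"),
                             seed = seed)
      needTest <- wanted || (referral && isSemisoft)
      if (needTest) {
        Xte <- encodeFeatureSet(exTe$features, cb, coding = tr[1],
                                pooling = tr[2], params = params)
        sc <- scoreImage(model, Xte)
        if (wanted) aucs[les, ti] <- 100 * aucScore(sc, yTe)
        if (referral && isSemisoft) refScores[, tolower(les)] <- sc
      }
      if (referral && isSemisoft)
        semisoftDetectors[[les]] <- model
    }
  }

  cvRes <- NULL
  if (referral)
    cvRes <- fiveByTwoCv(refScores, labTe$referral, seed = seed)
  list(aucs = aucs, referral = cvRes, sigma = sigma, backend = exTr$backend,
       detectors = semisoftDetectors)
}
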
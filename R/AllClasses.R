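#' @import methods
#' @importFrom stats rnorm runif sd qt quantile median setNames predict
#' @importFrom utils read.csv write.csv head
#' @useDynLib fundusBoVW, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' FundusImage: a colour fundus photograph
#'
#' Holds an RGB retinal photograph as an `H x W x 3` numeric array with
#' integer intensities in 0--255, together with an image identifier and a
#' dataset tag (e.g. the acquisition configuration it came from, which the
#' cross-dataset protocol keys on).
#'
#' Pixel coordinates throughout the package are 0-based with `x` = column and
#' `y` = row, so pixel `(x, y)` is `pixels(img)[y + 1, x + 1, ]`.
#'
#' @slot imageId character scalar identifier.
#' @slot pixels numeric array `H x W x 3`, values in 0--255.
#' @slot datasetTag character scalar, e.g. `"train-config"`.
#' @export
setClass("FundusImage",
  representation(imageId = "character", pixels = "array", datasetTag = "character"))

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be an H x W x 3 array")
  if (d[1] < 64 || d[2] < 64) return("image must be at least 64 x 64")
  if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must be finite and within 0..255")
  if (length(object@imageId) != 1) return("imageId must be a single string")
  TRUE
})

#' Construct a FundusImage
#'
#' @param pixels `H x W x 3` numeric array, intensities 0--255.
#' @param imageId image identifier.
#' @param datasetTag dataset/configuration tag.
#' @return A [FundusImage-class] object.
#' @export
FundusImage <- function(pixels, imageId = "img", datasetTag = "default") {
  ## integer storage halves the memory footprint of image batches
  if (!is.integer(pixels)) {
    pixels <- round(pixels)
    storage.mode(pixels) <- "integer"
  }
  new("FundusImage", imageId = imageId, pixels = pixels, datasetTag = datasetTag)
}

#' FovMask: field-of-view mask of a fundus photograph
#'
#' Boolean `H x W` grid marking pixels inside the circular retinal field of
#' view; features detected outside it are discarded.
#'
#' @slot mask logical matrix, `TRUE` inside the retina disk.
#' @slot insideCount integer, number of `TRUE` cells.
#' @export
setClass("FovMask", representation(mask = "matrix", insideCount = "integer"))

setValidity("FovMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@insideCount != sum(object@mask))
    return("insideCount inconsistent with mask")
  TRUE
})

#' DescriptorSet: local descriptors of one image
#'
#' `N` local descriptors (rows) with their keypoints. Descriptors produced by
#' the package's backend are 128-dimensional and L2-normalised; the class
#' itself permits any dimension so that toy instances can exercise the
#' coding/pooling machinery.
#'
#' @slot descriptors numeric matrix `N x D`.
#' @slot keypoints data.frame with columns `x`, `y`, `radius`, `source`.
#' @slot imageId character scalar.
#' @export
setClass("DescriptorSet",
  representation(descriptors = "matrix", keypoints = "data.frame",
                 imageId = "character"))

setValidity("DescriptorSet", function(object) {
  if (nrow(object@descriptors) != nrow(object@keypoints))
    return("descriptor row count must equal keypoint count")
  if (nrow(object@descriptors) > 0 && !all(is.finite(object@descriptors)))
    return("descriptors must be finite")
  kc <- c("x", "y", "radius", "source")
  if (!all(kc %in% names(object@keypoints)))
    return("keypoints need columns x, y, radius, source")
  TRUE
})

#' Construct a DescriptorSet
#' @param descriptors numeric matrix `N x D`.
#' @param keypoints keypoint data.frame (columns `x`, `y`, `radius`, `source`).
#' @param imageId image identifier.
#' @return A [DescriptorSet-class].
#' @export
DescriptorSet <- function(descriptors, keypoints, imageId = "img") {
  new("DescriptorSet", descriptors = descriptors,
      keypoints = as.data.frame(keypoints), imageId = imageId)
}

#' Codebook: visual dictionary with per-codeword class provenance
#'
#' Rows are codewords \eqn{c_m} in descriptor space. A class-aware codebook
#' (the default product of [learnClassAwareCodebook()]) concatenates `kHalf`
#' centroids learned from lesion-region descriptors followed by `kHalf`
#' centroids learned from normal-region descriptors; `provenance` records the
#' half each row came from.
#'
#' @slot codewords numeric matrix `M x D`.
#' @slot halfSize integer `k`, half the codebook size for class-aware books.
#' @slot provenance character vector, `"lesion"` or `"normal"` per row.
#' @slot featureMode `"sparse"` or `"dense"`.
#' @slot lesionLabel lesion the book was trained for (`"HE"`, `"SH"`, `"DH"`,
#'   `"RL"`, `"CS"`, `"D"`, or a free label for toy books).
#' @slot seed integer seed used for learning.
#' @slot id identifier binding encoded vectors and detectors to this book.
#' @export
setClass("Codebook",
  representation(codewords = "matrix", halfSize = "integer",
                 provenance = "character", featureMode = "character",
                 lesionLabel = "character", seed = "integer", id = "character"))

setValidity("Codebook", function(object) {
  M <- nrow(object@codewords)
  if (M < 1) return("codebook must contain at least one codeword")
  if (!all(is.finite(object@codewords))) return("codewords must be finite")
  if (length(object@provenance) != M)
    return("provenance length must equal the number of codewords")
  if (!all(object@provenance %in% c("lesion", "normal")))
    return("provenance entries must be 'lesion' or 'normal'")
  if (!object@featureMode %in% c("sparse", "dense"))
    return("featureMode must be 'sparse' or 'dense'")
  TRUE
})

#' Construct a Codebook
#'
#' Low-level constructor; [learnClassAwareCodebook()] is the usual entry
#' point and guarantees the lesion-first concatenation contract.
#'
#' @param codewords numeric matrix `M x D`.
#' @param provenance per-row class provenance; defaults to `"normal"`.
#' @param halfSize half size `k`; defaults to `floor(M/2)`.
#' @param featureMode `"sparse"` or `"dense"`.
#' @param lesionLabel lesion label.
#' @param seed integer seed recorded for provenance.
#' @param id identifier; autogenerated when `NULL`.
#' @return A [Codebook-class].
#' @export
Codebook <- function(codewords, provenance = NULL, halfSize = NULL,
                     featureMode = "sparse", lesionLabel = "toy",
                     seed = 0L, id = NULL) {
  codewords <- as.matrix(codewords)
  M <- nrow(codewords)
  if (is.null(provenance)) provenance <- rep("normal", M)
  if (is.null(halfSize)) halfSize <- M %/% 2L
  if (is.null(id)) {
    chk <- sum(abs(codewords) * seq_along(codewords)) %% 1e9
    id <- sprintf("%s-%s-k%d-s%d-%.0f", lesionLabel, featureMode,
                  as.integer(halfSize), as.integer(seed), chk)
  }
  new("Codebook", codewords = codewords, halfSize = as.integer(halfSize),
      provenance = provenance, featureMode = featureMode,
      lesionLabel = lesionLabel, seed = as.integer(seed), id = id)
}

setClassUnion("CodebookOrNULL", c("Codebook", "NULL"))

#' BoVWVector: pooled, normalised mid-level image representation
#'
#' The length-`M` image vector `z` obtained by coding every local descriptor
#' against a codebook and pooling the codes, together with the treatment
#' (coding scheme, pooling, normalisation) and the codebook it binds to.
#'
#' @slot z numeric vector of length `M`.
#' @slot codebookRef id of the codebook used.
#' @slot coding `"hard"`, `"soft"` or `"semisoft"`.
#' @slot pooling `"sum"` or `"max"`.
#' @slot norm `"L1"`, `"L2"` or `"none"`.
#' @export
setClass("BoVWVector",
  representation(z = "numeric", codebookRef = "character", coding = "character",
                 pooling = "character", norm = "character"))

setValidity("BoVWVector", function(object) {
  if (!all(is.finite(object@z))) return("z must be finite")
  if (!object@coding %in% c("hard", "soft", "semisoft")) return("bad coding")
  if (!object@pooling %in% c("sum", "max")) return("bad pooling")
  if (!object@norm %in% c("L1", "L2", "none")) return("bad norm")
  if (object@norm == "L1" && abs(sum(object@z) - 1) > 1e-9)
    return("L1-normalised vector must sum to 1")
  if (object@norm == "L2" && abs(sqrt(sum(object@z^2)) - 1) > 1e-9)
    return("L2-normalised vector must have unit length")
  TRUE
})

#' DetectorModel: per-lesion maximum-margin classifier
#'
#' An RBF-kernel SVM trained on BoVW vectors, bound to the codebook and
#' treatment its inputs were produced with; scoring with a vector built under
#' any other codebook or treatment is an error. The meta-classifier used for
#' the referral decision is the same class with `codebook = NULL` and
#' treatment `"scores"`.
#'
#' @slot lesionLabel lesion this detector targets (or `"referral"`).
#' @slot codebook the bound [Codebook-class], or `NULL` for the meta-model.
#' @slot treatment named character vector: featureMode, coding, pooling, norm.
#' @slot cost,gamma selected SVM hyper-parameters (cost is the SVM C).
#' @slot svm fitted `e1071::svm` object.
#' @slot center,scale per-feature standardisation fitted on the training
#'   set (the scaling step of the standard grid-search recipe) and applied
#'   to every vector before kernel evaluation.
#' @slot seed integer seed used for fold assignment in the grid search.
#' @export
setClass("DetectorModel",
  representation(lesionLabel = "character", codebook = "CodebookOrNULL",
                 treatment = "character", cost = "numeric", gamma = "numeric",
                 svm = "ANY", center = "numeric", scale = "numeric",
                 seed = "integer"))

#' RocCurve: receiver operating characteristic curve
#'
#' @slot thresholds decision thresholds swept over the distinct scores.
#' @slot sensitivity,specificity operating points per threshold.
#' @slot auc trapezoidal area under the (1-specificity, sensitivity) curve;
#'   equals the tie-corrected Mann-Whitney statistic.
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  n <- length(object@thresholds)
  if (length(object@sensitivity) != n || length(object@specificity) != n)
    return("thresholds, sensitivity, specificity must have equal length")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' AucTable: lesion-dataset x treatment AUC matrix
#'
#' Rows are lesion--dataset combinations, columns the six treatments
#' (sparse/dense crossed with hard/semi-soft/soft coding). Raw entries are
#' AUCs in percent; after [standardizeAucTable()] each row is centred and
#' scaled to unit sample standard deviation so treatments can be compared
#' across lesions of very different difficulty.
#'
#' @slot values numeric matrix with 6 columns.
#' @slot standardized logical; `TRUE` after row standardisation.
#' @export
setClass("AucTable",
  representation(values = "matrix", standardized = "logical"))

setValidity("AucTable", function(object) {
  if (ncol(object@values) != 6) return("an AucTable has exactly 6 treatment columns")
  if (!all(is.finite(object@values))) return("entries must be finite")
  if (!object@standardized &&
      (min(object@values) < 0 || max(object@values) > 100))
    return("raw AUC entries must lie in [0, 100] (percent)")
  TRUE
})

#' Construct an AucTable
#' @param values numeric matrix (rows = lesion-dataset, 6 treatment columns).
#' @param standardized whether the entries are already row-standardised.
#' @return An [AucTable-class].
#' @export
AucTable <- function(values, standardized = FALSE) {
  new("AucTable", values = as.matrix(values), standardized = standardized)
}

#' CvResult: 5x2-fold cross-validation summary
#'
#' @slot foldAucs the 10 test AUCs (5 repetitions x 2 fold directions).
#' @slot meanAuc,stdAuc mean and sample standard deviation of `foldAucs`.
#' @slot seed integer seed that generated the splits.
#' @export
setClass("CvResult",
  representation(foldAucs = "numeric", meanAuc = "numeric", stdAuc = "numeric",
                 seed = "integer"))

setValidity("CvResult", function(object) {
  if (length(object@foldAucs) != 10) return("a 5x2cv result has 10 fold AUCs")
  if (any(object@foldAucs < 0 | object@foldAucs > 1)) return("AUCs must lie in [0,1]")
  if (abs(object@meanAuc - mean(object@foldAucs)) > 1e-9) return("meanAuc inconsistent")
  if (abs(object@stdAuc - sd(object@foldAucs)) > 1e-9) return("stdAuc inconsistent")
  TRUE
})

#' FundusConfig: parameters of the synthetic fundus generator
#'
#' @slot width,height image size in pixels.
#' @slot fovRadiusFraction radius of the circular field of view as a fraction
#'   of `min(width, height)`.
#' @slot illuminationGain multiplicative gain of the background illumination
#'   field (emulates acquisition differences between datasets).
#' @slot noiseStd standard deviation of the additive Gaussian pixel noise on
#'   the 0--1 intensity scale.
#' @slot vesselCount number of vessel-like curvilinear structures.
#' @slot lesionMix named per-label planting probabilities
#'   (HE, SH, DH, RL, CS, D).
#' @slot regionsPerPositive integer range (length 2) of annotated regions per
#'   planted lesion label.
#' @slot seed integer master seed.
#' @export
setClass("FundusConfig",
  representation(width = "integer", height = "integer",
                 fovRadiusFraction = "numeric", illuminationGain = "numeric",
                 noiseStd = "numeric", vesselCount = "integer",
                 lesionMix = "numeric", regionsPerPositive = "integer",
                 seed = "integer"))

setValidity("FundusConfig", function(object) {
  if (any(object@lesionMix < 0 | object@lesionMix > 1))
    return("lesionMix probabilities must lie in [0, 1]")
  if (!identical(names(object@lesionMix), c("HE", "SH", "DH", "RL", "CS", "D")))
    return("lesionMix must be named HE, SH, DH, RL, CS, D in that order")
  r <- object@regionsPerPositive
  if (length(r) != 2 || r[1] < 1 || r[2] > 10 || r[1] > r[2])
    return("regionsPerPositive must be a range within 1..10")
  TRUE
})

#' SyntheticDataset: generated images, annotations and labels
#'
#' @slot images list of [FundusImage-class].
#' @slot annotations list of region annotations (see [regionAnnotation()]).
#' @slot labels data.frame with columns `imageId`, `he`, `sh`, `dh`, `rl`,
#'   `cs`, `d`, `referral` (binary); referral is the OR over planted labels.
#' @slot config the [FundusConfig-class] that produced the dataset.
#' @export
setClass("SyntheticDataset",
  representation(images = "list", annotations = "list", labels = "data.frame",
                 config = "FundusConfig"))

setValidity("SyntheticDataset", function(object) {
  lc <- c("imageId", "he", "sh", "dh", "rl", "cs", "d", "referral")
  if (!all(lc %in% names(object@labels))) return("labels missing columns")
  if (nrow(object@labels) != length(object@images))
    return("one label row per image required")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s' [%s]: %d x %d, 3 channels\n",
              object@imageId, object@datasetTag, d[2], d[1]))
})

setMethod("show", "FovMask", function(object) {
  cat(sprintf("FovMask: %d x %d, %d px inside (%.1f%%)\n",
              ncol(object@mask), nrow(object@mask), object@insideCount,
              100 * object@insideCount / length(object@mask)))
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet '%s': %d descriptors x %d dims (%s)\n",
              object@imageId, nrow(object@descriptors), ncol(object@descriptors),
              paste(unique(object@keypoints$source), collapse = "+")))
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook '%s': %d codewords x %d dims (%d lesion + %d normal), %s features\n",
              object@id, nrow(object@codewords), ncol(object@codewords),
              sum(object@provenance == "lesion"),
              sum(object@provenance == "normal"), object@featureMode))
})

setMethod("show", "BoVWVector", function(object) {
  cat(sprintf("BoVWVector: M = %d, %s coding, %s pooling, %s norm [codebook %s]\n",
              length(object@z), object@coding, object@pooling, object@norm,
              object@codebookRef))
})

setMethod("show", "DetectorModel", function(object) {
  cat(sprintf("DetectorModel '%s': RBF-SVM (C = %.4g, gamma = %.4g), treatment %s\n",
              object@lesionLabel, object@cost, object@gamma,
              paste(object@treatment, collapse = "/")))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d operating points, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

setMethod("show", "AucTable", function(object) {
  cat(sprintf("AucTable (%s): %d lesion-dataset rows x 6 treatments\n",
              if (object@standardized) "standardized" else "raw AUC %",
              nrow(object@values)))
  print(round(object@values, 3))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("5x2cv: mean AUC = %.3f +/- %.3f (10 folds, seed %d)\n",
              object@meanAuc, object@stdAuc, object@seed))
})

setMethod("show", "FundusConfig", function(object) {
  cat(sprintf("FundusConfig: %d x %d, gain %.2f, noise %.3f, %d vessels, seed %d\n",
              object@width, object@height, object@illuminationGain,
              object@noiseStd, object@vesselCount, object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d images (%d referable), %d annotated regions\n",
              length(object@images), sum(object@labels$referral),
              length(object@annotations)))
})
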
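#' Accessors for the core containers
#'
#' Small accessor generics so that slots are never reached into directly:
#' `imageId()`, `pixels()`, `fovMask()`, `insideCount()`, `descriptors()`,
#' `keypoints()`, `codewords()`, `provenance()`, `halfSize()`, `codebookId()`,
#' `bovw()`, `auc()`, `foldAucs()`, `aucValues()`, `datasetLabels()`,
#' `datasetImages()`, `datasetAnnotations()`.
#'
#' @param object an object of the matching class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("fovMask", function(object) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setGeneric("insideCount", function(object) standardGeneric("insideCount"))
#' @rdname accessors
#' @export
setGeneric("descriptors", function(object) standardGeneric("descriptors"))
#' @rdname accessors
#' @export
setGeneric("keypoints", function(object) standardGeneric("keypoints"))
#' @rdname accessors
#' @export
setGeneric("codewords", function(object) standardGeneric("codewords"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("halfSize", function(object) standardGeneric("halfSize"))
#' @rdname accessors
#' @export
setGeneric("codebookId", function(object) standardGeneric("codebookId"))
#' @rdname accessors
#' @export
setGeneric("bovw", function(object) standardGeneric("bovw"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("foldAucs", function(object) standardGeneric("foldAucs"))
#' @rdname accessors
#' @export
setGeneric("aucValues", function(object) standardGeneric("aucValues"))
#' @rdname accessors
#' @export
setGeneric("datasetLabels", function(object) standardGeneric("datasetLabels"))
#' @rdname accessors
#' @export
setGeneric("datasetImages", function(object) standardGeneric("datasetImages"))
#' @rdname accessors
#' @export
setGeneric("datasetAnnotations", function(object) standardGeneric("datasetAnnotations"))

#' @rdname accessors
setMethod("imageId", "FundusImage", function(object) object@imageId)
#' @rdname accessors
setMethod("imageId", "DescriptorSet", function(object) object@imageId)
#' @rdname accessors
setMethod("pixels", "FundusImage", function(object) object@pixels)
#' @rdname accessors
setMethod("fovMask", "FovMask", function(object) object@mask)
#' @rdname accessors
setMethod("insideCount", "FovMask", function(object) object@insideCount)
#' @rdname accessors
setMethod("descriptors", "DescriptorSet", function(object) object@descriptors)
#' @rdname accessors
setMethod("keypoints", "DescriptorSet", function(object) object@keypoints)
#' @rdname accessors
setMethod("codewords", "Codebook", function(object) object@codewords)
#' @rdname accessors
setMethod("provenance", "Codebook", function(object) object@provenance)
#' @rdname accessors
setMethod("halfSize", "Codebook", function(object) object@halfSize)
#' @rdname accessors
setMethod("codebookId", "Codebook", function(object) object@id)
#' @rdname accessors
setMethod("codebookId", "BoVWVector", function(object) object@codebookRef)
#' @rdname accessors
setMethod("bovw", "BoVWVector", function(object) object@z)
#' @rdname accessors
setMethod("auc", "RocCurve", function(object) object@auc)
#' @rdname accessors
setMethod("auc", "CvResult", function(object) object@meanAuc)
#' @rdname accessors
setMethod("foldAucs", "CvResult", function(object) object@foldAucs)
#' @rdname accessors
setMethod("aucValues", "AucTable", function(object) object@values)
#' @rdname accessors
setMethod("datasetLabels", "SyntheticDataset", function(object) object@labels)
#' @rdname accessors
setMethod("datasetImages", "SyntheticDataset", function(object) object@images)
#' @rdname accessors
setMethod("datasetAnnotations", "SyntheticDataset", function(object) object@annotations)

#' Grayscale intensity matrix of a fundus image
#'
#' Channel mean rescaled to `[0, 1]`; the intensity the FOV threshold and the
#' sparse detector operate on.
#'
#' @param object a [FundusImage-class].
#' @return `H x W` numeric matrix in `[0, 1]`.
#' @export
setGeneric("grayMatrix", function(object) standardGeneric("grayMatrix"))

#' @rdname grayMatrix
setMethod("grayMatrix", "FundusImage", function(object) {
  (object@pixels[, , 1] + object@pixels[, , 2] + object@pixels[, , 3]) / (3 * 255)
})
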
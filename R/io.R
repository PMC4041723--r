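#' Read and write fundus images
#'
#' Thin wrappers over EBImage's readers/writers (PNG, JPEG, TIFF). Pixels are
#' converted between EBImage's `[0, 1]` x-major layout and the package's
#' `H x W x 3` 0--255 arrays.
#'
#' @param path image file path.
#' @param imageId identifier for the created object (default: file name).
#' @param datasetTag dataset tag.
#' @return `readFundusImage` returns a [FundusImage-class].
#' @export
readFundusImage <- function(path, imageId = basename(path),
                            datasetTag = "default") {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  px <- round(255 * aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)))
  FundusImage(px, imageId = imageId, datasetTag = datasetTag)
}

#' @rdname readFundusImage
#' @param image a [FundusImage-class].
#' @export
writeFundusImage <- function(image, path) {
  a <- aperm(pixels(image) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Read and write keypoints as CSV
#'
#' @param keypoints keypoint data.frame.
#' @param path CSV path.
#' @return `readKeypointsCsv` returns the keypoint data.frame.
#' @export
writeKeypointsCsv <- function(keypoints, path) {
  write.csv(keypoints, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKeypointsCsv
#' @export
readKeypointsCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Read and write descriptor sets (CSV matrix + JSON sidecar)
#'
#' The descriptor matrix is written as a headerless CSV; keypoints go to
#' `<path>.keypoints.csv`; the JSON sidecar records the image id and the
#' backend identifier so the provenance of serialized features is explicit.
#'
#' @param dset a [DescriptorSet-class].
#' @param path CSV path for the descriptor matrix.
#' @param backendId backend identifier recorded in the sidecar.
#' @return `readDescriptors` returns a [DescriptorSet-class].
#' @export
writeDescriptors <- function(dset, path, backendId = "doh-surf128-v1") {
  write.table(descriptors(dset), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  writeKeypointsCsv(keypoints(dset), paste0(path, ".keypoints.csv"))
  jsonlite::write_json(list(imageId = imageId(dset), backend = backendId,
                            n = nrow(descriptors(dset)), dim = ncol(descriptors(dset))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDescriptors
#' @export
readDescriptors <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  kp <- readKeypointsCsv(paste0(path, ".keypoints.csv"))
  X <- if (meta$n == 0) matrix(0, 0, meta$dim) else {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    m
  }
  DescriptorSet(X, kp, imageId = meta$imageId)
}
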
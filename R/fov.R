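#' Compute the field-of-view mask of a fundus photograph
#'
#' Fundus photographs show the retina as a bright disk on a dark surround.
#' The mask is obtained by thresholding the grayscale intensity (channel mean
#' scaled to `[0, 1]`), closing small gaps with a morphological closing
#' (disk-shaped brush), and keeping the largest connected component so that
#' isolated bright specks outside the retina are excluded. Keypoints falling
#' outside the mask are discarded by the feature-extraction steps.
#'
#' @param image a [FundusImage-class].
#' @param thresholdFraction gray-intensity threshold in `(0, 1)`; pixels
#'   strictly above it are candidate foreground. Default 0.08, low enough to
#'   keep the dimly lit retinal periphery while rejecting the dark surround.
#' @param brushSize diameter in pixels of the closing brush (odd integer).
#' @return A [FovMask-class].
#' @examples
#' cfg <- fundusConfigA(seed = 1)
#' img <- generateFundusImage(cfg, seed = 1)$image
#' computeFovMask(img)
#' @export
computeFovMask <- function(image, thresholdFraction = 0.08, brushSize = 5L) {
  stopifnot(is(image, "FundusImage"),
            thresholdFraction > 0, thresholdFraction < 1)
  .fovMaskFromGray(grayMatrix(image), thresholdFraction, brushSize)
}

.fovMaskFromGray <- function(g, thresholdFraction, brushSize = 5L) {
  stopifnot(thresholdFraction > 0, thresholdFraction < 1)
  fg <- g > thresholdFraction
  if (!any(fg))
    stop("empty FOV: no pixel exceeds the threshold (all-background image)")
  ## EBImage works x-major: transpose in, transpose out
  fgx <- EBImage::Image(t(fg) * 1)
  closed <- EBImage::closing(fgx, EBImage::makeBrush(as.integer(brushSize), "disc"))
  lab <- EBImage::bwlabel(closed)
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  mask <- labm == keep
  new("FovMask", mask = mask, insideCount = as.integer(sum(mask)))
}

#' Test whether keypoints lie inside a FOV mask
#'
#' @param mask a [FovMask-class].
#' @param x,y 0-based pixel coordinates (x = column, y = row).
#' @return Logical vector.
#' @export
insideFov <- function(mask, x, y) {
  m <- fovMask(mask)
  xi <- round(x) + 1L; yi <- round(y) + 1L
  ok <- xi >= 1L & xi <= ncol(m) & yi >= 1L & yi <= nrow(m)
  res <- logical(length(x))
  res[ok] <- m[cbind(yi[ok], xi[ok])]
  res
}
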
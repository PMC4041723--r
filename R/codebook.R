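#' Region annotation of a lesion
#'
#' Lesion-region annotations mark where a specialist outlined a lesion.
#' Shapes are circles (`cx`, `cy`, `r`, pixels, 0-based coordinates) or
#' polygons (vertex vectors `px`, `py`); membership of a keypoint is judged
#' by its centre only (circle: Euclidean distance at most the radius;
#' polygon: even-odd rule).
#'
#' @param imageId image the region belongs to.
#' @param lesionLabel one of `"HE"`, `"SH"`, `"DH"`, `"RL"`, `"CS"`, `"D"`.
#' @param shape list: `list(type = "circle", cx, cy, r)` or
#'   `list(type = "polygon", px, py)`.
#' @return A `regionAnnotation` object (list).
#' @export
regionAnnotation <- function(imageId, lesionLabel, shape) {
  stopifnot(lesionLabel %in% c("HE", "SH", "DH", "RL", "CS", "D"),
            shape$type %in% c("circle", "polygon"))
  if (shape$type == "circle") stopifnot(shape$r > 0)
  if (shape$type == "polygon") stopifnot(length(shape$px) >= 3,
                                         length(shape$px) == length(shape$py))
  structure(list(imageId = imageId, lesionLabel = lesionLabel, shape = shape),
            class = "regionAnnotation")
}

## even-odd rule point-in-polygon
.inPolygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.inRegion <- function(region, x, y) {
  s <- region$shape
  if (s$type == "circle") (x - s$cx)^2 + (y - s$cy)^2 <= s$r^2
  else .inPolygon(x, y, s$px, s$py)
}

#' Partition descriptors into lesion and normal pools
#'
#' A descriptor joins the lesion pool iff its keypoint centre falls inside at
#' least one annotated region; all others are normal. The two pools are
#' disjoint and together contain every descriptor.
#'
#' @param dset a [DescriptorSet-class].
#' @param regions list of [regionAnnotation()] objects for this image (empty
#'   for healthy images). Regions with a different `imageId` are an error.
#' @return list with matrices `lesionPool` and `normalPool`.
#' @export
partitionDescriptors <- function(dset, regions = list()) {
  stopifnot(is(dset, "DescriptorSet"))
  X <- descriptors(dset)
  kp <- keypoints(dset)
  if (length(regions)) {
    ids <- vapply(regions, `[[`, "", "imageId")
    if (!all(ids == imageId(dset)))
      stop("regions do not belong to image '", imageId(dset), "'")
  }
  inLesion <- rep(FALSE, nrow(X))
  for (rg in regions)
    inLesion <- inLesion | .inRegion(rg, kp$x, kp$y)
  list(lesionPool = X[inLesion, , drop = FALSE],
       normalPool = X[!inLesion, , drop = FALSE])
}

## ---- seeded k-means (k-means++ init, Lloyd iterations) ------------------

.squaredDist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

.kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  x2 <- rowSums(X^2)
  d2to <- function(ci) {
    cv <- X[ci, ]
    pmax(x2 + sum(cv^2) - 2 * drop(X %*% cv), 0)
  }
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  minD2 <- d2to(centers[1])
  for (i in seq_len(k - 1)) {
    if (!all(is.finite(minD2)) || sum(minD2) == 0)
      centers[i + 1] <- sample.int(n, 1)
    else
      centers[i + 1] <- sample.int(n, 1, prob = minD2 / sum(minD2))
    minD2 <- pmin(minD2, d2to(centers[i + 1]))
  }
  X[centers, , drop = FALSE]
}

## Lloyd iterations with k-means++ init; empty clusters are reseeded to the
## point farthest from its assigned centre. Converges when the largest
## relative centroid shift drops below tol. Returns centers, assignments and
## the within-cluster sum-of-squares trace.
.kmeansLloyd <- function(X, k, maxIter = 200L, tol = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Xt <- t(X)
  withr::with_seed(as.integer(seed), {
    C <- .kmeansPlusPlusInit(X, k)
    trace <- numeric(0)
    step <- NULL
    for (it in seq_len(maxIter)) {
      step <- cppKmeansStep(Xt, t(C))
      trace <- c(trace, step$wss)
      counts <- as.numeric(step$counts)
      Cnew <- C
      got <- counts > 0
      Cnew[got, ] <- t(step$sums)[got, , drop = FALSE] / counts[got]
      empty <- which(!got)
      if (length(empty)) {
        far <- order(step$dmin2, decreasing = TRUE)
        Cnew[empty, ] <- X[far[seq_along(empty)], , drop = FALSE]
      }
      shift <- sqrt(rowSums((Cnew - C)^2)) / (sqrt(rowSums(C^2)) + 1e-12)
      C <- Cnew
      if (max(shift) < tol) break
    }
    step <- cppKmeansStep(Xt, t(C))
    list(centers = C, cluster = as.integer(step$assign), wssTrace = trace,
         iterations = length(trace))
  })
}

#' Learn a class-aware codebook by per-class k-means
#'
#' Two independent k-means clusterings (Euclidean distance, k-means++
#' initialisation, Lloyd iterations for at most `maxIter` rounds or until the
#' relative centroid shift falls below `1e-4`) are run on the lesion and
#' normal descriptor pools, each with `kHalf` centroids, and the centroid
#' sets are concatenated lesion-first into a codebook of `2 * kHalf`
#' codewords. Empty clusters are reseeded to the farthest point. The whole
#' procedure is deterministic given `seed`.
#'
#' Defaults follow the standard settings of the framework: `kHalf = 250` for
#' sparse features and `750` for dense features (pass `kHalf` explicitly to
#' override). Pools larger than `subsampleCap` rows are subsampled with the
#' same seed before clustering.
#'
#' @param lesionPool,normalPool descriptor matrices (rows = descriptors).
#' @param kHalf half codebook size; default depends on `featureMode`.
#' @param maxIter maximum Lloyd rounds (default 200).
#' @param seed integer seed (k-means++ sampling and subsampling).
#' @param featureMode `"sparse"` or `"dense"`.
#' @param lesionLabel lesion label recorded in the codebook.
#' @param subsampleCap per-pool descriptor cap before clustering.
#' @return A [Codebook-class] with `2 * kHalf` rows, lesion rows first.
#' @export
learnClassAwareCodebook <- function(lesionPool, normalPool, kHalf = NULL,
                                    maxIter = 200L, seed = 1L,
                                    featureMode = c("sparse", "dense"),
                                    lesionLabel = "HE",
                                    subsampleCap = 100000L) {
  featureMode <- match.arg(featureMode)
  if (is.null(kHalf)) kHalf <- if (featureMode == "sparse") 250L else 750L
  kHalf <- as.integer(kHalf)
  lesionPool <- as.matrix(lesionPool); normalPool <- as.matrix(normalPool)
  if (nrow(lesionPool) < kHalf)
    stop(sprintf("insufficient descriptors in lesion pool (%d < kHalf = %d)",
                 nrow(lesionPool), kHalf))
  if (nrow(normalPool) < kHalf)
    stop(sprintf("insufficient descriptors in normal pool (%d < kHalf = %d)",
                 nrow(normalPool), kHalf))
  cap <- function(X, s) {
    if (nrow(X) > subsampleCap)
      X[withr::with_seed(s, sample.int(nrow(X), subsampleCap)), , drop = FALSE]
    else X
  }
  lesionPool <- cap(lesionPool, as.integer(seed))
  normalPool <- cap(normalPool, as.integer(seed) + 1L)
  kmL <- .kmeansLloyd(lesionPool, kHalf, maxIter = maxIter, seed = as.integer(seed))
  kmN <- .kmeansLloyd(normalPool, kHalf, maxIter = maxIter, seed = as.integer(seed) + 1L)
  cw <- rbind(kmL$centers, kmN$centers)
  cb <- Codebook(cw,
                 provenance = rep(c("lesion", "normal"), each = kHalf),
                 halfSize = kHalf, featureMode = featureMode,
                 lesionLabel = lesionLabel, seed = as.integer(seed))
  ## convergence traces ride along as external attributes (not serialized)
  attr(cb, "wssTraceLesion") <- kmL$wssTrace
  attr(cb, "wssTraceNormal") <- kmN$wssTrace
  cb
}

## ---- serialization ------------------------------------------------------

#' Read and write codebooks as CSV + JSON sidecar
#'
#' The codeword matrix is written as a headerless CSV (one codeword per row);
#' the sidecar `<path>.json` records half size, seed, feature mode, lesion
#' label, per-row provenance and the codebook id, so a round trip preserves
#' the lesion-first concatenation contract exactly.
#'
#' @param codebook a [Codebook-class].
#' @param path CSV file path (sidecar gets `.json` appended).
#' @return `readCodebook` returns the reconstructed [Codebook-class].
#' @export
writeCodebook <- function(codebook, path) {
  write.table(codewords(codebook), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  meta <- list(kHalf = halfSize(codebook), seed = codebook@seed,
               featureMode = codebook@featureMode,
               lesionLabel = codebook@lesionLabel,
               provenance = provenance(codebook), id = codebookId(codebook))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  cw <- as.matrix(read.csv(path, header = FALSE))
  dimnames(cw) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("Codebook", codewords = cw, halfSize = as.integer(meta$kHalf),
      provenance = meta$provenance, featureMode = meta$featureMode,
      lesionLabel = meta$lesionLabel, seed = as.integer(meta$seed),
      id = meta$id)
}

#' Read and write region annotations as JSON lines
#'
#' One JSON object per line: `{"imageId": ..., "lesionLabel": ...,
#' "shape": {"type": ...}}`.
#'
#' @param annotations list of [regionAnnotation()] objects.
#' @param path file path.
#' @return `readRegionAnnotations` returns a list of annotations.
#' @export
writeRegionAnnotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    jsonlite::toJSON(list(imageId = a$imageId, lesionLabel = a$lesionLabel,
                          shape = a$shape), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRegionAnnotations
#' @export
readRegionAnnotations <- function(path) {
  lapply(readLines(path), function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    sh <- as.list(o$shape)
    regionAnnotation(o$imageId, o$lesionLabel, sh)
  })
}
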
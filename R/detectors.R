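## Per-lesion maximum-margin classification: RBF-SVM with cross-validated
## grid search over the usual exponential (C, gamma) grid, model selection by
## mean stratified-fold AUC.

.defaultCGrid <- function() 2^seq(-5, 15, by = 2)
.defaultGammaGrid <- function() 2^seq(-15, 3, by = 2)

## Stratified fold assignment, deterministic given seed.
.stratifiedFolds <- function(y, nFolds, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
  })
  folds
}

## Decision scores oriented so that larger = more positive ("pos" class).
.svmScores <- function(fit, X) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  nm <- strsplit(colnames(dv)[1], "/")[[1]]
  if (nm[1] == "pos") dv[, 1] else -dv[, 1]
}

.asLabelFactor <- function(labels) {
  y <- as.integer(as.logical(labels))
  factor(ifelse(y == 1, "pos", "neg"), levels = c("pos", "neg"))
}

## Per-feature standardisation fitted on the training matrix (the scaling
## step of the standard libsvm grid-search recipe); zero-variance columns
## are centred but left unscaled.
.fitFeatureScaling <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < 1e-12] <- 1
  list(center = mu, scale = sdev)
}

.applyFeatureScaling <- function(X, sc) {
  sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
}

#' Cross-validated grid search for RBF-SVM hyper-parameters
#'
#' Evaluates every `(C, gamma)` cell of an exponential grid by stratified
#' `nFolds`-fold cross-validation and returns the pair maximising the mean
#' fold AUC. Ties are broken towards the smallest `C`, then the smallest
#' `gamma`. Following the standard grid-search recipe, features are
#' standardised (training-set column mean/sd) before the search so the
#' exponential gamma grid matches the data scale.
#'
#' @param X numeric matrix of BoVW vectors (one image per row).
#' @param labels binary labels (1 = lesion present).
#' @param CGrid,gammaGrid hyper-parameter grids.
#' @param nFolds number of stratified folds.
#' @param seed fold-assignment seed.
#' @return list with `C`, `gamma` and the grid of mean fold AUCs.
#' @export
gridSearchSvm <- function(X, labels, CGrid = .defaultCGrid(),
                          gammaGrid = .defaultGammaGrid(), nFolds = 5L,
                          seed = 1L) {
  X <- as.matrix(X)
  y <- .asLabelFactor(labels)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (min(table(y)) < 2) stop("need at least 2 examples per class")
  stopifnot(length(CGrid) > 0, length(gammaGrid) > 0)
  nFolds <- min(nFolds, min(table(y)))
  folds <- .stratifiedFolds(y, nFolds, seed)
  X <- .applyFeatureScaling(X, .fitFeatureScaling(X))
  CGrid <- sort(CGrid); gammaGrid <- sort(gammaGrid)
  best <- list(C = CGrid[1], gamma = gammaGrid[1], auc = -Inf)
  aucGrid <- matrix(NA_real_, length(CGrid), length(gammaGrid),
                    dimnames = list(paste0("C=", CGrid),
                                    paste0("g=", gammaGrid)))
  for (ci in seq_along(CGrid)) {
    for (gi in seq_along(gammaGrid)) {
      aucs <- vapply(seq_len(nFolds), function(f) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2) return(NA_real_)
        ## loose solver tolerance: model *selection* is insensitive to the
        ## final digits of the dual solution, and CV dominates runtime
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = CGrid[ci], gamma = gammaGrid[gi],
                          tolerance = 0.05, scale = FALSE)
        sc <- .svmScores(fit, X[!tr, , drop = FALSE])
        aucScore(sc, y[!tr] == "pos")
      }, 0)
      m <- mean(aucs, na.rm = TRUE)
      aucGrid[ci, gi] <- m
      if (m > best$auc + 1e-12) best <- list(C = CGrid[ci], gamma = gammaGrid[gi], auc = m)
    }
  }
  list(C = best$C, gamma = best$gamma, meanAuc = best$auc, aucGrid = aucGrid)
}

.stackBovw <- function(vectors) {
  stopifnot(length(vectors) > 0)
  ref <- codebookId(vectors[[1]])
  treat <- c(coding = vectors[[1]]@coding, pooling = vectors[[1]]@pooling,
             norm = vectors[[1]]@norm)
  for (v in vectors) {
    if (codebookId(v) != ref || v@coding != treat["coding"] ||
        v@pooling != treat["pooling"] || v@norm != treat["norm"])
      stop("all BoVW vectors must share one codebook and treatment")
  }
  list(X = do.call(rbind, lapply(vectors, bovw)), ref = ref, treatment = treat)
}

#' Train a per-lesion RBF-SVM detector
#'
#' Fits a Gaussian-kernel SVM on BoVW vectors at the grid-searched
#' `(C, gamma)`; the returned model binds the codebook and treatment used to
#' produce its training vectors, so scoring a vector produced any other way
#' is rejected. One detector is trained per lesion.
#'
#' @param x list of [BoVWVector-class] (all sharing one codebook/treatment),
#'   or a plain matrix (then `codebook` must be given).
#' @param labels binary labels (1 = lesion present).
#' @param lesionLabel lesion this detector targets.
#' @param codebook the bound [Codebook-class] (required when `x` is a matrix;
#'   inferred otherwise it must match the vectors' reference).
#' @param treatment named character vector (coding, pooling, norm) when `x`
#'   is a matrix.
#' @param CGrid,gammaGrid,nFolds,seed passed to [gridSearchSvm()].
#' @param classWeights optional named class weights (`pos`, `neg`) for
#'   imbalanced training sets; `NULL` (default) applies none.
#' @param solverTolerance libsvm termination tolerance for the final fit
#'   (default the libsvm standard 1e-3; tighten to make scores invariant to
#'   training-example order down to numerical precision).
#' @return A [DetectorModel-class].
#' @export
trainDetector <- function(x, labels, lesionLabel = "HE", codebook = NULL,
                          treatment = NULL, CGrid = .defaultCGrid(),
                          gammaGrid = .defaultGammaGrid(), nFolds = 5L,
                          seed = 1L, classWeights = NULL,
                          solverTolerance = 1e-3) {
  if (is.list(x) && !is.matrix(x)) {
    st <- .stackBovw(x)
    X <- st$X
    treatment <- c(featureMode = if (!is.null(codebook)) codebook@featureMode else "sparse",
                   st$treatment)
    if (!is.null(codebook) && codebookId(codebook) != st$ref)
      stop("supplied codebook does not match the vectors' codebook reference")
  } else {
    X <- as.matrix(x)
    if (is.null(treatment))
      treatment <- c(featureMode = "sparse", coding = "hard", pooling = "sum",
                     norm = "L1")
  }
  y <- .asLabelFactor(labels)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (all(apply(X, 2, function(col) length(unique(col))) == 1))
    stop("degenerate training set: all features constant")
  gs <- gridSearchSvm(X, labels, CGrid = CGrid, gammaGrid = gammaGrid,
                      nFolds = nFolds, seed = seed)
  sc <- .fitFeatureScaling(X)
  fit <- e1071::svm(.applyFeatureScaling(X, sc), y, kernel = "radial",
                    cost = gs$C, gamma = gs$gamma,
                    tolerance = solverTolerance,
                    scale = FALSE, class.weights = classWeights)
  new("DetectorModel", lesionLabel = lesionLabel, codebook = codebook,
      treatment = as.character(treatment), cost = gs$C, gamma = gs$gamma,
      svm = fit, center = sc$center, scale = sc$scale,
      seed = as.integer(seed))
}

#' Score an image's BoVW vector with a trained detector
#'
#' Returns the real-valued SVM margin, monotone in lesion confidence. The
#' vector must have been produced with the detector's own codebook and
#' treatment (the cross-dataset contract: test images are encoded with the
#' training codebook); a mismatch is an error.
#'
#' @param model a [DetectorModel-class].
#' @param v a [BoVWVector-class] (or matrix of raw vectors to score with no
#'   guard, one per row).
#' @return numeric decision score(s).
#' @export
scoreImage <- function(model, v) {
  if (is(v, "BoVWVector")) {
    if (!is.null(model@codebook) && codebookId(v) != codebookId(model@codebook))
      stop("codebook mismatch: vector was not encoded with this detector's codebook")
    tr <- model@treatment
    if (length(tr) == 4 &&
        !all(c(v@coding, v@pooling, v@norm) == tr[2:4]))
      stop("treatment mismatch: vector encoded under a different treatment")
    X <- matrix(bovw(v), nrow = 1)
  } else {
    X <- as.matrix(v)
  }
  X <- .applyFeatureScaling(X, list(center = model@center, scale = model@scale))
  as.numeric(.svmScores(model@svm, X))
}

#' Encode and score an image's descriptors in one step
#'
#' Encodes a [DescriptorSet-class] with the detector's bound codebook and
#' treatment, then scores it.
#'
#' @param model a [DetectorModel-class] with a bound codebook.
#' @param dset a [DescriptorSet-class].
#' @param params [codingParams()].
#' @return numeric decision score.
#' @export
scoreDescriptors <- function(model, dset, params = codingParams()) {
  if (is.null(model@codebook))
    stop("this detector has no bound codebook (meta-classifier?)")
  tr <- model@treatment
  v <- encodeImage(dset, model@codebook, coding = tr[2], pooling = tr[3],
                   norm = tr[4], params = params)
  scoreImage(model, v)
}

#' Save / load a detector model
#'
#' Models are self-contained (codebook + SVM + treatment) and persisted with
#' base R serialisation.
#'
#' @param model a [DetectorModel-class].
#' @param path file path.
#' @return `loadDetector` returns the [DetectorModel-class].
#' @export
saveDetector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) readRDS(path)
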
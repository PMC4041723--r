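#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC by sweeping a decision threshold over all distinct scores
#' (predicted positive when `score >= threshold`) and computes the area under
#' the (1 - specificity, sensitivity) curve by the trapezoid rule. With ties
#' handled by grouping equal scores, the trapezoidal area equals the
#' tie-corrected Mann--Whitney statistic.
#'
#' @param scores numeric decision scores, larger = more lesion-like.
#' @param labels binary labels (logical or 0/1), 1 = positive.
#' @return A [RocCurve-class].
#' @examples
#' auc(rocCurve(c(.9, .8, .1, .2), c(1, 1, 0, 0)))
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(1 - l, grp, sum)
  cumTp <- cumsum(tp); cumFp <- cumsum(fp)
  thresholds <- s[!duplicated(s)]
  sens <- as.numeric(cumTp) / nPos
  fpr <- as.numeric(cumFp) / nNeg
  ## trapezoid over (0,0) .. (1,1)
  xs <- c(0, fpr); ys <- c(0, sens)
  a <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  new("RocCurve", thresholds = as.numeric(thresholds), sensitivity = sens,
      specificity = 1 - fpr, auc = a)
}

#' @rdname rocCurve
#' @export
aucScore <- function(scores, labels) auc(rocCurve(scores, labels))

#' Standardize an AUC table per lesion-dataset row
#'
#' Lesions and datasets vary widely in difficulty, so raw AUCs cannot be
#' compared across rows. For each lesion--dataset row with entries
#' \eqn{\beta_\ell}, the row mean \eqn{\mu_\ell} and sample standard
#' deviation \eqn{\sigma_\ell} over the six treatments are computed and each
#' entry becomes \eqn{(\beta_\ell - \mu_\ell) / \sigma_\ell}. Every output
#' row then has mean 0 and sample standard deviation 1, and the standardized
#' effects of a treatment can be averaged across lesions.
#'
#' @param x an [AucTable-class] or a numeric matrix with 6 treatment columns.
#' @return A standardized [AucTable-class].
#' @export
standardizeAucTable <- function(x) {
  v <- if (is(x, "AucTable")) aucValues(x) else as.matrix(x)
  if (is(x, "AucTable") && x@standardized)
    stop("table is already standardized")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop("constant row (zero spread across treatments): cannot standardize")
  z <- (v - rowMeans(v)) / sds
  AucTable(z, standardized = TRUE)
}

#' Mean standardized effect of a treatment with a 95% confidence interval
#'
#' Column mean of the standardized table across lesion--dataset rows, with a
#' t-based 95% confidence interval. With a single row the CI is undefined
#' (returned as `NA` with a warning).
#'
#' @param x a standardized [AucTable-class] (or matrix).
#' @param treatment column name or index.
#' @return list with `mean`, `ciLow`, `ciHigh`, `n`.
#' @export
treatmentEffectSummary <- function(x, treatment) {
  v <- if (is(x, "AucTable")) aucValues(x) else as.matrix(x)
  col <- v[, treatment]
  n <- length(col)
  m <- mean(col)
  if (n < 2) {
    warning("single row: confidence interval undefined")
    return(list(mean = m, ciLow = NA_real_, ciHigh = NA_real_, n = n))
  }
  half <- qt(0.975, n - 1) * sd(col) / sqrt(n)
  list(mean = m, ciLow = m - half, ciHigh = m + half, n = n)
}

#' Published cross-dataset benchmark AUC table (DR2 test set)
#'
#' The 4 lesions x 6 treatments AUC matrix (percent) from the cross-dataset
#' benchmark in which detectors were trained on the DR1 dataset and tested on
#' DR2: rows HE, RL, CS, D; columns sparse/dense crossed with
#' hard/semi-soft/soft coding. Shipped as a plain-text fixture; used by the
#' standardized-effect analysis.
#'
#' @return An [AucTable-class] (raw, percent scale).
#' @export
dr2BenchmarkAucs <- function() {
  path <- system.file("extdata", "dr2_treatment_aucs.csv",
                      package = "fundusBoVW", mustWork = TRUE)
  readAucTable(path)
}

#' Read and write AUC tables as CSV
#'
#' CSV layout: first column `lesion` (row names), then the six treatment
#' columns.
#'
#' @param x an [AucTable-class].
#' @param path CSV path.
#' @return `readAucTable` returns an [AucTable-class].
#' @export
writeAucTable <- function(x, path) {
  v <- aucValues(x)
  df <- data.frame(lesion = rownames(v), v, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAucTable
#' @param standardized whether the file holds standardized values.
#' @export
readAucTable <- function(path, standardized = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  AucTable(v, standardized = standardized)
}
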
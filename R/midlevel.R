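#' Coding parameters
#'
#' @param sigma Gaussian kernel standard deviation for soft coding (codeword
#'   uncertainty). The default 45 suits raw, un-normalised 128-d descriptor
#'   distances; backends producing L2-normalised descriptors (such as this
#'   package's built-in one, whose pairwise distances live on a 0--2 scale)
#'   should derive a matching value from a population of descriptor
#'   distances, e.g. with [sigmaFromDescriptors()].
#' @param epsilon distance guard for semi-soft coding so a descriptor
#'   coinciding with a codeword yields a finite activation.
#' @return list of coding parameters.
#' @export
codingParams <- function(sigma = 45, epsilon = 1e-12) {
  stopifnot(sigma > 0, epsilon > 0)
  list(sigma = sigma, epsilon = epsilon)
}

.asDescriptorMatrix <- function(x, cb) {
  X <- if (is(x, "DescriptorSet")) descriptors(x) else
    if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(codewords(cb)))
    stop("descriptor dimensionality does not match the codebook")
  X
}

#' Hard assignment coding
#'
#' Activates the single closest codeword with weight one:
#' \eqn{\alpha_m = 1} for \eqn{m = \arg\min_{m'} \|x - c_{m'}\|_2}, zero
#' elsewhere. Ties go to the lowest codeword index.
#'
#' @param x a 128-d descriptor (numeric vector), or a matrix of descriptors
#'   (one per row) for which a code matrix is returned.
#' @param cb a [Codebook-class].
#' @return numeric code vector of length `M` (or `N x M` matrix).
#' @export
codeHard <- function(x, cb) {
  X <- .asDescriptorMatrix(x, cb)
  d2 <- .squaredDist(X, codewords(cb))
  idx <- max.col(-d2, ties.method = "first")
  A <- matrix(0, nrow(X), nrow(codewords(cb)))
  A[cbind(seq_len(nrow(X)), idx)] <- 1
  if (is.matrix(x) || is(x, "DescriptorSet")) A else A[1, ]
}

#' Soft assignment coding (codeword uncertainty)
#'
#' Distributes the activation over all codewords with Gaussian-kernel
#' weights, normalised to sum to one:
#' \deqn{\alpha_m = K_\sigma(\|x - c_m\|) / \sum_{m'} K_\sigma(\|x - c_{m'}\|),}
#' \eqn{K_\sigma(d) = \exp(-d^2 / 2\sigma^2)}. If every kernel value
#' underflows to zero the descriptor falls back to hard assignment (logged
#' with a message).
#'
#' @inheritParams codeHard
#' @param params [codingParams()].
#' @return numeric code vector (or matrix); rows sum to 1.
#' @export
codeSoft <- function(x, cb, params = codingParams()) {
  X <- .asDescriptorMatrix(x, cb)
  d2 <- .squaredDist(X, codewords(cb))
  K <- exp(-d2 / (2 * params$sigma^2))
  s <- rowSums(K)
  dead <- s == 0
  if (any(dead)) {
    message(sprintf("codeSoft: kernel underflow for %d descriptor(s); falling back to hard assignment",
                    sum(dead)))
    idx <- max.col(-d2[dead, , drop = FALSE], ties.method = "first")
    K[dead, ] <- 0
    K[cbind(which(dead), idx)] <- 1
    s[dead] <- 1
  }
  A <- K / s
  if (is.matrix(x) || is(x, "DescriptorSet")) A else A[1, ]
}

#' Semi-soft assignment coding
#'
#' Combines the sparsity of hard assignment with a slow distance decay: only
#' the closest codeword is activated, with activation proportional to the
#' inverse of its distance, \eqn{\alpha_m = 1 / (\|x - c_m\| + \epsilon)} at
#' \eqn{m = \arg\min} and zero elsewhere. Ties go to the lowest index. The
#' codes are maximally sparse yet the influence of a descriptor decays far
#' more slowly with distance than under a Gaussian kernel.
#'
#' @inheritParams codeSoft
#' @return numeric code vector (or matrix) with exactly one nonzero per row.
#' @export
codeSemisoft <- function(x, cb, params = codingParams()) {
  X <- .asDescriptorMatrix(x, cb)
  d2 <- .squaredDist(X, codewords(cb))
  idx <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(X)), idx)])
  A <- matrix(0, nrow(X), nrow(codewords(cb)))
  A[cbind(seq_len(nrow(X)), idx)] <- 1 / (dmin + params$epsilon)
  if (is.matrix(x) || is(x, "DescriptorSet")) A else A[1, ]
}

.poolCheck <- function(codes) {
  if (is.list(codes)) codes <- do.call(rbind, codes)
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1)
  if (nrow(codes) == 0) stop("no descriptors: cannot pool an empty code set")
  codes
}

#' Sum pooling
#'
#' The classical counting of words: \eqn{z_m = \sum_j \alpha_{m,j}}.
#'
#' @param codes code matrix (one code per row) or list of code vectors.
#' @return pooled numeric vector of length `M`.
#' @export
poolSum <- function(codes) colSums(.poolCheck(codes))

#' Max pooling
#'
#' Takes the maximum activation of each codeword over the image's codes:
#' \eqn{z_m = \max_j \alpha_{m,j}}.
#'
#' @inheritParams poolSum
#' @return pooled numeric vector of length `M`.
#' @export
poolMax <- function(codes) {
  codes <- .poolCheck(codes)
  do.call(pmax, lapply(seq_len(nrow(codes)), function(i) codes[i, ]))
}

#' Normalise a pooled BoVW vector
#'
#' `L1` divides by the component sum (turning occurrence counts into relative
#' frequencies), `L2` by the Euclidean length, `none` is the identity.
#'
#' @param z pooled vector.
#' @param norm `"L1"`, `"L2"` or `"none"`.
#' @return normalised vector.
#' @export
normalizeBovw <- function(z, norm = c("L1", "L2", "none")) {
  norm <- match.arg(norm)
  if (norm == "none") return(z)
  if (all(z == 0)) stop("cannot normalise an all-zero vector")
  if (norm == "L1") z / sum(z) else z / sqrt(sum(z^2))
}

#' Encode an image's descriptors into a BoVW vector
#'
#' Codes every descriptor against the codebook, pools the codes and
#' normalises the result. The default pooling pairs each coding scheme with
#' its standard partner: hard with sum pooling, soft and semi-soft with max
#' pooling; the default final normalisation is L1.
#'
#' @param dset a [DescriptorSet-class] (or plain descriptor matrix).
#' @param cb a [Codebook-class].
#' @param coding `"hard"`, `"soft"` or `"semisoft"`.
#' @param pooling `"sum"` or `"max"`; `NULL` picks the scheme default.
#' @param norm `"L1"`, `"L2"` or `"none"`.
#' @param params [codingParams()].
#' @return A [BoVWVector-class].
#' @export
encodeImage <- function(dset, cb, coding = c("hard", "soft", "semisoft"),
                        pooling = NULL, norm = "L1",
                        params = codingParams()) {
  coding <- match.arg(coding)
  if (is.null(pooling)) pooling <- if (coding == "hard") "sum" else "max"
  stopifnot(pooling %in% c("sum", "max"), is(cb, "Codebook"))
  X <- .asDescriptorMatrix(dset, cb)
  if (nrow(X) == 0) stop("no descriptors: cannot encode an empty DescriptorSet")
  M <- nrow(codewords(cb))
  d2 <- .squaredDist(X, codewords(cb))
  N <- nrow(X)
  if (coding == "soft") {
    K <- exp(-d2 / (2 * params$sigma^2))
    s <- rowSums(K)
    dead <- s == 0
    if (any(dead)) {
      message(sprintf("encodeImage: kernel underflow for %d descriptor(s); falling back to hard assignment",
                      sum(dead)))
      idx <- max.col(-d2[dead, , drop = FALSE], ties.method = "first")
      K[dead, ] <- 0
      K[cbind(which(dead), idx)] <- 1
      s[dead] <- 1
    }
    A <- K / s
    z <- if (pooling == "sum") colSums(A) else apply(A, 2, max)
  } else {
    idx <- max.col(-d2, ties.method = "first")
    val <- if (coding == "hard") rep(1, N)
           else 1 / (sqrt(d2[cbind(seq_len(N), idx)]) + params$epsilon)
    z <- numeric(M)
    if (pooling == "sum") {
      agg <- rowsum(val, idx)
      z[as.integer(rownames(agg))] <- agg[, 1]
    } else {
      agg <- tapply(val, idx, max)
      z[as.integer(names(agg))] <- agg
    }
  }
  z <- normalizeBovw(z, norm)
  new("BoVWVector", z = z, codebookRef = codebookId(cb), coding = coding,
      pooling = pooling, norm = norm)
}

#' Derive a soft-coding sigma from a descriptor population
#'
#' The Gaussian-kernel scale for codeword-uncertainty coding should match the
#' scale on which descriptor distances live. Following the practice of
#' deriving it from an observed population of distances between descriptor
#' pairs, this helper samples pairs from the supplied descriptor sets and
#' returns `fraction` times the median pairwise distance.
#'
#' @param dsets list of [DescriptorSet-class] (or matrices).
#' @param nPairs number of sampled pairs.
#' @param fraction multiple of the median pairwise distance to return.
#' @param seed sampling seed.
#' @return numeric sigma.
#' @export
sigmaFromDescriptors <- function(dsets, nPairs = 2000, fraction = 0.25,
                                 seed = 1L) {
  X <- do.call(rbind, lapply(dsets, function(d)
    if (is(d, "DescriptorSet")) descriptors(d) else d))
  if (nrow(X) < 2) stop("need at least two descriptors")
  withr::with_seed(as.integer(seed), {
    i <- sample.int(nrow(X), nPairs, replace = TRUE)
    j <- sample.int(nrow(X), nPairs, replace = TRUE)
    ok <- i != j
    d <- sqrt(rowSums((X[i[ok], , drop = FALSE] - X[j[ok], , drop = FALSE])^2))
    fraction * median(d)
  })
}
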
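test_that("hard coding activates the single nearest codeword, lowest index on ties", {
  cb <- toyCodebook(rbind(c(0, 0), c(10, 0), c(0, 10)))
  expect_equal(codeHard(c(4, 0), cb), c(1, 0, 0))    # distances 4 vs 6 vs ~10.8
  expect_equal(codeHard(c(10, 0), cb), c(0, 1, 0))   # exact codeword hit
  expect_equal(codeHard(c(5, 0), cb), c(1, 0, 0))    # equidistant -> lowest index
  ## exact hit on a specific codeword index
  cb4 <- toyCodebook(diag(4) * 3)
  expect_equal(which(codeHard(c(0, 0, 3, 0), cb4) == 1), 3L)
})

test_that("soft coding matches direct kernel evaluation and sums to one", {
  cb <- toyCodebook(rbind(c(0, 0), c(10, 0)))
  a <- codeSoft(c(4, 0), cb, codingParams(sigma = 45))
  k1 <- exp(-16 / (2 * 45^2)); k2 <- exp(-36 / (2 * 45^2))
  expect_equal(a, c(k1, k2) / (k1 + k2), tolerance = 1e-12)
  expect_equal(round(a, 4), c(0.5012, 0.4988))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  ## equidistant to all codewords -> uniform
  cbu <- toyCodebook(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  expect_equal(codeSoft(c(0, 0), cbu, codingParams(sigma = 2)), rep(0.25, 4))
})

test_that("soft coding underflow falls back to hard assignment", {
  cb <- toyCodebook(rbind(c(0, 0), c(100, 0)))
  expect_message(a <- codeSoft(c(40, 0), cb, codingParams(sigma = 1e-3)),
                 "underflow")
  expect_equal(a, c(1, 0))
})

test_that("semi-soft coding is inverse-distance on the argmin only", {
  cb <- toyCodebook(rbind(c(0, 0), c(10, 0)))
  a <- codeSemisoft(c(4, 0), cb)
  expect_equal(a, c(0.25, 0), tolerance = 1e-9)
  ## coinciding with a codeword: guarded, finite
  a2 <- codeSemisoft(c(10, 0), cb, codingParams(epsilon = 1e-12))
  expect_equal(a2[2], 1e12)
  expect_equal(a2[1], 0)
  expect_true(all(is.finite(a2)))
  ## exactly one nonzero, and the same index as hard assignment
  set.seed(42)
  for (i in 1:25) {
    C <- matrix(rnorm(8), 4, 2)
    x <- rnorm(2)
    s <- codeSemisoft(x, toyCodebook(C))
    h <- codeHard(x, toyCodebook(C))
    expect_equal(sum(s != 0), 1)
    expect_equal(which(s != 0), which(h == 1))
  }
})

test_that("pooling operators satisfy their defining identities", {
  expect_equal(poolSum(rbind(c(1, 0), c(0, 1))), c(1, 1))
  expect_equal(poolMax(rbind(c(0.2, 0.8), c(0.5, 0.1))), c(0.5, 0.8))
  ## single code is returned unchanged by both
  expect_equal(poolSum(rbind(c(0.3, 0.7))), c(0.3, 0.7))
  expect_equal(poolMax(rbind(c(0.3, 0.7))), c(0.3, 0.7))
  ## hard codes: sum pooling conserves descriptor count
  cb <- toyCodebook(matrix(rnorm(12), 6, 2))
  set.seed(7)
  A <- codeHard(matrix(rnorm(20), 10, 2), cb)
  expect_equal(sum(poolSum(A)), 10)
  ## max pooling is idempotent under duplication
  expect_equal(poolMax(rbind(A, A)), poolMax(A))
  expect_error(poolSum(matrix(0, 0, 3)), "no descriptors")
  expect_error(poolMax(matrix(0, 0, 3)), "no descriptors")
})

test_that("normalisation follows L1/L2/none conventions and rejects zero vectors", {
  expect_equal(normalizeBovw(c(1, 1), "L1"), c(0.5, 0.5))
  expect_equal(normalizeBovw(c(3, 4), "L2"), c(0.6, 0.8))
  expect_equal(normalizeBovw(c(2, 0), "none"), c(2, 0))
  expect_error(normalizeBovw(c(0, 0), "L1"), "all-zero")
})

test_that("encodeImage composes coding, pooling and normalisation correctly", {
  cb <- toyCodebook(matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 5), 5, 2,
                           byrow = TRUE))
  ## one descriptor equal to codeword 5: hard-sum L1 gives the unit vector
  v <- encodeImage(matrix(c(5, 5), 1, 2), cb, coding = "hard")
  expect_equal(bovw(v), c(0, 0, 0, 0, 1))
  expect_equal(v@pooling, "sum")  # default pairing for hard
  ## histogram with norm "none" sums to N
  set.seed(3)
  X <- matrix(rnorm(24, sd = 6), 12, 2)
  vn <- encodeImage(X, cb, coding = "hard", norm = "none")
  expect_equal(sum(bovw(vn)), 12)
  ## default pairings for soft and semisoft are max pooling
  expect_equal(encodeImage(X, cb, coding = "semisoft")@pooling, "max")
  expect_equal(encodeImage(X, cb, coding = "soft")@pooling, "max")
  ## semisoft-max: nonzero count bounded by min(N, M)
  for (i in 1:20) {
    n <- sample(1:20, 1); m <- sample(2:8, 1)
    Ci <- matrix(rnorm(m * 3), m, 3)
    Xi <- matrix(rnorm(n * 3), n, 3)
    z <- bovw(encodeImage(Xi, toyCodebook(Ci), coding = "semisoft"))
    expect_lte(sum(z != 0), min(n, m))
  }
  expect_error(encodeImage(matrix(0, 0, 2), cb, coding = "hard"),
               "no descriptors")
  expect_error(encodeImage(matrix(1, 1, 3), cb, coding = "hard"),
               "dimensionality")
})

test_that("encodeImage matches the naive double-loop oracle on random instances", {
  set.seed(99)
  schemes <- list(c("hard", "sum"), c("hard", "max"), c("soft", "sum"),
                  c("soft", "max"), c("semisoft", "sum"), c("semisoft", "max"))
  for (i in 1:40) {
    M <- sample(2:8, 1); N <- sample(1:20, 1); D <- sample(2:4, 1)
    C <- matrix(runif(M * D), M, D)
    X <- matrix(runif(N * D), N, D)
    cb <- toyCodebook(C)
    for (s in schemes) {
      z <- bovw(encodeImage(X, cb, coding = s[1], pooling = s[2],
                            params = codingParams(sigma = 0.7)))
      zo <- oracleEncode(X, C, coding = s[1], pooling = s[2], sigma = 0.7)
      expect_equal(z, zo, tolerance = 1e-9)
    }
  }
})

test_that("soft coding converges to hard coding as sigma shrinks", {
  set.seed(5)
  for (i in 1:10) {
    C <- matrix(runif(12), 6, 2)
    x <- runif(2)
    h <- codeHard(x, toyCodebook(C))
    s <- suppressMessages(codeSoft(x, toyCodebook(C),
                                   codingParams(sigma = 1e-3)))
    expect_equal(s, h, tolerance = 1e-9)
  }
})

test_that("pooled vectors are equivariant under codeword permutation", {
  set.seed(8)
  C <- matrix(rnorm(16), 8, 2)
  X <- matrix(rnorm(20), 10, 2)
  perm <- sample(8)
  for (coding in c("hard", "soft", "semisoft")) {
    z1 <- bovw(encodeImage(X, toyCodebook(C), coding = coding,
                           params = codingParams(sigma = 0.9)))
    z2 <- bovw(encodeImage(X, toyCodebook(C[perm, , drop = FALSE]),
                           coding = coding, params = codingParams(sigma = 0.9)))
    expect_equal(z2, z1[perm], tolerance = 1e-12)
  }
})

test_that("BoVWVector validity enforces its normalisation invariant", {
  expect_error(new("BoVWVector", z = c(0.4, 0.4), codebookRef = "x",
                   coding = "hard", pooling = "sum", norm = "L1"),
               "sum to 1")
  expect_s4_class(new("BoVWVector", z = c(0.5, 0.5), codebookRef = "x",
                      coding = "hard", pooling = "sum", norm = "L1"),
                  "BoVWVector")
})
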
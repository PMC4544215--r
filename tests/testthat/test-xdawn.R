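test_that("design matrices carry the Toeplitz onset structure", {
  # one target onset at sample 3 (1-based), response length 2, 6 samples:
  # ones exactly at (3,1) and (4,2)
  d <- buildDesign(6, allOnsets = c(1, 3), targetOnsets = 3, n1 = 2, n2 = 2)
  d1 <- as.matrix(d@d1)
  expect_equal(which(d1 == 1, arr.ind = TRUE)[order(which(d1 == 1)), ],
               matrix(c(3, 4, 1, 2), 2, dimnames = list(NULL, c("row", "col"))),
               ignore_attr = TRUE)
  expect_equal(sum(d1), 2)
  # no targets -> all-zero D1
  d0 <- buildDesign(6, allOnsets = c(1, 3), targetOnsets = numeric(),
                    n1 = 2, n2 = 2)
  expect_equal(sum(d0@d1), 0)
  # onsets at every sample with a length-1 response -> identity column
  dI <- buildDesign(4, allOnsets = 1:4, targetOnsets = 1:4, n1 = 1, n2 = 1)
  expect_equal(as.matrix(dI@d2), matrix(1, 4, 1), ignore_attr = TRUE)
  # responses running past the recording end are truncated
  dT <- buildDesign(4, allOnsets = 3, targetOnsets = 3, n1 = 3, n2 = 3)
  expect_equal(sum(dT@d1), 2)   # samples 5+ truncated
  expect_error(buildDesign(6, 1, 1, n1 = 0, n2 = 2), "positive")
})

test_that("least squares recovers planted responses exactly without noise", {
  set.seed(10)
  n1 <- 4L; n2 <- 3L; ns <- 3L
  onsets <- c(2L, 15L, 30L, 44L)
  design <- buildDesign(60, allOnsets = onsets,
                        targetOnsets = onsets[c(1, 3)], n1 = n1, n2 = n2)
  a1 <- matrix(rnorm(n1 * ns), n1)
  a2 <- matrix(rnorm(n2 * ns), n2)
  x <- as.matrix(design@d1 %*% a1 + design@d2 %*% a2)
  est <- estimateResponses(x, design)
  expect_equal(est$a1, a1, tolerance = 1e-10)
  expect_equal(est$a2, a2, tolerance = 1e-10)
})

test_that("single-onset single-channel estimation matches scalar least squares", {
  # one stimulus that is also the target, n1 = n2 = 1: the design has two
  # identical columns -> rank deficient, pseudoinverse splits the effect
  design <- buildDesign(5, allOnsets = 2, targetOnsets = 2, n1 = 1, n2 = 1)
  x <- matrix(c(0, 6, 0, 0, 0), 5, 1)
  expect_warning(est <- estimateResponses(x, design), "pseudoinverse")
  # minimum-norm solution of a + b = 6 is a = b = 3
  expect_equal(est$a1[1, 1], 3, tolerance = 1e-8)
  expect_equal(est$a2[1, 1], 3, tolerance = 1e-8)
  # distinct columns: ordinary least squares on each
  design2 <- buildDesign(6, allOnsets = c(2, 5), targetOnsets = 2,
                         n1 = 1, n2 = 1)
  x2 <- matrix(0, 6, 1); x2[2] <- 4; x2[5] <- 1
  est2 <- estimateResponses(x2, design2)
  # D2 covers samples 2 and 5, D1 sample 2: solving the 2x2 normal
  # equations by hand gives a2 = 1, a1 = 3
  expect_equal(est2$a2[1, 1], 1, tolerance = 1e-10)
  expect_equal(est2$a1[1, 1], 3, tolerance = 1e-10)
})

test_that("noise-only estimates shrink as the recording grows", {
  set.seed(11)
  norms <- sapply(c(400, 6400), function(nt) {
    onsets <- seq(1, nt - 8, by = 8)
    design <- buildDesign(nt, onsets, onsets[seq(1, length(onsets), 5)],
                          n1 = 4, n2 = 4)
    x <- matrix(rnorm(nt * 2), nt, 2)
    max(abs(estimateResponses(x, design)$a1))
  })
  expect_lt(norms[2], norms[1])
})

test_that("the generalized eigenproblem matches a hand-solved 2x2 case", {
  # B = [[3,1],[1,1]], W = [[2,0],[0,1]]: det(B - lambda W) = 0 gives
  # 2 lambda^2 - 5 lambda + 2 = 0 -> lambda = 2 and 1/2, top eigenvector
  # proportional to (1, 1)
  b <- matrix(c(3, 1, 1, 1), 2)
  w <- diag(c(2, 1))
  fit <- rsvpTriage:::rayleighFilters(b, w, 2)
  expect_equal(fit$values, c(2, 0.5), tolerance = 1e-10)
  u1 <- fit$u[, 1]
  expect_equal(u1[1] / u1[2], 1, tolerance = 1e-10)
  # normalization in the W metric
  expect_equal(drop(t(u1) %*% w %*% u1), 1, tolerance = 1e-10)
})

test_that("SSNR of the top filter beats exhaustive random search", {
  set.seed(12)
  nt <- 800; ns <- 3
  onsets <- seq(4, nt - 40, by = 16)
  targets <- onsets[seq(1, length(onsets), 4)]
  design <- buildDesign(nt, onsets, targets, n1 = 8, n2 = 8)
  tpl <- sin(seq(0, pi, length.out = 8))
  mix <- c(1, -0.5, 0.25)
  x <- as.matrix(design@d1 %*% (tpl %o% mix)) + matrix(rnorm(nt * ns), nt)
  a1 <- estimateResponses(x, design)$a1
  filt <- fitSpatialFilters(x, design, a1, nFilters = 3)
  b <- crossprod(as.matrix(design@d1 %*% a1))
  w <- crossprod(x)
  # oracle: 1e5 random unit vectors never exceed the top Rayleigh quotient
  rand <- matrix(rnorm(3e5), 3)
  rq <- colSums(rand * (b %*% rand)) / colSums(rand * (w %*% rand))
  expect_gte(filt@ssnr[1], max(rq) - 1e-9)
  expect_equal(filt@ssnr[1], rsvpTriage:::ssnrQuotient(filt@u[, 1], b, w),
               tolerance = 1e-9)
  expect_false(is.unsorted(rev(filt@ssnr)))
})

test_that("SSNR is invariant to filter scaling", {
  set.seed(13)
  b <- crossprod(matrix(rnorm(12), 4, 3))
  w <- crossprod(matrix(rnorm(30), 10, 3)) + diag(3)
  u <- rnorm(3)
  for (c in c(-2, 0.1, 7))
    expect_equal(rsvpTriage:::ssnrQuotient(c * u, b, w),
                 rsvpTriage:::ssnrQuotient(u, b, w))
})

test_that("a signal confined to a noise-free channel subspace is found", {
  set.seed(14)
  nt <- 2000
  onsets <- seq(8, nt - 20, by = 20)
  design <- buildDesign(nt, onsets, onsets[c(TRUE, FALSE)], n1 = 8, n2 = 8)
  tpl <- sin(seq(0, pi, length.out = 8))
  x <- matrix(0, nt, 3)
  x[, 1] <- as.vector(design@d1 %*% tpl)       # signal only in channel 1
  x[, 2:3] <- matrix(rnorm(nt * 2), nt)        # noise only in channels 2-3
  a1 <- estimateResponses(x, design)$a1
  filt <- fitSpatialFilters(x, design, a1, nFilters = 1)
  u <- filt@u[, 1]
  cosine <- abs(u[1]) / sqrt(sum(u^2))
  expect_gt(cosine, 0.99)
})

test_that("feature extraction concatenates filtered time courses filter-major", {
  arr <- array(0, c(2, 2, 4))
  arr[1, 1, ] <- 1:4; arr[1, 2, ] <- 5:8
  ep <- epochsFromArray(arr, rate = 4, window = c(0, 1000),
                        labelsIn = c("target", "background"))
  filters <- new("SpatialFilterSet",
                 u = matrix(c(1, 0, 0, 1), 2), ssnr = c(2, 1),
                 a1 = matrix(0, 4, 2), a2 = matrix(0, 4, 2),
                 channelLabels = c("C1", "C2"))
  feats <- applyFilters(ep, filters)
  expect_equal(dim(feats), c(2, 8))
  expect_equal(feats[1, ], c(1:4, 5:8))   # filter 1 samples, then filter 2
  expect_equal(feats[2, ], rep(0, 8))     # zero epoch -> zero vector
  # identity-like single filter on single-channel data returns the epoch
  one <- epochsFromArray(array(arr[1, 1, ], c(1, 1, 4)), rate = 4,
                         window = c(0, 1000))
  f1 <- new("SpatialFilterSet", u = matrix(1, 1, 1), ssnr = 1,
            a1 = matrix(0, 4, 1), a2 = matrix(0, 4, 1),
            channelLabels = "C1")
  expect_equal(applyFilters(one, f1)[1, ], 1:4)
  badCh <- new("SpatialFilterSet", u = matrix(1, 3, 1), ssnr = 1,
               a1 = matrix(0, 4, 3), a2 = matrix(0, 4, 3),
               channelLabels = c("a", "b", "c"))
  expect_error(applyFilters(ep, badCh), "mismatch")
  expect_error(
    fitSpatialFilters(matrix(rnorm(20), 10, 2),
                      buildDesign(10, 2, 2, 2, 2),
                      matrix(0, 2, 2), nFilters = 5),
    "more filters")
})

test_that("training filters never touches validation data", {
  cfg <- tinyConfig("TO", blockDuration = 60, samplingRate = 64, seed = 21L)
  s <- quietly(generateSequence(cfg))
  ep <- epochData(downsample(generateEEG(s, cfg), 32), s, c(0, 1000))
  trainIdx <- 1:80; valIdx <- 81:nTrials(ep)
  f1 <- xdawnTrain(ep[trainIdx], nFilters = 4)
  shuffled <- ep
  shuffled@labels[valIdx] <- sample(shuffled@labels[valIdx])
  f2 <- xdawnTrain(shuffled[trainIdx], nFilters = 4)
  expect_identical(f1@u, f2@u)
  expect_identical(applyFilters(ep[valIdx], f1),
                   applyFilters(shuffled[valIdx], f2))
})

test_that("generalized-eigen filters equal exhaustive maximization on random problems", {
  set.seed(15)
  for (rep in 1:5) {
    b <- crossprod(matrix(rnorm(9), 3))
    w <- crossprod(matrix(rnorm(30), 10, 3)) + 0.5 * diag(3)
    fit <- rsvpTriage:::rayleighFilters(b, w, 1)
    rand <- matrix(rnorm(3e4), 3)
    rq <- colSums(rand * (b %*% rand)) / colSums(rand * (w %*% rand))
    expect_gte(fit$values[1] + 1e-9, max(rq))
    # near-optimal random vectors align with the eigenvector
    best <- rand[, which.max(rq)]
    cosine <- abs(sum(best * fit$u[, 1])) /
      sqrt(sum(best^2) * sum(fit$u[, 1]^2))
    expect_gt(cosine, 0.8)
  }
})
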
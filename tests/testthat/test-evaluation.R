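test_that("contiguous folds cover every trial exactly once", {
  fs <- makeFolds(100)
  expect_equal(fs@slices[[1]], 1:10)
  expect_equal(fs@slices[[10]], 91:100)
  validated <- unlist(lapply(1:10, function(k) foldAssignments(fs, k)$validation))
  expect_setequal(validated, 1:100)
  expect_equal(length(validated), 100)
  # 103 trials: slice sizes differ by at most one, deterministically
  fs2 <- makeFolds(103)
  sizes <- lengths(fs2@slices)
  expect_equal(sort(unique(sizes)), c(10L, 11L))
  expect_equal(sizes, lengths(makeFolds(103)@slices))
  expect_equal(sum(sizes), 103)
  # roles are disjoint and complete within each fold
  a <- foldAssignments(fs2, 4)
  expect_equal(sort(c(a$train, a$threshold, a$validation)), 1:103)
  expect_error(makeFolds(8), "at least")
})

test_that("Az agrees with the pair-counting oracle", {
  expect_equal(azScore(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(azScore(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  # positives {3, 4} vs negatives {1, 2} are perfectly separated
  expect_equal(azScore(c(3, 1, 2, 4), c(1, 0, 0, 1)), 1)
  expect_equal(azScore(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  set.seed(30)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- round(rnorm(n), 1)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    expect_equal(azScore(s, y), pairCountAz(s, y))
  }
  expect_error(azScore(1:4, rep(0, 4)), "both classes")
})

test_that("Az agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- rnorm(150); y <- runif(150) < 0.25
  expect_equal(azScore(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("misclassification counts the documented directions", {
  cls <- rep(c("target", "nontarget", "background"), c(4, 12, 10))
  allRight <- c(rep(TRUE, 4), rep(FALSE, 22))
  expect_equal(misclassificationRates(allRight, cls),
               c(target = 0, nontarget = 0, background = 0))
  expect_equal(misclassificationRates(!allRight, cls),
               c(target = 1, nontarget = 1, background = 1))
  pred <- allRight
  pred[5:9] <- TRUE   # 5 of 12 non-targets called target
  expect_equal(misclassificationRates(pred, cls)[["nontarget"]], 5 / 12,
               tolerance = 1e-10)
  expect_message(misclassificationRates(c(TRUE, FALSE),
                                        c("target", "background")),
                 "nontarget")
})

test_that("the pipeline never leaks validation labels", {
  cfg <- tinyConfig("TO", blockDuration = 60, samplingRate = 64, seed = 33L)
  ses <- quietly(simulateSession(cfg))
  ep <- quietly(preprocessForClassification(ses$eeg, ses$events))
  r1 <- runPipeline(ep, "to_tvb", nFilters = 4)
  # permute the labels inside one validation slice; scores must not move
  fs <- makeFolds(nTrials(ep))
  val <- foldAssignments(fs, 3)$validation
  ep2 <- ep
  set.seed(1)
  ep2@labels[val] <- sample(ep2@labels[val])
  r2 <- runPipeline(ep2, "to_tvb", nFilters = 4)
  expect_identical(trialScores(r1), trialScores(r2))
})

test_that("a session without evoked signal classifies at chance", {
  cfg <- tinyConfig("TO", blockDuration = 120, nBlocks = 2L, seed = 34L,
                    samplingRate = 64,
                    erpAmplitudes = c(target = 0, nontarget = 0,
                                      background = 0))
  ses <- quietly(simulateSession(cfg))
  ep <- quietly(preprocessForClassification(ses$eeg, ses$events))
  rep <- runPipeline(ep, "to_tvb", nFilters = 4)
  y <- labels(rep@scored) == "target"
  se <- sqrt((sum(y) + sum(!y) + 1) / (12 * sum(y) * sum(!y)))
  expect_lt(abs(rep@azPooled - 0.5), 4 * se)
})

test_that("confidence sweeps retain the documented fractions and report dominance", {
  cfg <- tinyConfig("TN", blockDuration = 134, nBlocks = 2L, seed = 35L,
                    samplingRate = 64)
  ses <- quietly(simulateSession(cfg))
  ep <- quietly(preprocessForClassification(ses$eeg, ses$events))
  rep <- runPipeline(ep, "tn_tvbnt", nFilters = 4)
  sw <- quietly(sweepConfidence(rep))
  expect_equal(sw$percentile, seq(0, 90, 10))
  # retained fraction tracks 1 - p/100 and never increases
  expect_true(all(abs(sw$retained_fraction - (1 - sw$percentile / 100)) < 0.02))
  expect_true(all(diff(sw$retained_fraction) < 1e-12))
  # percentile 0 is the unthresholded report
  expect_equal(sw$az[1], rep@azPooled, tolerance = 1e-12)
  expect_equal(sw$misclass_target[1], rep@misclass[["target"]])
  # mitigation dominates classifier-only misclassification everywhere
  for (col in c("target", "nontarget", "background")) {
    plain <- sw[[paste0("misclass_", col)]]
    mit <- sw[[paste0("misclass_", col, "_mitigated")]]
    ok <- !is.na(plain) & !is.na(mit)
    expect_true(all(mit[ok] <= plain[ok] + 1e-12))
  }
})

test_that("manual relabeling of everything removes every error", {
  set.seed(36)
  cls <- sample(c("target", "nontarget", "background"), 200, TRUE,
                prob = c(0.1, 0.1, 0.8))
  s <- rnorm(200) + 2 * (cls == "target")
  st <- scoreTrials(s, selectThreshold(s, cls == "target"),
                    min(s), max(s), cls)
  everything <- simulateMitigation(st, threshold = Inf)
  expect_equal(unname(everything$misclass),
               rep(0, length(everything$misclass)))
  expect_equal(everything$az, 1)
  # threshold below every confidence: identical to classifier-only metrics
  nothing <- simulateMitigation(st, threshold = -1)
  expect_equal(nothing$misclass,
               misclassificationRates(st@predicted, st@trueClass))
  expect_equal(nothing$az, azScore(st@scores, cls == "target"))
  expect_equal(nothing$manual_fraction, 0)
})

test_that("labeling-time overhead is the documented linear formula", {
  expect_identical(labelingTimeOverhead(0.30, 1, 0.5), 60)
  expect_identical(labelingTimeOverhead(0, 1, 0.5), 0)
  expect_identical(labelingTimeOverhead(0.20, 1, 0.5), 40)
  expect_error(labelingTimeOverhead(0.3, 1, 0), "positive")
  expect_error(labelingTimeOverhead(-0.1, 1, 1), "non-negative")
})

test_that("pooled Az rises with the evoked amplitude (parameter recovery)", {
  azAt <- function(scale) {
    az <- numeric(2)
    for (s in 1:2) {
      cfg <- tinyConfig("TO", blockDuration = 120, nBlocks = 1L,
                        samplingRate = 64, seed = 100L + s,
                        erpAmplitudes = c(target = 13.66 * scale,
                                          nontarget = 0,
                                          background = -0.44 * scale))
      ses <- quietly(simulateSession(cfg))
      ep <- quietly(preprocessForClassification(ses$eeg, ses$events))
      az[s] <- runPipeline(ep, "to_tvb", nFilters = 4)@azPooled
    }
    mean(az)
  }
  grid <- vapply(c(0, 0.25, 0.6, 1.5), azAt, numeric(1))
  expect_true(all(diff(grid) > 0))
  expect_lt(grid[1], 0.65)
  expect_gt(grid[4], 0.95)
})

test_that("tn_tvb excludes non-targets before folds and to_tvb matches it", {
  cfg <- tinyConfig("TN", blockDuration = 134, samplingRate = 64, seed = 37L)
  ses <- quietly(simulateSession(cfg))
  ep <- quietly(preprocessForClassification(ses$eeg, ses$events))
  rep <- runPipeline(ep, "tn_tvb", nFilters = 4)
  expect_false("nontarget" %in% labels(rep@scored))
  expect_equal(nTrials(rep@scored),
               sum(labels(ep) %in% c("target", "background")))
})
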
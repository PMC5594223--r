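test_that("maximum-chance criterion reproduces the published chance levels", {
  expect_equal(maxChance(41, 71), 71 / 112)
  expect_equal(round(maxChance(41, 71), 2), 0.63)
  expect_equal(round(maxChance(71, 69), 2), 0.51)
  expect_equal(maxChance(10, 10), 0.5)
  expect_error(maxChance(0, 5), "positive")
})

test_that("per-group accuracy counts correct members per group", {
  truth <- factor(rep(c("g1", "g2"), c(4, 5)), levels = c("g1", "g2"))
  pred <- factor(c("g1", "g1", "g1", "g2",          # 3 of 4 g1 correct
                   rep("g1", 5)),                   # 0 of 5 g2 correct
                 levels = c("g1", "g2"))
  acc <- accuracyPerGroup(pred, truth)
  expect_equal(unname(acc), c(0.75, 0))
  # weighted mean identity with group sizes
  expect_equal(mean(pred == truth),
               sum(acc * c(4, 5)) / 9)
  allGood <- accuracyPerGroup(truth, truth)
  expect_equal(unname(allGood), c(1, 1))
  # empty group flagged
  onlyG1 <- factor(rep("g1", 3), levels = c("g1", "g2"))
  expect_true(is.na(accuracyPerGroup(onlyG1, onlyG1)[["g2"]]))
})

test_that("t-test ranking finds a strong feature and matches stats::t.test", {
  d <- makeTwoGroupFeatures(100, 100, pNoise = 49, informative = 50,
                            shift = 5, seed = 3)
  rk <- rankByTtest(d$x, d$y)
  expect_equal(rk$order[1], 50)
  expect_setequal(rk$order, 1:50)
  # agreement with the base implementation, pooled and Welch
  for (j in c(1, 50)) {
    ref <- stats::t.test(d$x[d$y == "g1", j], d$x[d$y == "g2", j],
                         var.equal = TRUE)
    expect_equal(rk$p[j], ref$p.value, tolerance = 1e-12)
    expect_equal(rk$t[j], unname(ref$statistic), tolerance = 1e-12)
  }
  rw <- rankByTtest(d$x, d$y, variant = "welch")
  refW <- stats::t.test(d$x[d$y == "g1", 7], d$x[d$y == "g2", 7])
  expect_equal(rw$p[7], refW$p.value, tolerance = 1e-12)
  # zero-variance feature gets p = 1 (and a note)
  xz <- cbind(d$x, 0)
  expect_message(rkz <- rankByTtest(xz, d$y), "zero-variance")
  expect_equal(rkz$p[51], 1)
  expect_error(rankByTtest(d$x[1:3, ], factor(c("g1", "g1", "g2"))),
               "at least 2")
})

test_that("under the null no feature is systematically top-ranked", {
  tops <- vapply(1:8, function(s) {
    d <- makeTwoGroupFeatures(30, 30, pNoise = 20, seed = 100 + s)
    rankByTtest(d$x, d$y)$order[1]
  }, 0L)
  expect_gt(length(unique(tops)), 1)
})

test_that("greedy selection recovers informative features and reports its stop", {
  d <- makeTwoGroupFeatures(40, 40, pNoise = 27, informative = 1:3,
                            shift = 2.5, seed = 11)
  cfg <- SelectionConfig(seed = 1)
  set.seed(cfg@seed)
  rk <- rankByTtest(d$x, d$y)
  sel <- greedyForwardSelect(d$x, d$y, rk$order, cfg)
  expect_true(all(1:3 %in% sel))
  expect_lte(length(sel), cfg@growthCap)
  expect_true(attr(sel, "stopReason") %in% c("exhausted", "growthCap", "stall"))
  # a single available feature is a forced choice
  sel1 <- greedyForwardSelect(d$x[, 5, drop = FALSE], d$y, 1L, cfg)
  expect_equal(as.integer(sel1), 1L)
})

test_that("the stall rule halts after 10% consecutive rejections", {
  # one weak feature duplicated 40 times: every duplicate ties on overall and
  # per-group counts, so criterion (iii) (strict improvement while specificity
  # is below 0.5) rejects all of them deterministically
  set.seed(21)
  n1 <- 15; n2 <- 5
  base <- rnorm(n1 + n2)
  x <- matrix(base, n1 + n2, 41)
  y <- factor(rep(c("a", "b"), c(n1, n2)), levels = c("a", "b"))
  cfg <- SelectionConfig(seed = 2)
  set.seed(cfg@seed)
  sel <- greedyForwardSelect(x, y, 1:41, cfg)
  r <- eegspect:::.innerCVCounts(x[, 1, drop = FALSE], y,
                                 local({set.seed(2); eegspect:::stratifiedFolds(y, 10)}),
                                 cfg)
  expect_lt(r$c2 / r$n2, 0.5)    # precondition: criterion (iii) is active
  expect_identical(attr(sel, "stopReason"), "stall")
  # stall limit = ceiling(0.10 * 41) = 5 rejected candidates after the first
  expect_equal(attr(sel, "nEvaluated"), 1L + 5L)
  expect_equal(as.integer(sel), 1L)
})

test_that("vote consolidation applies thresholds, fallbacks and the final cap", {
  cfg <- SelectionConfig()
  unanimous <- rep(list(42L), 10)
  expect_equal(as.integer(consolidateVotes(unanimous, cfg)), 42L)
  # nothing reaches 3 votes: falls back to 2
  two <- c(rep(list(7L), 2), rep(list(integer(0)), 8))
  expect_equal(as.integer(consolidateVotes(two, cfg)), 7L)
  # nothing reaches 2: falls back to 1
  one <- c(list(9L), rep(list(integer(0)), 9))
  expect_equal(as.integer(consolidateVotes(one, cfg)), 9L)
  # 50 features each selected in >= 3 folds: exactly 41 survive, by votes
  sels <- lapply(1:10, function(k) 1:50)
  kept <- consolidateVotes(sels, cfg)
  expect_length(kept, 41)
  # ties broken by better mean rank: features appear in list order, so the
  # first 41 in-fold positions win
  expect_setequal(as.integer(kept), 1:41)
  expect_error(consolidateVotes(rep(list(integer(0)), 10), cfg), "empty")
  expect_error(consolidateVotes(sels[1:9], cfg), "expected 10")
})

test_that("vote counts outrank mean position when both apply", {
  cfg <- SelectionConfig(finalCap = 2)
  sels <- list(c(5L, 9L), c(9L, 5L), c(5L, 9L, 2L), c(2L, 9L), c(2L, 5L),
               3L, c(3L, 9L), integer(0), integer(0), integer(0))
  kept <- consolidateVotes(sels, cfg)
  # votes: 9 -> 5, 5 -> 4, 2 -> 3, 3 -> 2; cap 2 keeps {9, 5}
  expect_setequal(as.integer(kept), c(5L, 9L))
})

test_that("outer split honors group proportions and the published sizes", {
  d <- makeTwoGroupFeatures(39, 41, pNoise = 10, informative = 1,
                            shift = 3, seed = 5)
  se <- makeFeatureSE(d$x, ifelse(d$y == "g1", "AD", "aSCC"))
  cfg <- SelectionConfig(seed = 4)
  res <- runComparison(se, c("AD", "aSCC"), cfg, scenario = "unit")
  expect_equal(length(res@foldRecords$outerTest), 8)      # 10% of 80
  expect_equal(length(res@foldRecords$middleFoldAssignment), 72)
  expect_equal(res@chanceLevel, 41 / 80)
  expect_lte(nrow(res@finalFeatures), 41)
  expect_length(res@perFoldSelections, 10)
})

test_that("no outer-test subject ever enters ranking or inner CV", {
  d <- makeTwoGroupFeatures(20, 20, pNoise = 12, informative = 1,
                            shift = 3, seed = 6)
  se <- makeFeatureSE(d$x, as.character(d$y))
  res <- runComparison(se, c("g1", "g2"), SelectionConfig(seed = 8), "unit")
  testIds <- res@foldRecords$outerTest
  trainIds <- names(res@foldRecords$middleFoldAssignment)
  expect_length(intersect(testIds, trainIds), 0)
  for (rs in res@foldRecords$rankingSubjects) {
    expect_length(intersect(testIds, rs), 0)
    expect_true(all(rs %in% trainIds))
  }
})

test_that("the full comparison is a pure function of features, config and seed", {
  d <- makeTwoGroupFeatures(20, 20, pNoise = 8, informative = 1,
                            shift = 3, seed = 9)
  se <- makeFeatureSE(d$x, as.character(d$y))
  cfg <- SelectionConfig(seed = 123)
  r1 <- runComparison(se, c("g1", "g2"), cfg, "unit")
  r2 <- runComparison(se, c("g1", "g2"), cfg, "unit")
  expect_identical(r1@overallAccuracy, r2@overallAccuracy)
  expect_identical(r1@finalFeatures$id, r2@finalFeatures$id)
  expect_identical(r1@perFoldSelections, r2@perFoldSelections)
  r3 <- runComparison(se, c("g1", "g2"), SelectionConfig(seed = 124), "unit")
  expect_false(identical(r1@foldRecords$outerTest, r3@foldRecords$outerTest))
})
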
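#' Maximum-chance criterion
#'
#' The accuracy attainable by always predicting the larger of the two groups:
#' max(n1, n2) / (n1 + n2).
#'
#' @param n1,n2 group sizes.
#' @return Fraction in [0.5, 1).
#' @export
maxChance <- function(n1, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  max(n1, n2) / (n1 + n2)
}

#' Per-group classification accuracy
#'
#' The proportion of correctly classified individuals within each group.
#'
#' @param predictions factor of predicted labels.
#' @param labels factor of true labels (its levels define the groups).
#' @return Named numeric vector, one accuracy per group level; NA flags a
#'   group absent from the test set.
#' @export
accuracyPerGroup <- function(predictions, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  predictions <- factor(predictions, levels = levels(labels))
  vapply(levels(labels), function(lv) {
    inG <- labels == lv
    if (!any(inG)) return(NA_real_)
    mean(predictions[inG] == lv)
  }, 0)
}

#' Rank features by two-sample t-test
#'
#' Student's two-sample t-test (pooled variance by default, Welch optional)
#' per feature between the two groups; features are ordered by ascending
#' p-value, ties broken by original column index. Features with zero variance
#' in both groups get p = 1.
#'
#' @param x n x p feature matrix (rows = subjects).
#' @param y two-level factor of length n; both groups need >= 2 members.
#' @param variant "pooled" (default) or "welch".
#' @return List with \code{order} (permutation of all column indices),
#'   \code{p} and \code{t} in original column order.
#' @export
rankByTtest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  y <- factor(y)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 members")
  x1 <- x[g1, , drop = FALSE]; x2 <- x[!g1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
  if (variant == "pooled") {
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) *
                 (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tv <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tv), df)
  degenerate <- !is.finite(tv)
  if (any(degenerate)) {
    message(sprintf("%d zero-variance feature(s); p set to 1",
                    sum(degenerate)))
    tv[degenerate] <- 0
    p[degenerate] <- 1
  }
  list(order = order(p, seq_along(p)), p = p, t = tv)
}

# stratified k-fold assignment preserving group proportions; uses the
# current RNG state (callers seed once per pipeline run)
stratifiedFolds <- function(y, k) {
  y <- factor(y)
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1)
    assign[idx] <- ((start + seq_along(idx) - 2L) %% k) + 1L
  }
  assign
}

# stratified holdout: per group max(1, round(fraction * n_g)) test subjects
stratifiedHoldout <- function(y, fraction) {
  y <- factor(y)
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    nTest <- max(1L, round(fraction * length(idx)))
    idx[sample.int(length(idx), nTest)]
  }), use.names = FALSE)
}

.standardize <- function(train, test = NULL) {
  mu <- colMeans(train)
  sd <- sqrt(colMeans((train - rep(mu, each = nrow(train)))^2))
  sd[sd == 0] <- 1
  scaleIt <- function(m) sweep(sweep(m, 2, mu), 2, sd, "/")
  if (is.null(test)) scaleIt(train) else
    list(train = scaleIt(train), test = scaleIt(test))
}

# inner k-fold cross-validated SVM; returns exact correct/total counts so
# the greedy inclusion rules can compare accuracies in integer arithmetic
.innerCVCounts <- function(x, y, foldAssign, config) {
  lv <- levels(y)
  correct <- c(0L, 0L)
  for (k in sort(unique(foldAssign))) {
    tr <- foldAssign != k
    if (length(unique(y[tr])) < 2L)
      stop("inner fold lost a class; groups too small for stratified folds")
    std <- if (config@standardize)
      .standardize(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    else list(train = x[tr, , drop = FALSE], test = x[!tr, , drop = FALSE])
    fit <- trainSVM(std$train, y[tr], cost = config@svmCost)
    pred <- predict(fit, std$test)
    yk <- y[!tr]
    correct[1] <- correct[1] + sum(pred == yk & yk == lv[1])
    correct[2] <- correct[2] + sum(pred == yk & yk == lv[2])
  }
  list(c1 = correct[1], c2 = correct[2],
       n1 = sum(y == lv[1]), n2 = sum(y == lv[2]))
}

#' Greedy stepwise forward feature selection
#'
#' Starting from the top-ranked feature, candidate features are appended in
#' rank order and evaluated by inner k-fold cross-validated SVM accuracy. A
#' candidate is kept only if (i) its overall accuracy is at least as high as
#' the maximum of all previously obtained accuracies, (ii) when the best
#' first-group accuracy so far is below the sensitivity threshold (0.75),
#' the new first-group accuracy is at least that maximum, and (iii) when the
#' best second-group accuracy so far is below the specificity threshold
#' (0.5), the new second-group accuracy exceeds that maximum. The search
#' stops when the features are exhausted, the vector reaches the growth cap
#' (40), or the consecutive-rejection count reaches the stall limit (10% of
#' the available features).
#'
#' Accuracy comparisons use exact integer counts of correct inner-CV
#' predictions (every subject is predicted exactly once per candidate), so
#' ties are decided without floating-point artifacts. "Best so far" maxima
#' are tracked over every evaluated candidate, accepted or not.
#'
#' @param x n x p feature matrix of the middle-layer training set.
#' @param y two-level factor (first level = sensitivity group).
#' @param rankedFeatures column indices in t-test rank order (from
#'   \code{\link{rankByTtest}} on this training set only).
#' @param config a \linkS4class{SelectionConfig}.
#' @return Integer vector of selected column indices, in order of addition,
#'   with attributes \code{stopReason} ("exhausted", "growthCap" or "stall")
#'   and \code{nEvaluated} (number of candidate vectors scored).
#' @export
greedyForwardSelect <- function(x, y, rankedFeatures, config) {
  x <- as.matrix(x)
  y <- factor(y)
  nf <- length(rankedFeatures)
  if (nf == 0L) stop("no features to select from")
  innerAssign <- stratifiedFolds(y, config@innerFolds)
  stallLimit <- max(1L, as.integer(ceiling(config@stallFraction * nf)))

  selected <- rankedFeatures[1]
  r <- .innerCVCounts(x[, selected, drop = FALSE], y, innerAssign, config)
  nTot <- r$n1 + r$n2
  bestCorrect <- r$c1 + r$c2
  bestC1 <- r$c1
  bestC2 <- r$c2
  consec <- 0L
  nEval <- 1L
  stopReason <- "exhausted"

  for (f in rankedFeatures[-1]) {
    if (length(selected) >= config@growthCap) { stopReason <- "growthCap"; break }
    r <- .innerCVCounts(x[, c(selected, f), drop = FALSE], y, innerAssign,
                        config)
    nEval <- nEval + 1L
    ok <- (r$c1 + r$c2) >= bestCorrect
    if (ok && bestC1 < config@sensThreshold * r$n1)
      ok <- r$c1 >= bestC1
    if (ok && bestC2 < config@specThreshold * r$n2)
      ok <- r$c2 > bestC2
    bestCorrect <- max(bestCorrect, r$c1 + r$c2)
    bestC1 <- max(bestC1, r$c1)
    bestC2 <- max(bestC2, r$c2)
    if (ok) {
      selected <- c(selected, f)
      consec <- 0L
    } else {
      consec <- consec + 1L
      if (consec >= stallLimit) { stopReason <- "stall"; break }
    }
  }
  structure(selected, stopReason = stopReason, nEvaluated = nEval)
}

#' Consolidate middle-layer feature selections by vote counting
#'
#' Counts how often each feature was selected across the middle-layer folds
#' and keeps those selected in at least 3 of them; if that leaves none, the
#' threshold falls back to 2, then 1. If more than the final cap (41)
#' survive, the most-voted 41 are kept, ties broken by better (smaller) mean
#' selection position within the folds, then by feature index.
#'
#' @param selections list of integer vectors (one per middle fold).
#' @param config a \linkS4class{SelectionConfig}.
#' @return Integer vector of consolidated feature indices, most-voted first.
#' @export
consolidateVotes <- function(selections, config) {
  if (length(selections) != config@middleFolds)
    stop(sprintf("expected %d middle-fold selections, got %d",
                 config@middleFolds, length(selections)))
  all <- unlist(selections, use.names = FALSE)
  if (!length(all)) stop("all middle-fold selections are empty")
  counts <- table(all)
  feats <- as.integer(names(counts))
  votes <- as.integer(counts)
  keep <- integer(0)
  for (th in config@voteThresholds) {
    keep <- feats[votes >= th]
    if (length(keep)) { votes <- votes[votes >= th]; break }
  }
  if (!length(keep)) stop("vote consolidation produced no features")
  meanPos <- vapply(keep, function(f) {
    pos <- vapply(selections, function(s) {
      i <- match(f, s); if (is.na(i)) NA_real_ else as.numeric(i)
    }, 0)
    mean(pos, na.rm = TRUE)
  }, 0)
  ord <- order(-votes, meanPos, keep)
  keep <- keep[ord]
  if (length(keep) > config@finalCap) keep <- keep[seq_len(config@finalCap)]
  keep
}

#' Run one pairwise group comparison
#'
#' The full three-layer procedure on one scenario feature set: a single
#' stratified 90/10 outer split; a middle layer of 10 stratified folds over
#' the outer training set, each ranking features by t-test on its own
#' training subjects only and running greedy forward selection with inner
#' 10-fold cross-validation; vote consolidation; an SVM trained with the
#' final features on the whole outer training set and evaluated once on the
#' held-out outer test set. All splits preserve the group proportions, and
#' outer-test subjects never enter ranking or inner cross-validation.
#'
#' @param featureSet \code{SummarizedExperiment} (features x subjects) whose
#'   colData has a \code{group} column, e.g. from
#'   \code{\link{buildInitialVector}}.
#' @param groupPair character(2); order defines the sensitivity (first) and
#'   specificity (second) group.
#' @param config a \linkS4class{SelectionConfig}.
#' @param scenario label stored in the result.
#' @return A \linkS4class{ComparisonResult}.
#' @export
runComparison <- function(featureSet, groupPair, config = SelectionConfig(),
                          scenario = "custom") {
  groups <- SummarizedExperiment::colData(featureSet)$group
  keep <- groups %in% groupPair
  if (!all(groupPair %in% groups))
    stop("both groups of the pair must be present")
  x <- t(SummarizedExperiment::assay(featureSet)[, keep, drop = FALSE])
  y <- factor(groups[keep], levels = groupPair)
  ids <- colnames(featureSet)[keep]
  desc <- as.data.frame(SummarizedExperiment::rowData(featureSet))

  set.seed(config@seed)
  testIdx <- sort(stratifiedHoldout(y, config@outerTestFraction))
  trainIdx <- setdiff(seq_len(nrow(x)), testIdx)
  yTrain <- y[trainIdx]
  foldAssign <- stratifiedFolds(yTrain, config@middleFolds)

  selections <- vector("list", config@middleFolds)
  rankingSubjects <- vector("list", config@middleFolds)
  for (k in seq_len(config@middleFolds)) {
    midIdx <- trainIdx[foldAssign != k]
    rankingSubjects[[k]] <- ids[midIdx]
    rk <- rankByTtest(x[midIdx, , drop = FALSE], y[midIdx])
    selections[[k]] <- greedyForwardSelect(x[midIdx, , drop = FALSE],
                                           y[midIdx], rk$order, config)
  }
  final <- consolidateVotes(selections, config)

  xs <- if (config@standardize)
    .standardize(x[trainIdx, final, drop = FALSE],
                 x[testIdx, final, drop = FALSE])
  else list(train = x[trainIdx, final, drop = FALSE],
            test = x[testIdx, final, drop = FALSE])
  fit <- trainSVM(xs$train, yTrain, cost = config@svmCost)
  pred <- predict(fit, xs$test)
  yTest <- y[testIdx]
  perGroup <- accuracyPerGroup(pred, yTest)
  overall <- mean(pred == yTest)

  new("ComparisonResult",
      groupPair = groupPair, scenario = scenario,
      overallAccuracy = overall,
      perGroupAccuracy = perGroup,
      chanceLevel = maxChance(sum(y == groupPair[1]), sum(y == groupPair[2])),
      finalFeatures = desc[final, , drop = FALSE],
      perFoldSelections = lapply(selections, function(s) desc$id[s]),
      foldRecords = list(outerTest = ids[testIdx],
                         middleFoldAssignment = stats::setNames(foldAssign,
                                                                ids[trainIdx]),
                         rankingSubjects = rankingSubjects))
}
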
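#' @import methods
NULL

#' The 17-channel clinical montage used throughout the package
#'
#' Electrode labels of the reduced 10-20 montage, in the canonical order used
#' for every connectivity matrix, feature descriptor and EDF export.
#'
#' @return Character vector of length 17.
#' @export
channelLabels17 <- function() {
  c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' The 14 spectral interaction measures
#'
#' @return Character vector naming the measures in canonical order.
#' @export
connectivityMeasures <- function() {
  c("S", "h", "Af", "DC", "COH", "iCOH", "pCOH",
    "PDC", "PDCF", "GPDC", "DTF", "dDTF", "ffDTF", "GGC")
}

#' Canonical frequency bands
#'
#' Integer frequencies (Hz) belonging to each band of the 2-80 Hz analysis
#' grid: delta 2-4, theta 5-7, alpha 8-13, beta 14-30, gamma 31-80.
#'
#' @return Named list of integer vectors.
#' @export
bandDefinitions <- function() {
  list(delta = 2:4, theta = 5:7, alpha = 8:13, beta = 14:30, gamma = 31:80)
}

#' Global graph metrics computed from connectivity matrices
#' @return Character vector of metric names.
#' @export
graphMetricNames <- function() {
  c("assortativity", "efficiency", "clustering", "modularity", "transitivity")
}

# ---------------------------------------------------------------------------
# MVARModel
# ---------------------------------------------------------------------------

#' Multivariate autoregressive model
#'
#' Holds the coefficient stack A_1..A_p (an m x m x p array), the residual
#' covariance Sigma, the sampling rate and channel labels of a fitted or
#' constructed MVAR model X(t) = sum_k A_k X(t-k) + E(t).
#'
#' @slot order integer model order p.
#' @slot coefficients m x m x p array; \code{coefficients[i, j, k]} is the
#'   influence of channel j at lag k on channel i.
#' @slot residualCovariance m x m symmetric innovation covariance.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of length m.
#' @export
setClass("MVARModel",
  representation(
    order = "integer",
    coefficients = "array",
    residualCovariance = "matrix",
    samplingRate = "numeric",
    channelLabels = "character"
  )
)

setValidity("MVARModel", function(object) {
  msg <- character()
  dm <- dim(object@coefficients)
  if (length(dm) != 3L || dm[1] != dm[2])
    msg <- c(msg, "coefficients must be an m x m x p array")
  if (length(dm) == 3L && dm[3] != object@order)
    msg <- c(msg, "third dimension of coefficients must equal the order")
  if (!all(is.finite(object@coefficients)))
    msg <- c(msg, "coefficients contain non-finite values")
  S <- object@residualCovariance
  if (!all(is.finite(S)) || nrow(S) != ncol(S))
    msg <- c(msg, "residualCovariance must be a finite square matrix")
  if (length(dm) == 3L && nrow(S) != dm[1])
    msg <- c(msg, "residualCovariance dimension must match channel count")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    msg <- c(msg, "residualCovariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    msg <- c(msg, "residualCovariance must be positive semi-definite")
  if (length(object@channelLabels) != dm[1])
    msg <- c(msg, "channelLabels length must equal channel count")
  if (length(msg)) msg else TRUE
})

#' Construct an MVARModel
#'
#' @param coefficients m x m x p array of AR coefficient matrices (lag along
#'   the third dimension). A plain m x m matrix is treated as order 1.
#' @param residualCovariance m x m innovation covariance (default identity).
#' @param samplingRate sampling rate in Hz (default 200).
#' @param channelLabels optional channel names.
#' @return An \linkS4class{MVARModel}.
#' @export
MVARModel <- function(coefficients, residualCovariance = NULL,
                      samplingRate = 200,
                      channelLabels = NULL) {
  if (is.matrix(coefficients)) coefficients <- array(coefficients, c(dim(coefficients), 1L))
  m <- dim(coefficients)[1]
  if (is.null(residualCovariance)) residualCovariance <- diag(m)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  new("MVARModel",
    order = as.integer(dim(coefficients)[3]),
    coefficients = coefficients,
    residualCovariance = residualCovariance,
    samplingRate = samplingRate,
    channelLabels = channelLabels)
}

#' @describeIn MVARModel number of channels
#' @param object,x an MVARModel
#' @export
nChannels <- function(x) dim(x@coefficients)[1]

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: %d channels, order %d, fs = %g Hz\n",
              nChannels(object), object@order, object@samplingRate))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
  cat(sprintf("  stable: %s (spectral radius %.4f)\n",
              isStable(object), spectralRadius(object)))
})

# ---------------------------------------------------------------------------
# SpectralMatrices
# ---------------------------------------------------------------------------

#' Frequency-domain transforms of an MVAR model
#'
#' Holds, per frequency f of the analysis grid, the AR polynomial
#' Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs), its inverse H(f)
#' (the transfer function) and the spectral matrix S(f) = H(f) Sigma H(f)*.
#'
#' @slot frequencies numeric grid in Hz.
#' @slot Af complex m x m x F array (AR polynomial).
#' @slot H complex m x m x F array (transfer function).
#' @slot S complex m x m x F array (cross-spectral matrix).
#' @slot residualCovariance the Sigma used to form S.
#' @slot channelLabels channel names.
#' @export
setClass("SpectralMatrices",
  representation(
    frequencies = "numeric",
    Af = "array",
    H = "array",
    S = "array",
    residualCovariance = "matrix",
    channelLabels = "character"
  )
)

setValidity("SpectralMatrices", function(object) {
  nf <- length(object@frequencies)
  for (nm in c("Af", "H", "S")) {
    a <- slot(object, nm)
    if (length(dim(a)) != 3L || dim(a)[3] != nf || dim(a)[1] != dim(a)[2])
      return(sprintf("%s must be an m x m x nFreq array", nm))
  }
  TRUE
})

setMethod("show", "SpectralMatrices", function(object) {
  cat(sprintf("SpectralMatrices: %d channels, %d frequencies (%g-%g Hz)\n",
              dim(object@Af)[1], length(object@frequencies),
              min(object@frequencies), max(object@frequencies)))
})

# ---------------------------------------------------------------------------
# ConnectivityArray / BandedConnectivity
# ---------------------------------------------------------------------------

#' Per-frequency connectivity values for one measure
#'
#' Real-valued m x m x F array for a single interaction measure. Entry
#' (i, j, f) quantifies the influence (or association) of source channel j
#' on sink channel i at frequency f.
#'
#' @slot measure measure name (one of \code{connectivityMeasures()}).
#' @slot frequencies Hz grid.
#' @slot values m x m x F real array.
#' @slot channelLabels channel names.
#' @export
setClass("ConnectivityArray",
  representation(
    measure = "character",
    frequencies = "numeric",
    values = "array",
    channelLabels = "character"
  )
)

setValidity("ConnectivityArray", function(object) {
  dm <- dim(object@values)
  if (length(dm) != 3L || dm[1] != dm[2]) return("values must be m x m x F")
  if (dm[3] != length(object@frequencies)) return("frequency dimension mismatch")
  if (!all(is.finite(object@values))) return("values contain non-finite entries")
  TRUE
})

ConnectivityArray <- function(measure, frequencies, values, channelLabels = NULL) {
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(dim(values)[1]))
  new("ConnectivityArray", measure = measure, frequencies = frequencies,
      values = values, channelLabels = channelLabels)
}

setMethod("show", "ConnectivityArray", function(object) {
  cat(sprintf("ConnectivityArray '%s': %d x %d channels, %d frequencies\n",
              object@measure, dim(object@values)[1], dim(object@values)[2],
              length(object@frequencies)))
})

#' Band-averaged connectivity for one measure
#'
#' @slot measure measure name.
#' @slot values m x m x 5 array, third dimension named
#'   delta/theta/alpha/beta/gamma.
#' @slot channelLabels channel names.
#' @export
setClass("BandedConnectivity",
  representation(
    measure = "character",
    values = "array",
    channelLabels = "character"
  )
)

setValidity("BandedConnectivity", function(object) {
  dm <- dim(object@values)
  if (length(dm) != 3L || dm[1] != dm[2]) return("values must be m x m x nBands")
  if (!identical(dimnames(object@values)[[3]], names(bandDefinitions())))
    return("third dimension must be named by the canonical bands")
  TRUE
})

setMethod("show", "BandedConnectivity", function(object) {
  cat(sprintf("BandedConnectivity '%s': %d x %d channels x %d bands\n",
              object@measure, dim(object@values)[1], dim(object@values)[2],
              dim(object@values)[3]))
})

# ---------------------------------------------------------------------------
# SPECTProfile
# ---------------------------------------------------------------------------

#' Regional SPECT perfusion profile
#'
#' A vector of 46 cerebellar-ratio perfusion values over the canonical region
#' list (\code{\link{spectRegionNames}}).
#'
#' @slot values named numeric vector of length 46, strictly positive.
#' @export
setClass("SPECTProfile", representation(values = "numeric"))

setValidity("SPECTProfile", function(object) {
  v <- object@values
  if (length(v) != 46L) return("SPECT profile must have exactly 46 regions")
  if (!identical(names(v), spectRegionNames()))
    return("region names must match the canonical list in canonical order")
  if (!all(is.finite(v)) || any(v <= 0))
    return("perfusion ratios must be finite and > 0")
  TRUE
})

setMethod("show", "SPECTProfile", function(object) {
  cat(sprintf("SPECTProfile: 46 regions, mean ratio %.3f (range %.3f-%.3f)\n",
              mean(object@values), min(object@values), max(object@values)))
})

# ---------------------------------------------------------------------------
# Cohort specification
# ---------------------------------------------------------------------------

#' Specification of one diagnostic group for the synthetic cohort generator
#'
#' @slot name group label.
#' @slot nSubjects number of subjects to generate.
#' @slot mvarTemplate the group's generating \linkS4class{MVARModel}.
#' @slot spectMeans named 46-vector of regional perfusion means (ratio units).
#' @slot spectSd per-region standard deviations (length 46 or scalar recycled).
#' @slot subjectJitter relative scale of per-subject Gaussian perturbation of
#'   the nonzero template coefficients.
#' @export
setClass("GroupSpec",
  representation(
    name = "character",
    nSubjects = "integer",
    mvarTemplate = "MVARModel",
    spectMeans = "numeric",
    spectSd = "numeric",
    subjectJitter = "numeric"
  )
)

setValidity("GroupSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (!isStable(object@mvarTemplate)) msg <- c(msg, "mvarTemplate must be stable")
  if (length(object@spectMeans) != 46L) msg <- c(msg, "spectMeans must have 46 regions")
  if (any(object@spectSd < 0)) msg <- c(msg, "spectSd must be >= 0")
  if (object@subjectJitter < 0) msg <- c(msg, "subjectJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GroupSpec-class
#' @param name,nSubjects,mvarTemplate,spectMeans,spectSd,subjectJitter see slots.
#' @export
GroupSpec <- function(name, nSubjects, mvarTemplate, spectMeans,
                      spectSd = 0.05, subjectJitter = 0.05) {
  if (is.null(names(spectMeans))) names(spectMeans) <- spectRegionNames()
  if (length(spectSd) == 1L) spectSd <- rep(spectSd, 46L)
  new("GroupSpec", name = name, nSubjects = as.integer(nSubjects),
      mvarTemplate = mvarTemplate, spectMeans = spectMeans,
      spectSd = spectSd, subjectJitter = subjectJitter)
}

setMethod("show", "GroupSpec", function(object) {
  cat(sprintf("GroupSpec '%s': %d subjects, template order %d, jitter %g\n",
              object@name, object@nSubjects, object@mvarTemplate@order,
              object@subjectJitter))
})

#' Specification of a full synthetic cohort
#'
#' @slot groups list of \linkS4class{GroupSpec}.
#' @slot samplingRate Hz (default 200).
#' @slot duration seconds of EEG per subject (default 180).
#' @slot nChannels channel count shared by all groups (default 17).
#' @slot seed master seed; every subject's seed derives deterministically
#'   from it.
#' @export
setClass("CohortSpec",
  representation(
    groups = "list",
    samplingRate = "numeric",
    duration = "numeric",
    nChannels = "integer",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (!length(object@groups)) return("at least one group required")
  if (!all(vapply(object@groups, is, TRUE, "GroupSpec")))
    return("groups must be GroupSpec objects")
  mOk <- vapply(object@groups, function(g) nChannels(g@mvarTemplate), 1L)
  if (!all(mOk == object@nChannels))
    return("all group templates must match nChannels")
  TRUE
})

#' @rdname CohortSpec-class
#' @param groups,samplingRate,duration,nChannels,seed see slots.
#' @export
CohortSpec <- function(groups, samplingRate = 200, duration = 180,
                       nChannels = NULL, seed = 1L) {
  if (is.null(nChannels)) nChannels <- nChannels(groups[[1]]@mvarTemplate)
  new("CohortSpec", groups = groups, samplingRate = samplingRate,
      duration = duration, nChannels = as.integer(nChannels),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  ns <- vapply(object@groups, slot, 1L, "nSubjects")
  nms <- vapply(object@groups, slot, "", "name")
  cat(sprintf("CohortSpec: %d groups (%s), fs = %g Hz, %g s, %d channels, seed %d\n",
              length(ns), paste(sprintf("%s:%d", nms, ns), collapse = ", "),
              object@samplingRate, object@duration, object@nChannels,
              object@seed))
})

#' One synthetic or real subject
#'
#' @slot id subject identifier.
#' @slot group diagnostic group label.
#' @slot eeg channels x samples matrix.
#' @slot spect \linkS4class{SPECTProfile}.
#' @export
setClass("Subject",
  representation(id = "character", group = "character",
                 eeg = "matrix", spect = "SPECTProfile"))

setValidity("Subject", function(object) {
  if (!all(is.finite(object@eeg))) return("eeg contains non-finite values")
  TRUE
})

setMethod("show", "Subject", function(object) {
  cat(sprintf("Subject %s (%s): %d x %d EEG, SPECT profile present\n",
              object@id, object@group, nrow(object@eeg), ncol(object@eeg)))
})

# ---------------------------------------------------------------------------
# SelectionConfig / ComparisonResult
# ---------------------------------------------------------------------------

#' Configuration of the nested cross-validation and feature selection
#'
#' Defaults reproduce the published design: a single stratified 90/10 outer
#' split, a middle layer of 10 stratified folds each running t-test ranking
#' plus greedy forward selection with inner 10-fold cross-validation,
#' sensitivity/specificity inclusion thresholds of 0.75 and 0.5, a growth cap
#' of 40 features during search, a final cap of 41 after vote counting with
#' vote thresholds 3, then 2, then 1 of 10, and a stall rule of 10% of the
#' available features.
#'
#' @slot middleFolds,innerFolds fold counts (both 10).
#' @slot outerTestFraction fraction held out in the outer layer (0.10).
#' @slot sensThreshold,specThreshold inclusion thresholds (0.75, 0.5).
#' @slot growthCap maximum vector length during greedy search (40).
#' @slot finalCap maximum features kept after vote counting (41).
#' @slot voteThresholds strictly decreasing vote cutoffs (3, 2, 1).
#' @slot stallFraction consecutive-rejection stop rule as a fraction of the
#'   available features (0.10).
#' @slot svmCost soft-margin penalty C of the 2-norm SVM.
#' @slot standardize standardize features to training-set mean/sd before SVM.
#' @slot seed master seed for all splits.
#' @export
setClass("SelectionConfig",
  representation(
    middleFolds = "integer", innerFolds = "integer",
    outerTestFraction = "numeric",
    sensThreshold = "numeric", specThreshold = "numeric",
    growthCap = "integer", finalCap = "integer",
    voteThresholds = "integer", stallFraction = "numeric",
    svmCost = "numeric", standardize = "logical", seed = "integer"
  )
)

setValidity("SelectionConfig", function(object) {
  msg <- character()
  if (object@outerTestFraction <= 0 || object@outerTestFraction >= 1)
    msg <- c(msg, "outerTestFraction must be in (0, 1)")
  if (object@growthCap < 1L || object@finalCap < 1L)
    msg <- c(msg, "caps must be positive")
  if (any(diff(object@voteThresholds) >= 0))
    msg <- c(msg, "voteThresholds must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname SelectionConfig-class
#' @param middleFolds,innerFolds,outerTestFraction,sensThreshold,specThreshold
#'   see slots.
#' @param growthCap,finalCap,voteThresholds,stallFraction,svmCost,standardize,seed
#'   see slots.
#' @export
SelectionConfig <- function(middleFolds = 10, innerFolds = 10,
                            outerTestFraction = 0.10,
                            sensThreshold = 0.75, specThreshold = 0.5,
                            growthCap = 40, finalCap = 41,
                            voteThresholds = c(3L, 2L, 1L),
                            stallFraction = 0.10,
                            svmCost = 1, standardize = TRUE, seed = 1L) {
  new("SelectionConfig",
      middleFolds = as.integer(middleFolds), innerFolds = as.integer(innerFolds),
      outerTestFraction = outerTestFraction,
      sensThreshold = sensThreshold, specThreshold = specThreshold,
      growthCap = as.integer(growthCap), finalCap = as.integer(finalCap),
      voteThresholds = as.integer(voteThresholds),
      stallFraction = stallFraction, svmCost = svmCost,
      standardize = standardize, seed = as.integer(seed))
}

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf(paste0("SelectionConfig: outer %.0f%% test, %d middle x %d inner folds,\n",
                     "  thresholds sens %.2f / spec %.2f, caps %d/%d, votes %s, stall %.0f%%, seed %d\n"),
              100 * object@outerTestFraction, object@middleFolds, object@innerFolds,
              object@sensThreshold, object@specThreshold,
              object@growthCap, object@finalCap,
              paste(object@voteThresholds, collapse = "/"),
              100 * object@stallFraction, object@seed))
})

#' Result of one pairwise group comparison under one scenario
#'
#' @slot groupPair the two group labels, in pair order (first = "sensitivity"
#'   group).
#' @slot scenario scenario label.
#' @slot overallAccuracy fraction correct on the outer test set.
#' @slot perGroupAccuracy named accuracies for the two groups (Eq.-style
#'   per-group proportions); NA flags an empty test group.
#' @slot chanceLevel maximum-chance criterion for the pair.
#' @slot finalFeatures data.frame of selected feature descriptors.
#' @slot perFoldSelections list (one per middle fold) of selected feature ids.
#' @slot foldRecords bookkeeping of split memberships (outer test indices,
#'   middle fold assignment, subjects used for ranking per fold) for audit.
#' @export
setClass("ComparisonResult",
  representation(
    groupPair = "character", scenario = "character",
    overallAccuracy = "numeric", perGroupAccuracy = "numeric",
    chanceLevel = "numeric", finalFeatures = "data.frame",
    perFoldSelections = "list", foldRecords = "list"
  )
)

setValidity("ComparisonResult", function(object) {
  acc <- c(object@overallAccuracy, object@perGroupAccuracy)
  acc <- acc[is.finite(acc)]
  if (any(acc < 0 | acc > 1)) return("accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult %s vs %s [%s]\n", object@groupPair[1],
              object@groupPair[2], object@scenario))
  cat(sprintf("  overall %.2f (%.2f/%.2f), chance %.2f, %d features\n",
              object@overallAccuracy, object@perGroupAccuracy[1],
              object@perGroupAccuracy[2], object@chanceLevel,
              nrow(object@finalFeatures)))
})

#' @describeIn ComparisonResult-class overall accuracy accessor
#' @param x a ComparisonResult
#' @export
overallAccuracy <- function(x) x@overallAccuracy

#' @describeIn ComparisonResult-class per-group accuracy accessor
#' @export
perGroupAccuracy <- function(x) x@perGroupAccuracy

#' @describeIn ComparisonResult-class chance-level accessor
#' @export
chanceLevel <- function(x) x@chanceLevel

#' @describeIn ComparisonResult-class selected-feature descriptor accessor
#' @export
selectedFeatures <- function(x) x@finalFeatures
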
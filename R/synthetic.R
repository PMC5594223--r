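#' @title Synthetic cohort generator
#' @description Generates group-labelled synthetic subjects whose EEG is a
#' realization of a group-specific stable MVAR process (per-subject jittered)
#' and whose SPECT profile is drawn from group-specific regional means. The
#' generative model is deliberately the analysis model, so parameter recovery
#' is an exact oracle for every downstream stage.
#' @name synthetic
NULL

# deterministic sub-seed derivation, kept below 2^31
.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 100003 + as.numeric(index) * 10007) %%
               2147483629 + 1)
}

#' Build a stable MVAR template
#'
#' Constructs an order-p template with damped oscillatory diagonal dynamics
#' plus user-specified directed couplings, and verifies stability.
#'
#' @param m channel count.
#' @param order generator order (default 5).
#' @param diagCoef lag-1 diagonal autoregression (default 0.4).
#' @param oscillation optional list(freq =, fs =, strength =) adding a damped
#'   oscillation at the given frequency to every channel via lag-1/lag-2
#'   coefficients.
#' @param couplings list of list(source =, sink =, lag =, value =) entries
#'   setting A_lag[sink, source] = value.
#' @param residualCovariance innovation covariance (default identity).
#' @param samplingRate Hz (default 200).
#' @param channelLabels optional labels.
#' @return A stable \linkS4class{MVARModel}; error if the requested template
#'   is unstable.
#' @export
mvarTemplate <- function(m, order = 5, diagCoef = 0.4, oscillation = NULL,
                         couplings = list(), residualCovariance = NULL,
                         samplingRate = 200, channelLabels = NULL) {
  A <- array(0, c(m, m, order))
  diag(A[, , 1]) <- diagCoef
  if (!is.null(oscillation)) {
    # damped resonance at freq: poles r*exp(+-i*2*pi*freq/fs)
    r <- if (is.null(oscillation$damping)) 0.7 else oscillation$damping
    th <- 2 * pi * oscillation$freq / samplingRate
    a1 <- 2 * r * cos(th); a2 <- -r^2
    s <- if (is.null(oscillation$strength)) 1 else oscillation$strength
    diag(A[, , 1]) <- diagCoef + s * a1
    if (order >= 2) diag(A[, , 2]) <- s * a2
  }
  for (cp in couplings) {
    lag <- if (is.null(cp$lag)) 1L else cp$lag
    if (lag > order) stop("coupling lag exceeds template order")
    A[cp$sink, cp$source, lag] <- cp$value
  }
  mdl <- MVARModel(A, residualCovariance, samplingRate = samplingRate,
                   channelLabels = channelLabels)
  if (!isStable(mdl))
    stop(sprintf("template unstable (spectral radius %.3f); reduce coefficients",
                 spectralRadius(mdl)))
  mdl
}

# additive Gaussian jitter with sd proportional to each entry's magnitude;
# structural zeros stay zero, so injected coupling patterns survive jitter
.jitterModel <- function(template, jitter, maxRetries = 100L) {
  if (jitter == 0) return(template)
  A <- template@coefficients
  for (r in seq_len(maxRetries)) {
    Aj <- A + stats::rnorm(length(A), sd = jitter * abs(A))
    cand <- MVARModel(Aj, template@residualCovariance,
                      samplingRate = template@samplingRate,
                      channelLabels = template@channelLabels)
    if (isStable(cand)) return(cand)
  }
  stop(sprintf("no stable jittered model after %d retries (jitter %g)",
               maxRetries, jitter))
}

#' Simulate one subject's EEG from an MVAR template
#'
#' Draws a realization of the (per-subject jittered) process
#' X(t) = sum_k A_k X(t-k) + E(t), discarding a burn-in of
#' max(1000, 10 * order) samples. Jittered models are rejection-sampled for
#' stability (at most 100 retries).
#'
#' @param template a stable \linkS4class{MVARModel}.
#' @param jitter relative scale of the per-subject coefficient perturbation.
#' @param nSamples samples to return.
#' @param seed integer seed (the function sets the RNG deterministically).
#' @return channels x samples matrix.
#' @export
generateSubjectEEG <- function(template, jitter, nSamples, seed) {
  if (!isStable(template))
    stop(sprintf("template unstable (spectral radius %.3f)",
                 spectralRadius(template)))
  p <- template@order
  if (nSamples <= 10 * p) stop("nSamples must exceed 10 * order")
  set.seed(as.integer(seed))
  model <- .jitterModel(template, jitter)
  A <- model@coefficients
  m <- dim(A)[1]
  burn <- max(1000L, 10L * p)
  ntot <- nSamples + burn
  L <- t(chol(model@residualCovariance))
  E <- L %*% matrix(stats::rnorm(m * ntot), m, ntot)
  # flatten the lag stack: x_t = Aflat %*% state + e_t, state = (x_{t-1}; ...)
  Aflat <- matrix(0, m, m * p)
  for (k in seq_len(p)) Aflat[, (k - 1) * m + seq_len(m)] <- A[, , k]
  X <- matrix(0, m, ntot)
  state <- numeric(m * p)
  for (t in seq_len(ntot)) {
    xt <- Aflat %*% state + E[, t]
    X[, t] <- xt
    if (p > 1) state <- c(xt, state[seq_len(m * (p - 1))]) else state <- as.numeric(xt)
  }
  out <- X[, (burn + 1):ntot, drop = FALSE]
  rownames(out) <- model@channelLabels
  out
}

#' Draw one subject's SPECT profile
#'
#' Independent Gaussian draws per region, truncated at zero by redraw (not
#' clipping), which keeps the means unbiased for small standard deviations.
#'
#' @param means named or unnamed 46-vector of regional means (ratio units).
#' @param sd per-region standard deviations (length 46 or scalar).
#' @param seed integer seed.
#' @return A \linkS4class{SPECTProfile}.
#' @export
generateSubjectSPECT <- function(means, sd, seed) {
  if (length(means) != 46L) stop("means must have length 46")
  if (length(sd) == 1L) sd <- rep(sd, 46L)
  if (length(sd) != 46L) stop("sd must have length 46 (or be scalar)")
  if (any(sd < 0)) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  v <- stats::rnorm(46, mean = means, sd = sd)
  for (r in seq_len(100)) {
    bad <- v <= 0
    if (!any(bad)) break
    v[bad] <- stats::rnorm(sum(bad), mean = means[bad], sd = sd[bad])
  }
  if (any(v <= 0))
    stop("could not draw positive perfusion ratios; check means/sd")
  SPECTProfile(as.numeric(v))
}

#' Generate a full synthetic cohort
#'
#' Honors the per-group subject counts; every subject's EEG and SPECT seeds
#' derive deterministically from the cohort seed, so identical CohortSpecs
#' yield identical cohorts.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return List of \linkS4class{Subject}.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  nSamples <- round(spec@samplingRate * spec@duration)
  subjects <- list()
  idx <- 0L
  for (g in spec@groups) {
    for (s in seq_len(g@nSubjects)) {
      idx <- idx + 1L
      eeg <- tryCatch(
        generateSubjectEEG(g@mvarTemplate, g@subjectJitter, nSamples,
                           .deriveSeed(spec@seed, 2L * idx)),
        error = function(e) stop(sprintf("group %s, subject %d: %s", g@name,
                                         s, conditionMessage(e))))
      spect <- generateSubjectSPECT(g@spectMeans, g@spectSd,
                                    .deriveSeed(spec@seed, 2L * idx + 1L))
      subjects[[idx]] <- new("Subject",
                             id = sprintf("%s_%03d", g@name, s),
                             group = g@name, eeg = eeg, spect = spect)
    }
  }
  subjects
}

#' Default group specifications emulating the study cohort
#'
#' Four diagnostic groups (aSCC, aMCI, AD, DCI) with the published sizes
#' 41/71/39/69, 17 channels at 200 Hz, group-dependent directed coupling in
#' the low-frequency bands and group-dependent regional perfusion means.
#' Coupling and perfusion effect sizes are package choices (the study reports
#' none); see the methods vignette.
#'
#' @param m channel count (default 17; smaller values keep the couplings
#'   within range).
#' @param order generator order (default 5).
#' @param nSubjects named sizes (default c(aSCC = 41, aMCI = 71, AD = 39,
#'   DCI = 69)).
#' @param couplingDelta group-difference in directed low-frequency coupling
#'   strength (default 0.25).
#' @param spectShift perfusion reduction applied to AD temporoparietal
#'   regions (default 0.15 ratio units).
#' @param spectSd per-region SD (default 0.05).
#' @param jitter per-subject coefficient jitter (default 0.05).
#' @return List of four \linkS4class{GroupSpec}.
#' @export
defaultGroupSpecs <- function(m = 17, order = 5,
                              nSubjects = c(aSCC = 41, aMCI = 71, AD = 39,
                                            DCI = 69),
                              couplingDelta = 0.25, spectShift = 0.15,
                              spectSd = 0.05, jitter = 0.05) {
  labels <- if (m == 17) channelLabels17() else paste0("ch", seq_len(m))
  regions <- spectRegionNames()
  baseMeans <- stats::setNames(rep(1, 46), regions)
  adRegions <- grep("parietotemporal|temporal_lobe|temporal_pole",
                    regions, value = TRUE)
  mciRegions <- grep("medial_temporal", regions, value = TRUE)
  dciRegions <- grep("cingulate", regions, value = TRUE)

  osc <- list(freq = 10, damping = 0.6, strength = 0.5)
  cp <- function(extra) {
    # shared frontal->posterior delta/theta coupling plus a group-specific term
    c(list(list(source = 1, sink = min(5, m), lag = 1, value = 0.2)), extra)
  }
  tpl <- function(extraCouplings) {
    mvarTemplate(m, order, diagCoef = 0.35, oscillation = osc,
                 couplings = cp(extraCouplings), samplingRate = 200,
                 channelLabels = labels)
  }
  mk <- function(name, extraCouplings, meanShift) {
    means <- baseMeans
    means[names(meanShift)] <- means[names(meanShift)] + meanShift
    GroupSpec(name, nSubjects[[name]], tpl(extraCouplings), means,
              spectSd = spectSd, subjectJitter = jitter)
  }
  src <- 2; snk <- min(4, m)
  list(
    mk("aSCC", list(), stats::setNames(numeric(0), character(0))),
    mk("aMCI", list(list(source = src, sink = snk, lag = 1,
                         value = couplingDelta / 2)),
       stats::setNames(rep(-spectShift / 3, length(mciRegions)), mciRegions)),
    mk("AD", list(list(source = src, sink = snk, lag = 1,
                       value = couplingDelta)),
       stats::setNames(rep(-spectShift, length(adRegions)), adRegions)),
    mk("DCI", list(list(source = snk, sink = src, lag = 1,
                        value = couplingDelta / 2)),
       stats::setNames(rep(-spectShift / 2, length(dciRegions)), dciRegions))
  )
}
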
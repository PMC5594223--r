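.edfPad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a multichannel signal to EDF
#'
#' Minimal 16-bit EDF writer: one data record holding the whole signal,
#' per-channel symmetric physical scaling to the digital range -32767..32767.
#'
#' @param signal channels x samples matrix.
#' @param path output file.
#' @param samplingRate Hz.
#' @param channelLabels channel names (default from rownames).
#' @return The path, invisibly.
#' @export
writeEDF <- function(signal, path, samplingRate = 200,
                     channelLabels = rownames(signal)) {
  m <- nrow(signal); n <- ncol(signal)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  amax <- apply(abs(signal), 1, max)
  amax[amax == 0] <- 1
  dig <- round(signal / amax * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("synthetic subject", 80),
    .edfPad("eegspect export", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (1 + m), 8), .edfPad("", 44),
    .edfPad(1, 8), .edfPad(format(n / samplingRate, digits = 8), 8),
    .edfPad(m, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(channelLabels, .edfPad, "", width = 16),
    rep(.edfPad("", 80), m),                      # transducer
    rep(.edfPad("uV", 8), m),                     # physical dimension
    vapply(-amax, function(v) .edfPad(format(v, digits = 7), 8), ""),
    vapply(amax, function(v) .edfPad(format(v, digits = 7), 8), ""),
    rep(.edfPad(-32767, 8), m),
    rep(.edfPad(32767, 8), m),
    rep(.edfPad("", 80), m),                      # prefiltering
    rep(.edfPad(n, 8), m),
    rep(.edfPad("", 32), m))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (ch in seq_len(m))
    writeBin(as.integer(dig[ch, ]), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a multichannel signal from EDF
#'
#' Reads an EDF file, verifies the sampling rate, reorders the channels to
#' the expected canonical order and drops extra channels.
#'
#' @param path EDF file.
#' @param expectedLabels canonical channel order to return (default the
#'   17-channel montage); NULL keeps the file order.
#' @param expectedFs expected sampling rate; mismatch is an error unless
#'   \code{fsOverride}.
#' @param fsOverride accept a differing sampling rate.
#' @return channels x samples matrix with attributes \code{samplingRate}.
#' @export
readEDF <- function(path, expectedLabels = channelLabels17(),
                    expectedFs = 200, fsOverride = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                      # version
  readChar(con, 160, useBytes = TRUE)                    # patient + recording
  readChar(con, 16, useBytes = TRUE)                     # date + time
  readChar(con, 8, useBytes = TRUE)                      # header bytes
  readChar(con, 44, useBytes = TRUE)                     # reserved
  nRec <- as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  recDur <- as.numeric(trimws(readChar(con, 8, useBytes = TRUE)))
  m <- as.integer(trimws(readChar(con, 4, useBytes = TRUE)))
  labels <- trimws(vapply(seq_len(m), function(i)
    readChar(con, 16, useBytes = TRUE), ""))
  readChar(con, 80 * m, useBytes = TRUE)                 # transducer
  readChar(con, 8 * m, useBytes = TRUE)                  # physical dim
  pmin <- as.numeric(trimws(vapply(seq_len(m), function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  pmax <- as.numeric(trimws(vapply(seq_len(m), function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(m), function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(m), function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  readChar(con, 80 * m, useBytes = TRUE)                 # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(m), function(i)
    readChar(con, 8, useBytes = TRUE), "")))
  readChar(con, 32 * m, useBytes = TRUE)                 # reserved

  x <- matrix(0, m, spr[1] * nRec)
  for (r in seq_len(nRec)) {
    for (ch in seq_len(m)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) /
        (dmax[ch] - dmin[ch]) + pmin[ch]
      x[ch, (r - 1) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  rownames(x) <- labels
  fs <- spr[1] / recDur
  if (!is.null(expectedLabels)) {
    missing <- setdiff(expectedLabels, labels)
    if (length(missing))
      stop("EDF missing canonical channel(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(labels, expectedLabels)
    if (length(extra))
      message("dropping extra channel(s): ", paste(extra, collapse = ", "))
    x <- x[expectedLabels, , drop = FALSE]
  }
  if (!is.null(expectedFs) && abs(fs - expectedFs) > 1e-6 * expectedFs) {
    if (!fsOverride)
      stop(sprintf("sampling rate %g Hz differs from expected %g Hz", fs,
                   expectedFs))
    message(sprintf("accepting sampling rate %g Hz (override)", fs))
  }
  attr(x, "samplingRate") <- fs
  x
}

#' Write a cohort to disk
#'
#' One EDF file per subject, a CSV of SPECT profiles and a JSON manifest with
#' the generation parameters.
#'
#' @param cohort list of \linkS4class{Subject}.
#' @param dir output directory (created if needed).
#' @param samplingRate Hz stored in the EDFs.
#' @param seed optional seed recorded in the manifest.
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, samplingRate = 200, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort, function(s) {
    f <- file.path(dir, paste0(s@id, ".edf"))
    writeEDF(s@eeg, f, samplingRate = samplingRate)
    basename(f)
  }, "")
  writeSPECTCSV(cohort, file.path(dir, "spect.csv"))
  manifest <- list(
    samplingRate = samplingRate,
    nChannels = nrow(cohort[[1]]@eeg),
    nSamples = ncol(cohort[[1]]@eeg),
    seed = seed,
    subjects = data.frame(
      id = vapply(cohort, slot, "", "id"),
      group = vapply(cohort, slot, "", "group"),
      edf = files, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory.
#' @param expectedLabels canonical channel order (NULL keeps file order).
#' @return List of \linkS4class{Subject}.
#' @export
readCohort <- function(dir, expectedLabels = NULL) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  spect <- readSPECTCSV(file.path(dir, "spect.csv"))
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    row <- manifest$subjects[i, ]
    eeg <- readEDF(file.path(dir, row$edf), expectedLabels = expectedLabels,
                   expectedFs = manifest$samplingRate)
    sp <- spect[spect$subject_id == row$id, spectRegionNames()]
    new("Subject", id = row$id, group = row$group, eeg = eeg,
        spect = SPECTProfile(unlist(sp)))
  })
  subjects
}

.pairLabel <- function(pair) paste(pair, collapse = "-")

#' Run all pairwise comparisons across scenarios
#'
#' End-to-end orchestration: computes (or accepts) the cohort feature table,
#' then runs every pairwise group comparison under every requested scenario.
#' The merged scenarios re-use the optimized per-measure selections of the
#' eeg_single runs of the same pair (and the optimized SPECT selection for
#' eeg_merged_spect), as the scenario definitions require; they are run
#' automatically after their dependencies. Each (pair, scenario) run gets an
#' independent seed derived from the configuration seed, so a rerun with an
#' identical manifest reproduces the report exactly.
#'
#' @param cohort list of \linkS4class{Subject} (ignored when
#'   \code{featureSet} is given).
#' @param scenarios subset of \code{\link{scenarioLabels}} to run.
#' @param config a \linkS4class{SelectionConfig}.
#' @param measures connectivity measures for the EEG scenarios.
#' @param order MVAR analysis order.
#' @param frequencies analysis grid.
#' @param featureSet optional precomputed table from
#'   \code{\link{cohortFeatureSet}}.
#' @param groupOrder optional group ordering defining the pair columns.
#' @param outputDir optional directory for the report CSV, the JSON feature
#'   log and the provenance file.
#' @return List with \code{results} (nested: pair, then scenario key),
#'   \code{table} (the report data.frame) and \code{scenarios}.
#' @export
runAll <- function(cohort = NULL, scenarios = scenarioLabels(),
                   config = SelectionConfig(),
                   measures = connectivityMeasures(), order = 100,
                   frequencies = 2:80, featureSet = NULL, groupOrder = NULL,
                   outputDir = NULL) {
  scenarios <- match.arg(scenarios, scenarioLabels(), several.ok = TRUE)
  if (is.null(featureSet)) {
    if (is.null(cohort)) stop("either a cohort or a featureSet is required")
    needGraph <- any(c("eeg_graph", "eeg_graph_spect") %in% scenarios)
    featureSet <- cohortFeatureSet(cohort, order = order,
                                   frequencies = frequencies,
                                   measures = measures,
                                   includeGraph = needGraph)
  }
  groups <- unique(SummarizedExperiment::colData(featureSet)$group)
  if (!is.null(groupOrder)) groups <- groupOrder[groupOrder %in% groups]
  if (length(groups) < 2) stop("at least 2 groups required")
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  needSingle <- any(c("eeg_single", "eeg_single_spect", "eeg_merged",
                      "eeg_merged_spect") %in% scenarios)
  needSpectRun <- any(c("spect", "eeg_merged_spect") %in% scenarios)

  results <- list()
  runIdx <- 0L
  runOne <- function(fs, pair, scen) {
    runIdx <<- runIdx + 1L
    cfg <- config
    cfg@seed <- .deriveSeed(config@seed, runIdx)
    runComparison(fs, pair, cfg, scenario = scen)
  }
  for (pair in pairs) {
    pl <- .pairLabel(pair)
    res <- list()
    singleSel <- list()
    if (needSingle) {
      for (me in measures) {
        r <- runOne(buildInitialVector(featureSet, "eeg_single", me), pair,
                    paste0("eeg_single:", me))
        singleSel[[me]] <- selectedFeatures(r)
        if ("eeg_single" %in% scenarios) res[[paste0("eeg_single:", me)]] <- r
      }
    }
    spectRes <- NULL
    if (needSpectRun) {
      spectRes <- runOne(buildInitialVector(featureSet, "spect"), pair,
                         "spect")
      if ("spect" %in% scenarios) res[["spect"]] <- spectRes
    }
    if ("eeg_single_spect" %in% scenarios) {
      for (me in measures)
        res[[paste0("eeg_single_spect:", me)]] <-
          runOne(buildInitialVector(featureSet, "eeg_single_spect", me),
                 pair, paste0("eeg_single_spect:", me))
    }
    if ("eeg_merged" %in% scenarios)
      res[["eeg_merged"]] <-
        runOne(mergeOptimized(singleSel, featureSet), pair, "eeg_merged")
    if ("eeg_merged_spect" %in% scenarios)
      res[["eeg_merged_spect"]] <-
        runOne(mergeOptimized(c(singleSel,
                                list(spect = selectedFeatures(spectRes))),
                              featureSet), pair, "eeg_merged_spect")
    if ("eeg_graph" %in% scenarios)
      res[["eeg_graph"]] <-
        runOne(buildInitialVector(featureSet, "eeg_graph"), pair,
               "eeg_graph")
    if ("eeg_graph_spect" %in% scenarios)
      res[["eeg_graph_spect"]] <-
        runOne(buildInitialVector(featureSet, "eeg_graph_spect"), pair,
               "eeg_graph_spect")
    results[[pl]] <- res
  }
  tab <- reportTable(results)
  out <- list(results = results, table = tab, scenarios = scenarios)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outputDir, "report.csv"))
    log <- lapply(results, function(res) lapply(res, function(r)
      list(scenario = r@scenario,
           overall = r@overallAccuracy,
           perGroup = as.list(r@perGroupAccuracy),
           chance = r@chanceLevel,
           features = r@finalFeatures$id,
           perFoldSelections = r@perFoldSelections)))
    jsonlite::write_json(log, file.path(outputDir, "features.json"),
                         auto_unbox = TRUE, digits = NA)
    prov <- list(package = "eegspect",
                 version = as.character(utils::packageVersion("eegspect")),
                 seed = config@seed, scenarios = scenarios,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(prov, file.path(outputDir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Report table of a \code{\link{runAll}} result set
#'
#' Rows are scenario keys, columns group pairs, cells
#' "overall (acc1/acc2)"; a final row carries the maximum-chance level
#' (2 decimals, half away from zero).
#'
#' @param results nested result list from \code{\link{runAll}}.
#' @return data.frame of formatted cells.
#' @export
reportTable <- function(results) {
  pairNames <- names(results)
  scenKeys <- unique(unlist(lapply(results, names)))
  fmt <- function(r) sprintf("%.2f (%.2f/%.2f)", r@overallAccuracy,
                             r@perGroupAccuracy[1], r@perGroupAccuracy[2])
  tab <- vapply(pairNames, function(pl) {
    vapply(scenKeys, function(k) {
      r <- results[[pl]][[k]]
      if (is.null(r)) NA_character_ else fmt(r)
    }, "")
  }, character(length(scenKeys)))
  tab <- matrix(tab, nrow = length(scenKeys), ncol = length(pairNames),
                dimnames = list(scenKeys, pairNames))
  chance <- vapply(pairNames, function(pl) {
    r <- results[[pl]][[1]]
    sprintf("%.2f", .roundHalfUp(r@chanceLevel, 2))
  }, "")
  as.data.frame(rbind(tab, `chance` = chance), stringsAsFactors = FALSE)
}

# round half away from zero (matches the published table formatting)
.roundHalfUp <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
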
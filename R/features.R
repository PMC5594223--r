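#' The seven feature-vector scenarios
#'
#' Closed vocabulary of scenario labels: \code{eeg_single} (one connectivity
#' measure, all channel pairs and bands), \code{spect} (the 46 perfusion
#' ratios), \code{eeg_single_spect} (their concatenation),
#' \code{eeg_merged} (union of the optimized per-measure selections),
#' \code{eeg_merged_spect} (that union plus the optimized SPECT selection),
#' \code{eeg_graph} (5 graph metrics x 14 measures x 5 bands = 350 features)
#' and \code{eeg_graph_spect}.
#'
#' @return Character vector of the seven labels.
#' @export
scenarioLabels <- function() {
  c("eeg_single", "spect", "eeg_single_spect", "eeg_merged",
    "eeg_merged_spect", "eeg_graph", "eeg_graph_spect")
}

.eegDescriptors <- function(measures, labels) {
  bands <- names(bandDefinitions())
  m <- length(labels)
  rows <- lapply(measures, function(me) {
    lapply(bands, function(b) {
      data.frame(id = paste0("eeg|", me, "|", b, "|",
                             rep(labels, each = m), ">",
                             rep(labels, m)),
                 modality = "EEG", measure = me, band = b,
                 source = rep(labels, each = m), sink = rep(labels, m),
                 metric = NA_character_, region = NA_character_,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

.graphDescriptors <- function(measures) {
  bands <- names(bandDefinitions())
  metrics <- graphMetricNames()
  grid <- expand.grid(metric = metrics, band = bands, measure = measures,
                      stringsAsFactors = FALSE)
  data.frame(id = paste0("graph|", grid$measure, "|", grid$band, "|",
                         grid$metric),
             modality = "GRAPH", measure = grid$measure, band = grid$band,
             source = NA_character_, sink = NA_character_,
             metric = grid$metric, region = NA_character_,
             stringsAsFactors = FALSE)
}

# per-subject flat feature vector in the fixed descriptor order
.subjectFeatureValues <- function(banded, spect, measures, includeGraph) {
  eeg <- unlist(lapply(measures, function(me) {
    v <- banded[[me]]@values           # m x m x 5, [sink, source, band]
    # descriptor order: band slow, then source (column) slow / sink fast
    as.vector(vapply(seq_len(dim(v)[3]),
                     function(b) as.vector(v[, , b]),
                     numeric(dim(v)[1]^2)))
  }), use.names = FALSE)
  out <- eeg
  if (includeGraph) {
    g <- unlist(lapply(measures, function(me) {
      v <- banded[[me]]@values
      vapply(seq_len(dim(v)[3]), function(b) graphSummary(v[, , b]),
             numeric(5))
    }), use.names = FALSE)
    nbad <- sum(!is.finite(g))
    if (nbad) {
      message(sprintf("imputing %d degenerate graph metric(s) to 0", nbad))
      g[!is.finite(g)] <- 0
    }
    out <- c(out, g)
  }
  c(out, unname(spect@values))
}

#' Compute the complete feature table of a cohort
#'
#' Fits an MVAR model per subject, derives the band-averaged connectivity
#' tensors of the requested measures, the global graph summaries per
#' measure x band, and appends the SPECT profile. The result is a
#' \code{SummarizedExperiment} with one row per feature (rowData carries the
#' full feature descriptor: modality, measure, band, source, sink, metric,
#' region) and one column per subject (colData carries the group label).
#' All scenario vectors are row subsets of this table.
#'
#' @param cohort list of \linkS4class{Subject}.
#' @param order MVAR analysis order (production default 100; tests use
#'   smaller orders, correctness is order-independent).
#' @param frequencies analysis grid (default 2:80).
#' @param measures measures to compute (default all 14).
#' @param includeGraph compute the graph-metric features (default TRUE).
#' @return A \code{SummarizedExperiment}.
#' @export
cohortFeatureSet <- function(cohort, order = 100, frequencies = 2:80,
                             measures = connectivityMeasures(),
                             includeGraph = TRUE) {
  stopifnot(length(cohort) > 0)
  labels <- rownames(cohort[[1]]@eeg)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(cohort[[1]]@eeg)))
  desc <- .eegDescriptors(measures, labels)
  if (includeGraph) desc <- rbind(desc, .graphDescriptors(measures))
  desc <- rbind(desc, spectVector(cohort[[1]]@spect)$descriptors)

  vals <- vapply(cohort, function(s) {
    model <- fitMVAR(s@eeg, order,
                     samplingRate = attr(s@eeg, "samplingRate") %||% 200,
                     channelLabels = labels)
    banded <- computeAllMeasures(model, frequencies)
    .subjectFeatureValues(banded[measures], s@spect, measures, includeGraph)
  }, numeric(nrow(desc)))
  colnames(vals) <- vapply(cohort, slot, "", "id")
  rownames(vals) <- desc$id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals),
    rowData = S4Vectors::DataFrame(desc),
    colData = S4Vectors::DataFrame(
      group = vapply(cohort, slot, "", "group"),
      row.names = colnames(vals)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the initial feature vector of a scenario
#'
#' Subsets the cohort feature table to the rows of the requested scenario.
#' The merged scenarios depend on earlier selection runs and are assembled
#' with \code{\link{mergeOptimized}} instead.
#'
#' @param featureSet \code{SummarizedExperiment} from
#'   \code{\link{cohortFeatureSet}}.
#' @param scenario one of \code{"eeg_single"}, \code{"spect"},
#'   \code{"eeg_single_spect"}, \code{"eeg_graph"},
#'   \code{"eeg_graph_spect"}.
#' @param measure connectivity measure (required for the eeg_single
#'   scenarios).
#' @return Row-subset \code{SummarizedExperiment}.
#' @export
buildInitialVector <- function(featureSet, scenario, measure = NULL) {
  scenario <- match.arg(scenario,
                        setdiff(scenarioLabels(),
                                c("eeg_merged", "eeg_merged_spect")))
  rd <- SummarizedExperiment::rowData(featureSet)
  pick <- switch(scenario,
    eeg_single = {
      if (is.null(measure)) stop("eeg_single requires a measure")
      rd$modality == "EEG" & rd$measure == measure
    },
    spect = rd$modality == "SPECT",
    eeg_single_spect = {
      if (is.null(measure)) stop("eeg_single_spect requires a measure")
      (rd$modality == "EEG" & rd$measure == measure) | rd$modality == "SPECT"
    },
    eeg_graph = rd$modality == "GRAPH",
    eeg_graph_spect = rd$modality %in% c("GRAPH", "SPECT"))
  if (!any(pick)) stop(sprintf("no features available for scenario %s%s",
                               scenario,
                               if (is.null(measure)) "" else paste0(" / ", measure)))
  featureSet[pick, ]
}

#' Merge optimized feature selections into a new initial vector
#'
#' Deduplicated union (by feature id, preserving first occurrence) of the
#' final selected descriptor tables from earlier runs; the result is the
#' initial vector of a fresh selection run.
#'
#' @param selectedList list of descriptor data.frames (the
#'   \code{selectedFeatures} of earlier \linkS4class{ComparisonResult}s).
#' @param featureSet the cohort feature table to subset.
#' @return Row-subset \code{SummarizedExperiment}.
#' @export
mergeOptimized <- function(selectedList, featureSet) {
  ids <- unlist(lapply(selectedList, function(d) d$id), use.names = FALSE)
  ids <- ids[!duplicated(ids)]
  if (!length(ids)) stop("no features in the merged selection")
  idx <- match(ids, rownames(featureSet))
  if (anyNA(idx)) stop("merged selection contains unknown feature ids")
  featureSet[idx, ]
}
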
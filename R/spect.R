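#' Canonical SPECT region names
#'
#' The 46 regions of the perfusion profile: 22 bilateral regions (left and
#' right interleaved per region), then the pons+midbrain region and the
#' remaining-subcortical region.
#'
#' @return Character vector of length 46.
#' @export
spectRegionNames <- function() {
  base <- c("cerebellar_cortex", "cerebellar_white_matter",
            "nucleus_lentiformis", "nucleus_caudatus", "thalamus",
            "sensorimotor_cortex", "occipital_cortex",
            "superior_parietal_lobule", "anterior_dorsal_frontal",
            "posterior_dorsal_frontal", "anterior_orbital_frontal",
            "posterior_orbital_cortex", "parietotemporal_cortex",
            "medial_temporal_lobe", "lateral_temporal_lobe",
            "posterior_temporal_lobe", "temporal_pole", "insular_cortex",
            "anterior_cingulate", "posterior_cingulate",
            "anterior_subcortical", "posterior_subcortical")
  c(paste0(rep(base, each = 2), c("_left", "_right")),
    "pons_midbrain", "other_subcortical")
}

#' Construct a SPECT perfusion profile
#'
#' @param values numeric vector of length 46. If unnamed, the canonical
#'   region order is assumed; if named, names must match the canonical list.
#' @return A \linkS4class{SPECTProfile}.
#' @export
SPECTProfile <- function(values) {
  if (is.null(names(values))) {
    if (length(values) != 46L) stop("SPECT profile must have 46 values")
    names(values) <- spectRegionNames()
  } else {
    unknown <- setdiff(names(values), spectRegionNames())
    if (length(unknown))
      stop("unknown SPECT region(s): ", paste(unknown, collapse = ", "))
    values <- values[spectRegionNames()]
  }
  new("SPECTProfile", values = values)
}

#' Cerebellar count normalization
#'
#' Converts raw regional count rates to cerebellar perfusion ratios
#' ratio_i = count_i / cerebellar_count. Provided for real-data ingestion;
#' the synthetic generator draws directly in ratio space.
#'
#' @param regionCounts 46-vector of regional count rates.
#' @param cerebellarCount positive reference count rate.
#' @return A \linkS4class{SPECTProfile}.
#' @export
normalizeCounts <- function(regionCounts, cerebellarCount) {
  if (length(cerebellarCount) != 1L || !is.finite(cerebellarCount) ||
      cerebellarCount <= 0)
    stop("cerebellar reference count must be a positive scalar")
  SPECTProfile(regionCounts / cerebellarCount)
}

#' SPECT feature-vector fragment
#'
#' @param profile a \linkS4class{SPECTProfile}.
#' @return list with \code{values} (length 46) and \code{descriptors}
#'   (data.frame with modality and region columns).
#' @export
spectVector <- function(profile) {
  stopifnot(is(profile, "SPECTProfile"))
  regions <- spectRegionNames()
  list(values = unname(profile@values),
       descriptors = data.frame(
         id = paste0("spect|", regions),
         modality = "SPECT", measure = NA_character_, band = NA_character_,
         source = NA_character_, sink = NA_character_,
         metric = NA_character_, region = regions,
         stringsAsFactors = FALSE))
}

#' Read SPECT profiles from CSV
#'
#' Expects columns subject_id, group, then the 46 canonical region names.
#' Unknown or missing region columns are rejected.
#'
#' @param path CSV path.
#' @return data.frame with subject_id, group and one column per region.
#' @export
readSPECTCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", spectRegionNames())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SPECT CSV missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    stop("SPECT CSV has unknown column(s): ", paste(extra, collapse = ", "))
  df[, need]
}

#' Write SPECT profiles of a cohort to CSV
#'
#' @param cohort list of \linkS4class{Subject}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSPECTCSV <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    cbind(data.frame(subject_id = s@id, group = s@group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(s@spect@values), check.names = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
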
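#' Desikan-Killiany cortical region labels
#'
#' Returns the canonical ordered list of the 68 cortical regions of the
#' Desikan-Killiany parcellation: 34 left-hemisphere labels followed by the
#' 34 matching right-hemisphere labels, each prefixed `lh.` / `rh.`.  The
#' within-hemisphere order is the standard FreeSurfer `aparc` order.  All
#' connectivity matrices produced by this package carry these labels as
#' dimnames, and the readers refuse files whose label order deviates, which
#' guards against silent atlas-ordering mismatches between tools.
#'
#' @return Character vector of length 68; stable across runs.
#' @examples
#' labs <- dk_region_labels()
#' length(labs)   # 68
#' @export
dk_region_labels <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
  c(paste0("lh.", base), paste0("rh.", base))
}

#' Validate a label vector against the shipped atlas order
#'
#' For 68-region data the labels must match [dk_region_labels()] exactly and
#' in order; the first mismatching region is named in the error.  Shorter
#' (test-scale) parcellations are accepted as-is.
#'
#' @param labels character vector of region labels.
#' @return `labels`, invisibly, if valid.
#' @export
check_region_labels <- function(labels) {
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (length(labels) == length(dk_region_labels())) {
    ref <- dk_region_labels()
    bad <- which(labels != ref)
    if (length(bad)) {
      stop(sprintf(
        "region label order mismatch at position %d: expected '%s', got '%s'",
        bad[1], ref[bad[1]], labels[bad[1]]))
    }
  }
  invisible(labels)
}
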
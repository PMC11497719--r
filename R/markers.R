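#' Candidate plasma markers
#'
#' The four plasma analytes considered for the diagnostic panel:
#' the Abeta42/40 ratio (unitless), P-tau181 (pg/mL), GFAP (pg/mL) and
#' age-corrected NfL (pg/mL before correction; the identity correction
#' leaves it in pg/mL).
#'
#' @return Character vector of marker column names, in canonical order.
#' @export
candidate_markers <- function() {
  c("abeta_ratio", "ptau181", "gfap", "nfl_age_corrected")
}

#' Abnormal direction of each marker
#'
#' Lower Abeta42/40 indicates amyloid pathology; for all other markers
#' higher concentrations are abnormal.
#'
#' @return Named character vector, values `"higher_abnormal"` or
#'   `"lower_abnormal"`.
#' @export
marker_directions <- function() {
  c(abeta_ratio       = "lower_abnormal",
    ptau181           = "higher_abnormal",
    gfap              = "higher_abnormal",
    nfl               = "higher_abnormal",
    nfl_age_corrected = "higher_abnormal")
}

#' Display labels for markers
#' @param markers character vector of marker names.
#' @return character vector of display labels.
#' @export
marker_labels <- function(markers) {
  lab <- c(abeta_ratio = "Abeta42/40", ptau181 = "P-tau181",
           gfap = "GFAP", nfl = "NfL", nfl_age_corrected = "NfL (age-corr.)")
  out <- lab[markers]
  out[is.na(out)] <- markers[is.na(out)]
  unname(out)
}

# raw concentration columns that must be strictly positive when present
.raw_marker_cols <- function() c("abeta_ratio", "ptau181", "gfap", "nfl")

.diagnostic_groups <- function() {
  c("SCD", "MCI", "AD_dementia", "FTD", "DLB", "control_other")
}
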
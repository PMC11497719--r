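#' The six clinical questions
#'
#' The diagnostic questions the panel is developed for, each a case/control
#' contrast with an inclusion filter and a positive class:
#'
#' * `Q1_abeta_all` - amyloid-positive vs amyloid-negative across all
#'   clinical stages (SCD, MCI, AD dementia, FTD, DLB).
#' * `Q2_abeta_predementia` - amyloid-positive vs -negative in the
#'   pre-dementia stages (SCD and MCI only).
#' * `Q3_ad_vs_ftd` - AD dementia (positive) vs FTD.
#' * `Q4_ctrl_vs_ftd` - FTD (positive) vs controls (amyloid-negative SCD).
#' * `Q5_ad_vs_dlb` - AD dementia (positive) vs DLB.
#' * `Q6_ctrl_vs_dlb` - DLB (positive) vs controls (amyloid-negative SCD).
#'
#' Subjects with unknown amyloid status are excluded wherever amyloid
#' defines the outcome or the control arm (Q1, Q2 and the control arms of
#' Q4/Q6); `control_other` subjects are excluded from all six questions.
#'
#' @param id question identifier, e.g. `"Q2_abeta_predementia"` (the short
#'   forms `"Q1"`..`"Q6"` are also accepted).
#' @return A `clinical_question` object: a list with `question_id`,
#'   `label`, and the predicate functions `include` and `positive`
#'   operating on a cohort data.frame.
#' @export
clinical_question <- function(id) {
  ids <- names(.question_registry)
  if (id %in% paste0("Q", 1:6)) id <- ids[match(id, substr(ids, 1, 2))]
  if (!id %in% ids)
    stop("unknown question id; expected one of: ", paste(ids, collapse = ", "))
  q <- .question_registry[[id]]
  structure(list(question_id = id, label = q$label,
                 include = q$include, positive = q$positive),
            class = "clinical_question")
}

#' @rdname clinical_question
#' @export
clinical_questions <- function() {
  qs <- lapply(names(.question_registry), clinical_question)
  names(qs) <- names(.question_registry)
  qs
}

.staged <- c("SCD", "MCI", "AD_dementia", "FTD", "DLB")

.question_registry <- list(
  Q1_abeta_all = list(
    label = "Abeta+ vs Abeta- in the total cohort",
    include = function(d) d$group %in% .staged & d$amyloid != "unknown",
    positive = function(d) d$amyloid == "positive"),
  Q2_abeta_predementia = list(
    label = "Abeta+ vs Abeta- in SCD + MCI",
    include = function(d) d$group %in% c("SCD", "MCI") & d$amyloid != "unknown",
    positive = function(d) d$amyloid == "positive"),
  Q3_ad_vs_ftd = list(
    label = "AD dementia vs FTD",
    include = function(d) d$group %in% c("AD_dementia", "FTD"),
    positive = function(d) d$group == "AD_dementia"),
  Q4_ctrl_vs_ftd = list(
    label = "Controls (Abeta- SCD) vs FTD",
    include = function(d) (d$group == "SCD" & d$amyloid == "negative") |
      d$group == "FTD",
    positive = function(d) d$group == "FTD"),
  Q5_ad_vs_dlb = list(
    label = "AD dementia vs DLB",
    include = function(d) d$group %in% c("AD_dementia", "DLB"),
    positive = function(d) d$group == "AD_dementia"),
  Q6_ctrl_vs_dlb = list(
    label = "Controls (Abeta- SCD) vs DLB",
    include = function(d) (d$group == "SCD" & d$amyloid == "negative") |
      d$group == "DLB",
    positive = function(d) d$group == "DLB"))

#' @export
print.clinical_question <- function(x, ...) {
  cat(x$question_id, "-", x$label, "\n")
  invisible(x)
}

#' Subset a cohort for a clinical question
#'
#' Applies the question's inclusion filter and attaches the binary
#' `outcome` column (1 for the positive class). Errors on an empty subset
#' or a subset containing a single outcome class, which downstream fitting
#' cannot use.
#'
#' @param x a [cohort()].
#' @param question a [clinical_question()] or a question id.
#' @return A data.frame of included subjects with an `outcome` column and
#'   a `question` attribute.
#' @export
subset_for_question <- function(x, question) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(question)) question <- clinical_question(question)
  stopifnot(inherits(question, "clinical_question"))
  d <- as.data.frame(x)
  keep <- question$include(d)
  keep[is.na(keep)] <- FALSE
  sub <- d[keep, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("empty subset for ", question$question_id)
  sub$outcome <- as.integer(question$positive(sub))
  if (length(unique(sub$outcome)) < 2)
    stop("subset for ", question$question_id,
         " contains a single outcome class")
  rownames(sub) <- NULL
  attr(sub, "question") <- question$question_id
  sub
}
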
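#' Construct and validate a cohort table
#'
#' A cohort is a `data.frame` with one row per subject and the columns
#' `subject_id`, `age` (years), `sex` (`female`/`male`/`unknown`),
#' `group` (`SCD`, `MCI`, `AD_dementia`, `FTD`, `DLB`, `control_other`),
#' `amyloid` (`positive`/`negative`/`unknown`) and the plasma markers
#' `abeta_ratio`, `ptau181`, `gfap`, `nfl` (pg/mL; the ratio unitless).
#' Marker cells may be `NA`: subjects with partial marker missingness are
#' retained and counted in the load report, and are dropped per question
#' (complete-case) only at model-fitting time.
#'
#' Validation enforces unique subject ids, strictly positive marker
#' concentrations, `abeta_ratio` in (0, 1), and the recruitment rule that
#' every `AD_dementia` subject carries a positive amyloid status.
#'
#' @param data data.frame with the columns above.
#' @param name cohort name stored as an attribute.
#' @param provenance free-text provenance metadata (lot identifiers, site).
#' @return A validated `cohort` object (a classed data.frame) carrying a
#'   `load_report` attribute with per-column missing counts.
#' @export
cohort <- function(data, name = "cohort", provenance = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("subject_id", "age", "sex", "group", "amyloid",
                .raw_marker_cols())
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(data) == 0) stop("cohort is empty")
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  data$subject_id <- as.character(data$subject_id)
  if (anyNA(data$subject_id) || any(data$subject_id == ""))
    stop("subject_id must be non-missing")
  dup <- unique(data$subject_id[duplicated(data$subject_id)])
  if (length(dup) > 0)
    stop("duplicate subject_id: ", paste(utils::head(dup, 5), collapse = ", "))

  data$sex <- .normalize_level(data$sex, c("female", "male", "unknown"),
                               "unknown", "sex")
  data$amyloid <- .normalize_level(data$amyloid,
                                   c("positive", "negative", "unknown"),
                                   "unknown", "amyloid")
  data$group <- as.character(data$group)
  bad_group <- setdiff(unique(data$group), .diagnostic_groups())
  if (length(bad_group) > 0)
    stop("unknown diagnostic group(s): ", paste(bad_group, collapse = ", "))

  data$age <- as.numeric(data$age)
  if (any(!is.na(data$age) & (data$age <= 0 | data$age >= 120)))
    stop("age must be in (0, 120) years")

  for (m in .raw_marker_cols()) {
    data[[m]] <- as.numeric(data[[m]])
    bad <- !is.na(data[[m]]) & data[[m]] <= 0
    if (any(bad))
      stop("non-positive ", m, " for subject(s): ",
           paste(utils::head(data$subject_id[bad], 5), collapse = ", "))
  }
  bad_ratio <- !is.na(data$abeta_ratio) & data$abeta_ratio >= 1
  if (any(bad_ratio))
    stop("abeta_ratio must lie in (0, 1); offending subject(s): ",
         paste(utils::head(data$subject_id[bad_ratio], 5), collapse = ", "))

  ad_bad <- data$group == "AD_dementia" & data$amyloid != "positive"
  if (any(ad_bad))
    stop("AD_dementia subjects must be amyloid-positive: ",
         paste(utils::head(data$subject_id[ad_bad], 5), collapse = ", "))

  counted <- c("age", "sex", "amyloid", .raw_marker_cols(),
               intersect("nfl_age_corrected", names(data)))
  missing_counts <- vapply(counted, function(col) {
    v <- data[[col]]
    sum(is.na(v) | (is.character(v) & v == "unknown"))
  }, integer(1))

  structure(data,
            class = c("cohort", "data.frame"),
            cohort_name = name,
            provenance = provenance,
            load_report = list(name = name, n = nrow(data),
                               missing = as.list(missing_counts)))
}

.normalize_level <- function(x, levels, na_level, what) {
  x <- tolower(as.character(x))
  x[is.na(x) | x == ""] <- na_level
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0)
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "))
  x
}

#' Read a cohort from a delimited text file
#'
#' @param path path to a delimited text file with one header row; missing
#'   values are empty strings.
#' @param schema optional named character vector mapping canonical column
#'   names (see [cohort()]) to the file's column names, for source files
#'   with site-specific headers. Canonical names not listed are assumed to
#'   appear verbatim.
#' @param sep field separator (default comma).
#' @param name,provenance passed to [cohort()].
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, schema = NULL, sep = ",",
                        name = basename(path), provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "",
                           check.names = FALSE)
  if (!is.null(schema)) {
    missing_map <- setdiff(unname(schema), names(raw))
    if (length(missing_map) > 0)
      stop("mapped column(s) absent from file: ",
           paste(missing_map, collapse = ", "))
    for (canonical in names(schema))
      raw[[canonical]] <- raw[[schema[[canonical]]]]
  }
  keep <- intersect(c("subject_id", "age", "sex", "group", "amyloid",
                      .raw_marker_cols(), "nfl_age_corrected"), names(raw))
  cohort(raw[keep], name = name, provenance = provenance)
}

#' Write a cohort to a delimited text file
#'
#' Missing values are written as empty strings; a round trip through
#' [read_cohort()] is lossless.
#'
#' @param x a `cohort`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  utils::write.table(as.data.frame(x), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Retrieve or write the load report of a cohort
#'
#' The load report counts, per column, the subjects with a missing value
#' (markers, age) or an `unknown` level (sex, amyloid).
#'
#' @param x a `cohort`.
#' @param path optional path; when given the report is written as JSON.
#' @return The load report list, invisibly when `path` is given.
#' @export
load_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort"))
  rep <- attr(x, "load_report")
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", attr(x, "cohort_name"), "-", nrow(x), "subjects\n")
  print(table(group = x$group, amyloid = x$amyloid))
  invisible(x)
}

#' Append age-corrected NfL to a cohort
#'
#' Applies [correct_nfl_for_age()] row-wise and stores the result in the
#' `nfl_age_corrected` column used by the diagnostic models. The default
#' identity specification leaves NfL unchanged (see [age_correction_spec()]).
#'
#' @param x a `cohort`.
#' @param spec an [age_correction_spec()].
#' @return The cohort with an `nfl_age_corrected` column.
#' @export
add_age_corrected_nfl <- function(x, spec = age_correction_spec()) {
  stopifnot(inherits(x, "cohort"))
  ok <- !is.na(x$nfl) & !is.na(x$age)
  out <- rep(NA_real_, nrow(x))
  out[ok] <- correct_nfl_for_age(x$nfl[ok], x$age[ok], spec)
  x$nfl_age_corrected <- out
  x
}
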
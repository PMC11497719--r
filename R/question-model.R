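# internal: maximum-likelihood logistic fit on raw marker units, with
# explicit separation diagnosis so the failure names the culprit marker
.fit_logistic_raw <- function(data, markers) {
  y <- as.integer(data$outcome)
  X <- data[markers]
  for (m in markers) {
    lo <- X[[m]][y == 0]; hi <- X[[m]][y == 1]
    if (max(lo) < min(hi) || min(lo) > max(hi))
      stop("perfect separation on marker ", m)
  }
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(markers, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) stop("singular design matrix")
  list(coefficients = stats::coef(fit), converged = fit$converged,
       glm = fit)
}

.predict_prob <- function(coefficients, newdata) {
  markers <- names(coefficients)[-1]
  lp <- coefficients[1] +
    as.matrix(newdata[markers]) %*% coefficients[-1]
  as.numeric(stats::plogis(lp))
}

#' Logistic regression of a question outcome on plasma markers
#'
#' Maximum-likelihood logistic regression of the 0/1 outcome on the raw
#' (unstandardized) marker values, so the serialized coefficient formula
#' applies directly to pg/mL inputs. Fails with an explicit error when a
#' marker perfectly separates the classes or the design is singular;
#' warns when the subset is smaller than ten events per parameter.
#'
#' @param data question subset with `outcome` and marker columns
#'   (complete cases on the markers are used).
#' @param markers marker column names.
#' @return List with `coefficients` (intercept first), `converged`, the
#'   underlying `glm`, and `n_used`/`n_dropped`.
#' @export
fit_logistic <- function(data, markers) {
  stopifnot("outcome" %in% names(data))
  cc <- stats::complete.cases(data[markers])
  d <- data[cc, , drop = FALSE]
  if (length(unique(d$outcome)) < 2)
    stop("both outcome classes required")
  if (nrow(d) < 10 * (length(markers) + 1))
    warning("fewer than 10 subjects per parameter; estimates unstable")
  fit <- .fit_logistic_raw(d, markers)
  fit$n_used <- nrow(d)
  fit$n_dropped <- sum(!cc)
  fit
}

#' Fit a diagnostic question model
#'
#' The central fitting function: for one clinical question it fits the
#' logistic model combining the panel markers, derives the per-marker
#' Youden thresholds and the three probability thresholds (Youden, 90%
#' sensitivity, 90% specificity) on the full development data, and
#' computes the cross-validated panel ROC-AUC with a DeLong interval.
#' Thresholds are intentionally computed without cross-validation; only
#' the AUC is cross-validated.
#'
#' @param data a [cohort()] (subset internally) or a question subset from
#'   [subset_for_question()].
#' @param question a [clinical_question()] or question id; ignored when
#'   `data` is already a subset.
#' @param markers panel marker columns (default: P-tau181, GFAP and
#'   age-corrected NfL, the diagnostic panel).
#' @param folds,seed cross-validation folds and fold seed.
#' @param zone_convention `"sensitivity_specificity"` (low below the
#'   90%-sensitivity cutoff, high at or above the 90%-specificity cutoff,
#'   indeterminate between) or `"literal"` (low below the 90%-specificity
#'   cutoff, high above the 90%-sensitivity cutoff).
#' @param development_cohort provenance string.
#' @return An object of class `question_model`.
#' @export
fit_question_model <- function(data, question = NULL,
                               markers = c("ptau181", "gfap",
                                           "nfl_age_corrected"),
                               folds = 10, seed = 1,
                               zone_convention = c("sensitivity_specificity",
                                                   "literal"),
                               development_cohort = NULL) {
  zone_convention <- match.arg(zone_convention)
  if (inherits(data, "cohort")) {
    if (is.null(question)) stop("question required with a cohort input")
    if (is.null(development_cohort))
      development_cohort <- attr(data, "cohort_name")
    data <- subset_for_question(data, question)
  }
  stopifnot("outcome" %in% names(data))
  question_id <- attr(data, "question")
  miss <- setdiff(markers, names(data))
  if (length(miss) > 0)
    stop("marker column(s) absent: ", paste(miss, collapse = ", "))

  cc <- stats::complete.cases(data[markers])
  d <- data[cc, , drop = FALSE]
  if (length(unique(d$outcome)) < 2)
    stop("both outcome classes required after complete-case filtering")

  fit <- fit_logistic(d, markers)
  probs <- .predict_prob(fit$coefficients, d[markers])

  dirs <- marker_directions()
  marker_thresholds <- do.call(rbind, lapply(markers, function(m) {
    yt <- youden_threshold(d[[m]], d$outcome, dirs[[m]])
    data.frame(marker = m, cutoff = yt$cutoff, direction = yt$direction,
               sensitivity = yt$sensitivity, specificity = yt$specificity,
               stringsAsFactors = FALSE)
  }))

  prob_thresholds <- probability_thresholds(probs, d$outcome)
  roc <- cv_auc(d, markers, folds = folds, seed = seed)

  structure(list(
    question_id = question_id,
    markers = markers,
    coefficients = fit$coefficients,
    marker_thresholds = marker_thresholds,
    prob_thresholds = prob_thresholds,
    cv_auc = list(auc = roc$auc, ci = roc$ci, folds = folds),
    roc = roc,
    fitted_probs = probs,
    outcome = as.integer(d$outcome),
    zone_convention = zone_convention,
    n_used = nrow(d), n_dropped = sum(!cc),
    converged = fit$converged,
    development_cohort = development_cohort,
    seed = seed), class = "question_model")
}

#' @export
print.question_model <- function(x, ...) {
  cat("Diagnostic question model:",
      if (!is.null(x$question_id)) x$question_id else "(ad hoc subset)", "\n")
  cat("  markers:", paste(marker_labels(x$markers), collapse = ", "), "\n")
  cat(sprintf("  n = %d (%d dropped for missing markers)\n",
              x$n_used, x$n_dropped))
  cat(sprintf("  CV-AUC: %.3f [%.3f, %.3f] (%d-fold)\n", x$cv_auc$auc,
              x$cv_auc$ci[1], x$cv_auc$ci[2], x$cv_auc$folds))
  invisible(x)
}

#' @export
summary.question_model <- function(object, ...) {
  x <- object
  print(x)
  cat("\nLogistic coefficients (log-odds per unit):\n")
  print(round(x$coefficients, 5))
  cat("\nPer-marker Youden thresholds:\n")
  print(x$marker_thresholds, row.names = FALSE)
  pt <- x$prob_thresholds
  cat(sprintf("\nProbability thresholds: youden %.3f | sens90 %.3f | spec90 %.3f%s\n",
              pt$youden, pt$sens90, pt$spec90,
              if (pt$inverted_zones) "  [zones inverted: Youden-only]" else ""))
  invisible(x)
}

#' @export
coef.question_model <- function(object, ...) object$coefficients

#' Predict diagnostic probabilities from a question model
#'
#' @param object a `question_model`.
#' @param newdata data.frame (or cohort) containing the model's marker
#'   columns.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.question_model <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$markers, names(newdata))
  if (length(miss) > 0)
    stop("marker column(s) absent: ", paste(miss, collapse = ", "))
  lp <- object$coefficients[1] +
    as.matrix(as.data.frame(newdata)[object$markers]) %*%
    object$coefficients[-1]
  lp <- as.numeric(lp)
  if (type == "link") lp else stats::plogis(lp)
}

# zone from a probability under the model's convention
.likelihood_zone <- function(p, thr, convention) {
  if (convention == "literal") {
    if (p > thr$sens90) "high"
    else if (p < thr$spec90) "low"
    else "indeterminate"
  } else if (thr$inverted_zones) {
    if (p >= thr$youden) "high" else "low"
  } else {
    if (p >= thr$spec90) "high"
    else if (p <= thr$sens90) "low"
    else "indeterminate"
  }
}

#' Classify an individual patient
#'
#' Computes the patient's diagnostic probability by filling the model's
#' logistic predictor formula with the plasma marker levels, assigns the
#' likelihood zone (low / indeterminate / high) from the probability
#' thresholds (the boundary is inclusive on the high side), and flags
#' each marker as normal or abnormal against its Youden cutoff.
#'
#' @param model a `question_model`.
#' @param panel named list or vector of raw marker values (`ptau181`,
#'   `gfap`, `nfl` in pg/mL, optionally `abeta_ratio`).
#' @param age age in years, used for the NfL age correction.
#' @param age_spec an [age_correction_spec()] matching the one applied to
#'   the development cohort.
#' @return A `patient_result`: list with `probability`, `zone`, `flags`
#'   (named logical, `TRUE` = abnormal), `pattern`, `values`.
#' @export
classify_patient <- function(model, panel, age,
                             age_spec = age_correction_spec()) {
  stopifnot(inherits(model, "question_model"))
  panel <- as.list(panel)
  if (!is.null(panel$nfl) && is.null(panel$nfl_age_corrected))
    panel$nfl_age_corrected <- correct_nfl_for_age(panel$nfl, age, age_spec)
  miss <- setdiff(model$markers, names(panel))
  if (length(miss) > 0)
    stop("missing required marker(s): ", paste(miss, collapse = ", "))
  vals <- vapply(model$markers, function(m) as.numeric(panel[[m]]),
                 numeric(1))
  if (anyNA(vals))
    stop("missing required marker(s): ",
         paste(model$markers[is.na(vals)], collapse = ", "))

  p <- as.numeric(stats::plogis(model$coefficients[1] +
                                  sum(model$coefficients[-1] * vals)))
  zone <- .likelihood_zone(p, model$prob_thresholds, model$zone_convention)

  mt <- model$marker_thresholds
  flags <- vapply(seq_len(nrow(mt)), function(i) {
    v <- vals[[mt$marker[i]]]
    if (mt$direction[i] == "higher_abnormal") v >= mt$cutoff[i] else
      v <= mt$cutoff[i]
  }, logical(1))
  names(flags) <- mt$marker

  structure(list(probability = p, zone = zone, flags = flags,
                 pattern = paste(ifelse(flags, "A", "N"), collapse = ""),
                 values = vals, age = age,
                 question_id = model$question_id),
            class = "patient_result")
}

#' @export
print.patient_result <- function(x, ...) {
  cat("Patient result", if (!is.null(x$question_id))
    paste0("(", x$question_id, ")"), "\n")
  cat(sprintf("  probability: %.3f -> %s likelihood\n",
              x$probability, x$zone))
  for (m in names(x$flags))
    cat(sprintf("  %-18s %8.3f  %s\n", marker_labels(m), x$values[[m]],
                if (x$flags[[m]]) "ABNORMAL" else "normal"))
  invisible(x)
}

#' Serialize a question model to JSON
#'
#' Writes the deployable interpretation-tool artifact: coefficients,
#' per-marker thresholds, probability thresholds, zone convention and
#' provenance. [read_question_model()] restores an object usable with
#' [predict.question_model()] and [classify_patient()].
#'
#' @param model a `question_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_question_model <- function(model, path) {
  payload <- model[c("question_id", "markers", "coefficients",
                     "prob_thresholds", "cv_auc", "zone_convention",
                     "n_used", "n_dropped", "development_cohort", "seed")]
  payload$coefficients <- as.list(model$coefficients)
  payload$marker_thresholds <- model$marker_thresholds
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_question_model
#' @export
read_question_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(p$coefficients)
  thr <- p$prob_thresholds
  # JSON has no Inf; absent bounds mean the scan hit a boundary cutoff
  if (is.null(thr$sens90)) thr$sens90 <- -Inf
  if (is.null(thr$spec90)) thr$spec90 <- Inf
  structure(list(
    question_id = p$question_id, markers = p$markers,
    coefficients = coefs,
    marker_thresholds = as.data.frame(p$marker_thresholds),
    prob_thresholds = thr,
    cv_auc = p$cv_auc, zone_convention = p$zone_convention,
    n_used = p$n_used, n_dropped = p$n_dropped,
    development_cohort = p$development_cohort, seed = p$seed),
    class = "question_model")
}
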
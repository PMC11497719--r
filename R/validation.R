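#' Cohort-membership (case-mix) model
#'
#' Logistic regression of cohort membership (development vs validation)
#' on the panel markers, optionally including the question outcome, with
#' the AUC of pooled out-of-fold membership probabilities from stratified
#' cross-validation. A low AUC indicates a similar case mix between the
#' cohorts (results reproduce), a high AUC a different case mix (results
#' transport); no hard cutoff is imposed.
#'
#' @param dev_subset,val_subset question subsets from
#'   [subset_for_question()] for the two cohorts.
#' @param markers marker columns entering the membership model.
#' @param include_outcome include the question outcome as a predictor
#'   (the default).
#' @param folds,seed cross-validation folds and fold seed.
#' @return A `membership_report`: list with `auc`, `ci`,
#'   `predictors_used`, `cv_folds`, `n_dev`, `n_val`.
#' @export
membership_auc <- function(dev_subset, val_subset, markers,
                           include_outcome = TRUE, folds = 10, seed = 1) {
  preds <- c(markers, if (include_outcome) "outcome")
  dd <- dev_subset[stats::complete.cases(dev_subset[preds]), preds,
                   drop = FALSE]
  vv <- val_subset[stats::complete.cases(val_subset[preds]), preds,
                   drop = FALSE]
  if (nrow(dd) == 0 || nrow(vv) == 0)
    stop("both cohorts must be non-empty after subsetting")
  pooled <- rbind(dd, vv)
  pooled$membership <- rep(c(0L, 1L), c(nrow(dd), nrow(vv)))
  # reuse the CV machinery with membership as the outcome
  pooled$outcome_orig <- if (include_outcome) pooled$outcome else NULL
  pooled$outcome <- pooled$membership
  roc <- cv_auc(pooled,
                markers = c(markers, if (include_outcome) "outcome_orig"),
                folds = folds, seed = seed)
  structure(list(question_id = attr(dev_subset, "question"),
                 auc = roc$auc, ci = roc$ci,
                 predictors_used = preds, cv_folds = folds,
                 n_dev = nrow(dd), n_val = nrow(vv),
                 scores = roc$scores, labels = roc$labels),
            class = "membership_report")
}

#' @export
print.membership_report <- function(x, ...) {
  cat("Cohort-membership model",
      if (!is.null(x$question_id)) paste0("(", x$question_id, ")"), "\n")
  cat(sprintf("  AUC %.3f [%.3f, %.3f]  (dev n = %d, val n = %d)\n",
              x$auc, x$ci[1], x$ci[2], x$n_dev, x$n_val))
  cat("  predictors:", paste(x$predictors_used, collapse = ", "), "\n")
  invisible(x)
}

#' Transported discrimination of a frozen model
#'
#' Applies the development model without refitting to a validation
#' subset: AUC (with DeLong interval) of the frozen-model probabilities,
#' and accuracy / sensitivity / specificity plus the confusion matrix at
#' the development Youden probability cutoff.
#'
#' @param model a `question_model` fitted on the development cohort.
#' @param val_subset validation question subset.
#' @param cutoff probability cutoff for classification (default: the
#'   development Youden probability threshold).
#' @return List with `auc`, `ci`, `accuracy`, `sensitivity`,
#'   `specificity`, `confusion_matrix` (2x2, predicted x observed), `n`.
#' @export
transported_discrimination <- function(model, val_subset,
                                       cutoff = model$prob_thresholds$youden) {
  cc <- stats::complete.cases(val_subset[model$markers])
  d <- val_subset[cc, , drop = FALSE]
  y <- as.integer(d$outcome)
  if (length(unique(y)) < 2)
    stop("validation subset contains a single outcome class")
  p <- predict(model, d)
  a <- .auc_delong(p, y)
  pred <- as.integer(p >= cutoff)
  cm <- table(factor(pred, levels = c(1, 0)),
              factor(y, levels = c(1, 0)),
              dnn = c("predicted", "observed"))
  list(auc = a$auc, ci = a$ci,
       accuracy = mean(pred == y),
       sensitivity = mean(pred[y == 1] == 1),
       specificity = mean(pred[y == 0] == 0),
       confusion_matrix = cm, cutoff = cutoff, n = nrow(d))
}

#' Calibration-in-the-large and calibration slope
#'
#' Logistic recalibration of the validation outcome against the frozen
#' model's linear predictor: calibration-in-the-large is the intercept
#' of a logistic regression with the linear predictor as a fixed offset
#' (0 when the average predicted risk matches the observed risk);
#' the calibration slope is the coefficient of the linear predictor in a
#' logistic regression with a free intercept (1 when the spread of
#' predicted risks matches the observed).
#'
#' @param model a `question_model`.
#' @param val_subset validation question subset.
#' @return List with `citl` and `cal_slope`.
#' @export
calibration_metrics <- function(model, val_subset) {
  cc <- stats::complete.cases(val_subset[model$markers])
  d <- val_subset[cc, , drop = FALSE]
  y <- as.integer(d$outcome)
  lp <- predict(model, d, type = "link")
  if (stats::sd(lp) < 1e-12)
    stop("degenerate (constant) linear predictor; slope undefined")
  citl_fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  slope_fit <- stats::glm(y ~ lp, family = stats::binomial())
  list(citl = unname(stats::coef(citl_fit)[1]),
       cal_slope = unname(stats::coef(slope_fit)["lp"]))
}

#' TRIPOD-style calibration curve
#'
#' Equal-count quantile bins (deciles by default) of the predicted
#' probability, with per-bin mean predicted risk vs observed event rate,
#' plus a Loess curve of the outcome on the predicted probability
#' sampled on a fixed 100-point grid. Bins with fewer than 5 subjects
#' trigger a reduction of the bin count with a warning.
#'
#' @param model a `question_model`.
#' @param val_subset validation question subset.
#' @param bins number of quantile bins.
#' @param span Loess span.
#' @return List with `binned` (data.frame: `mean_predicted`, `observed`,
#'   `n`) and `smoothed` (data.frame: `predicted`, `observed`).
#' @export
calibration_curve <- function(model, val_subset, bins = 10, span = 0.75) {
  cc <- stats::complete.cases(val_subset[model$markers])
  d <- val_subset[cc, , drop = FALSE]
  if (nrow(d) < bins) stop("need at least as many subjects as bins")
  y <- as.integer(d$outcome)
  p <- predict(model, d)
  if (length(unique(p)) == 1) {
    warning("constant predictions; single calibration bin")
    return(list(binned = data.frame(mean_predicted = p[1],
                                    observed = mean(y),
                                    n = length(y)),
                smoothed = NULL, bins = 1))
  }

  repeat {
    br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1)))
    bin <- cut(p, breaks = br, include.lowest = TRUE)
    if (bins <= 1 || all(table(bin) >= 5)) break
    bins <- bins - 1
    warning("bin with fewer than 5 subjects; reducing to ", bins, " bins")
  }
  binned <- data.frame(
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    observed = as.numeric(tapply(y, bin, mean)),
    n = as.integer(table(bin)))

  smoothed <- NULL
  if (length(unique(p)) > 5) {
    lo <- stats::loess(y ~ p, span = span, degree = 1)
    grid <- seq(min(p), max(p), length.out = 100)
    smoothed <- data.frame(
      predicted = grid,
      observed = pmin(1, pmax(0, stats::predict(lo, newdata = data.frame(p = grid)))))
  }
  list(binned = binned, smoothed = smoothed, bins = bins)
}

#' Recalculate thresholds on a validation cohort
#'
#' Recomputes the per-marker Youden cutoffs and the three probability
#' thresholds on the validation subset and reports them next to the
#' development values with relative differences, to assess threshold
#' transportability between cohorts.
#'
#' @param val_subset validation question subset.
#' @param model a `question_model`.
#' @param flag_level relative difference above which a threshold is
#'   flagged as non-transportable.
#' @return List with `marker_thresholds` (data.frame with development and
#'   validation cutoffs, relative difference and flag) and
#'   `prob_thresholds`.
#' @export
recalculate_thresholds <- function(val_subset, model, flag_level = 0.2) {
  cc <- stats::complete.cases(val_subset[model$markers])
  d <- val_subset[cc, , drop = FALSE]
  if (length(unique(d$outcome)) < 2)
    stop("both outcome classes required")
  mt <- model$marker_thresholds
  val_cut <- vapply(seq_len(nrow(mt)), function(i)
    youden_threshold(d[[mt$marker[i]]], d$outcome, mt$direction[i])$cutoff,
    numeric(1))
  rel <- abs(val_cut - mt$cutoff) / abs(mt$cutoff)
  marker_thresholds <- data.frame(
    marker = mt$marker, direction = mt$direction,
    development = mt$cutoff, validation = val_cut,
    rel_difference = rel, flagged = rel > flag_level,
    stringsAsFactors = FALSE)

  p <- predict(model, d)
  val_pt <- probability_thresholds(p, d$outcome)
  dev_pt <- model$prob_thresholds
  prob_thresholds <- data.frame(
    threshold = c("youden", "sens90", "spec90"),
    development = c(dev_pt$youden, dev_pt$sens90, dev_pt$spec90),
    validation = c(val_pt$youden, val_pt$sens90, val_pt$spec90),
    stringsAsFactors = FALSE)
  list(marker_thresholds = marker_thresholds,
       prob_thresholds = prob_thresholds)
}

#' Full external validation of a question model
#'
#' Bundles [transported_discrimination()], [calibration_metrics()],
#' [calibration_curve()] and [recalculate_thresholds()] into one report.
#'
#' @param model a `question_model`.
#' @param val_subset validation question subset (or a [cohort()], which
#'   is subset by the model's question).
#' @param bins calibration bins.
#' @return A `validation_report` object.
#' @export
validate_model <- function(model, val_subset, bins = 10) {
  if (inherits(val_subset, "cohort"))
    val_subset <- subset_for_question(val_subset, model$question_id)
  disc <- transported_discrimination(model, val_subset)
  cal <- calibration_metrics(model, val_subset)
  curve <- calibration_curve(model, val_subset, bins = bins)
  thr <- recalculate_thresholds(val_subset, model)
  structure(list(question_id = model$question_id,
                 auc = disc$auc, ci = disc$ci,
                 accuracy = disc$accuracy,
                 sensitivity = disc$sensitivity,
                 specificity = disc$specificity,
                 confusion_matrix = disc$confusion_matrix,
                 cutoff = disc$cutoff,
                 citl = cal$citl, cal_slope = cal$cal_slope,
                 calibration_curve = curve,
                 recalculated_thresholds = thr,
                 n = disc$n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation",
      if (!is.null(x$question_id)) paste0("(", x$question_id, ")"), "\n")
  cat(sprintf("  AUC %.3f [%.3f, %.3f] on n = %d\n", x$auc, x$ci[1],
              x$ci[2], x$n))
  cat(sprintf("  at dev cutoff %.3f: accuracy %.3f, sens %.3f, spec %.3f\n",
              x$cutoff, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  calibration-in-the-large %+.3f (perfect 0), slope %.3f (perfect 1)\n",
              x$citl, x$cal_slope))
  invisible(x)
}

#' Plot a calibration curve
#'
#' Binned observed-vs-predicted points with the Loess smooth and the
#' ideal diagonal.
#'
#' @param x a `validation_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.validation_report <- function(x, ...) {
  cc <- x$calibration_curve
  graphics::plot(cc$binned$mean_predicted, cc$binned$observed,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 xlab = "predicted probability",
                 ylab = "observed event rate",
                 main = paste("Calibration:", x$question_id), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  if (!is.null(cc$smoothed))
    graphics::lines(cc$smoothed$predicted, cc$smoothed$observed,
                    col = "steelblue", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("CITL %+.2f, slope %.2f",
                                    x$citl, x$cal_slope))
  invisible(x)
}
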
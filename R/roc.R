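# ROC utilities: candidate cut points, Youden scans, probability
# thresholds and cross-validated AUC with DeLong intervals.

# candidate cutoffs: midpoints between adjacent distinct observed values,
# plus the two boundary cutoffs
.candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) < 2) return(c(-Inf, Inf))
  c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
}

.sens_spec <- function(cutoff, scores, labels, direction) {
  pos <- if (direction == "higher_abnormal") scores >= cutoff else
    scores <= cutoff
  c(sens = mean(pos[labels == 1]), spec = mean(!pos[labels == 0]))
}

#' Youden-index threshold for a single marker or score
#'
#' Scans all candidate cut points (midpoints between adjacent distinct
#' observed values plus the two boundary cutoffs) and returns the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1. A value is
#' called abnormal when it lies beyond the cutoff in the marker's
#' abnormal direction (at or above for `higher_abnormal`, at or below for
#' `lower_abnormal`). Ties in J are broken toward the cutoff with higher
#' specificity, then toward the smaller absolute cutoff.
#'
#' @param scores numeric marker values or probabilities.
#' @param labels binary outcome (1 = case).
#' @param direction `"higher_abnormal"` or `"lower_abnormal"`.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @examples
#' youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))$cutoff  # 2.5
#' @export
youden_threshold <- function(scores, labels,
                             direction = c("higher_abnormal",
                                           "lower_abnormal")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) stop("both outcome classes required")
  if (length(unique(scores)) < 2)
    stop("constant scores: no informative cutoff")
  cand <- .candidate_cutoffs(scores)
  ss <- vapply(cand, .sens_spec, numeric(2),
               scores = scores, labels = labels, direction = direction)
  j <- ss["sens", ] + ss["spec", ] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-ss["spec", best], abs(cand[best]))][1]
  list(cutoff = cand[best], sensitivity = unname(ss["sens", best]),
       specificity = unname(ss["spec", best]), j = unname(j[best]),
       direction = direction)
}

#' Probability thresholds defining the likelihood zones
#'
#' From the fitted probabilities of a diagnostic model on its development
#' data, computes the three clinical cut points: the Youden-index
#' probability threshold, the 90%-sensitivity threshold (largest cutoff
#' whose sensitivity is still at least 0.90) and the 90%-specificity
#' threshold (smallest cutoff whose specificity is at least 0.90). When
#' the 90%-sensitivity cutoff exceeds the 90%-specificity cutoff the
#' likelihood zones would invert (no indeterminate band); the result is
#' flagged and zone interpretation degrades to Youden-only.
#'
#' @param probs fitted probabilities.
#' @param labels binary outcome (1 = case).
#' @return List with `youden`, `sens90`, `spec90`, `inverted_zones`.
#' @export
probability_thresholds <- function(probs, labels) {
  ok <- !is.na(probs) & !is.na(labels)
  probs <- probs[ok]; labels <- as.integer(labels[ok])
  yj <- youden_threshold(probs, labels, "higher_abnormal")
  cand <- .candidate_cutoffs(probs)
  ss <- vapply(cand, .sens_spec, numeric(2),
               scores = probs, labels = labels,
               direction = "higher_abnormal")
  sens_ok <- cand[ss["sens", ] >= 0.90]
  spec_ok <- cand[ss["spec", ] >= 0.90]
  sens90 <- max(sens_ok[is.finite(sens_ok)], -Inf)
  spec90 <- min(spec_ok[is.finite(spec_ok)], Inf)
  list(youden = yj$cutoff, sens90 = sens90, spec90 = spec90,
       inverted_zones = isTRUE(sens90 > spec90))
}

# stratified fold assignment, deterministic given seed
.stratified_folds <- function(labels, k, seed) {
  if (min(table(labels)) < 2)
    stop("too few subjects in a class to stratify folds")
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.auc_delong <- function(scores, labels) {
  rc <- pROC::roc(response = labels, predictor = scores,
                  levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- withCallingHandlers(
    as.numeric(pROC::ci.auc(rc, method = "delong")),
    warning = function(w) {
      if (grepl("always 1-1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(auc = as.numeric(pROC::auc(rc)), ci = c(ci[1], ci[3]), roc = rc)
}

#' Cross-validated ROC curve and AUC
#'
#' For a panel of markers, a logistic model is refit on each of `folds`
#' stratified training folds and out-of-fold probabilities are pooled;
#' the AUC and its DeLong 95% interval are computed on the pooled scores.
#' For a single marker the marker value itself (oriented by its abnormal
#' direction) is the score, so no refitting is needed; the AUC is then
#' invariant under any strictly increasing transform of the marker.
#'
#' @param data a question subset from [subset_for_question()] (or any
#'   data.frame with an `outcome` column and the marker columns).
#' @param markers character vector of marker columns; a single name
#'   triggers the raw-score path.
#' @param folds number of cross-validation folds.
#' @param seed seed controlling the fold assignment.
#' @return An object of class `roc_curve`: list with `auc`, `ci`,
#'   `thresholds`, `sensitivities`, `specificities`, pooled `scores` and
#'   `labels`, `markers`, `folds`.
#' @export
cv_auc <- function(data, markers, folds = 10, seed = 1) {
  stopifnot("outcome" %in% names(data))
  cc <- stats::complete.cases(data[markers])
  d <- data[cc, , drop = FALSE]
  y <- as.integer(d$outcome)
  if (length(unique(y)) < 2) stop("both outcome classes required")
  if (length(markers) == 1) {
    dirn <- marker_directions()[[markers]]
    scores <- if (identical(dirn, "lower_abnormal")) -d[[markers]] else
      d[[markers]]
    labels <- y
  } else {
    fold <- .stratified_folds(y, folds, seed)
    scores <- rep(NA_real_, nrow(d))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2)
        stop("training fold with a single outcome class")
      fit <- .fit_logistic_raw(d[tr, , drop = FALSE], markers)
      scores[!tr] <- .predict_prob(fit$coefficients,
                                   d[!tr, markers, drop = FALSE])
    }
    labels <- y
  }
  a <- .auc_delong(scores, labels)
  structure(list(auc = a$auc, ci = a$ci,
                 thresholds = a$roc$thresholds,
                 sensitivities = a$roc$sensitivities,
                 specificities = a$roc$specificities,
                 scores = scores, labels = labels,
                 markers = markers, folds = folds),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f [%.3f, %.3f], %d-fold CV\n",
              paste(x$markers, collapse = " + "), x$auc,
              x$ci[1], x$ci[2], x$folds))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(1 - x$specificities, x$sensitivities)
  graphics::plot(1 - x$specificities[ord], x$sensitivities[ord],
                 type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("AUC %.2f [%.2f, %.2f]",
                                x$auc, x$ci[1], x$ci[2]), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
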
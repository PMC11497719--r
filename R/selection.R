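#' Default penalty grid for LASSO tuning
#'
#' 60 log-spaced values on \[1e-4, 1\], spanning the per-question optima
#' typically found for these panels (roughly 0.01-0.12).
#'
#' @return Increasing numeric vector.
#' @export
default_alpha_grid <- function() {
  exp(seq(log(1e-4), log(1), length.out = 60))
}

#' Tune the LASSO penalty by cross-validated mean squared error
#'
#' The 0/1 outcome is regressed on the standardized candidate markers
#' with an L1-penalized *linear* model (the penalty weight `alpha` here
#' is `glmnet`'s `lambda`), and the penalty minimizing the mean 10-fold
#' cross-validation squared error is returned. Predictors are
#' standardized within each training fold; the outcome is left as 0/1.
#' Ties are resolved toward the largest (most parsimonious) penalty;
#' when every grid value gives the same CV error the largest is returned
#' with a warning that the grid is uninformative.
#'
#' @param data question subset with `outcome` and marker columns.
#' @param markers candidate marker columns.
#' @param alpha_grid candidate penalty values.
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @return The selected penalty (scalar).
#' @export
optimize_alpha <- function(data, markers = candidate_markers(),
                           alpha_grid = default_alpha_grid(),
                           folds = 10, seed = 1) {
  stopifnot("outcome" %in% names(data), length(alpha_grid) >= 1)
  cc <- stats::complete.cases(data[markers])
  d <- data[cc, , drop = FALSE]
  y <- as.numeric(d$outcome)
  if (length(unique(y)) < 2) stop("both outcome classes required")
  if (nrow(d) < 2 * folds)
    stop("need at least ", 2 * folds, " subjects for ", folds, "-fold CV")
  x <- as.matrix(d[markers])
  lam <- sort(unique(alpha_grid), decreasing = TRUE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(d)))
  cv <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = lam, foldid = foldid,
                          type.measure = "mse", standardize = TRUE)
  if (diff(range(cv$cvm)) < 1e-12) {
    warning("all penalties give identical CV error; returning the largest")
    return(max(lam))
  }
  cv$lambda.min
}

#' Bootstrapped LASSO marker selection
#'
#' For each of `n_bootstrap` iterations, subjects are resampled with
#' replacement (same n), predictors are standardized within the
#' resample, an L1-penalized linear regression of the 0/1 outcome is fit
#' at the fixed penalty `alpha`, and the markers with numerically
#' non-zero coefficients (|coef| > 1e-8) are recorded. A resample
#' containing a single outcome class is redrawn (and counted) so the
#' denominator stays at `n_bootstrap`.
#'
#' @param data question subset with `outcome` and marker columns.
#' @param alpha the penalty, typically from [optimize_alpha()].
#' @param markers candidate marker columns.
#' @param n_bootstrap number of bootstrap iterations (study default 1000).
#' @param seed seed for the resampling.
#' @return A `selection_report`: list with `question_id`, `alpha_star`,
#'   `frequencies` (named, in \[0, 1\]), `n_bootstrap`, `n_redrawn`,
#'   `seed`.
#' @export
bootstrap_select <- function(data, alpha, markers = candidate_markers(),
                             n_bootstrap = 1000, seed = 1) {
  stopifnot(alpha > 0, n_bootstrap >= 1)
  cc <- stats::complete.cases(data[markers])
  d <- data[cc, , drop = FALSE]
  y <- as.numeric(d$outcome)
  if (length(unique(y)) < 2) stop("both outcome classes required")
  x <- as.matrix(d[markers])
  n <- nrow(x)
  # descending path ending exactly at the target penalty, so the
  # extracted coefficients need no interpolation
  lam <- alpha * c(16, 8, 4, 2, 1)
  hits <- matrix(FALSE, n_bootstrap, length(markers),
                 dimnames = list(NULL, markers))
  n_redrawn <- 0L
  set.seed(seed)
  for (b in seq_len(n_bootstrap)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                          family = "gaussian", alpha = 1, lambda = lam,
                          standardize = TRUE)
    cf <- as.numeric(stats::coef(fit, s = alpha))[-1]
    hits[b, ] <- abs(cf) > 1e-8
  }
  structure(list(question_id = attr(data, "question"),
                 alpha_star = alpha,
                 frequencies = colMeans(hits),
                 n_bootstrap = n_bootstrap, n_redrawn = n_redrawn,
                 seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("LASSO bootstrap selection",
      if (!is.null(x$question_id)) paste0("(", x$question_id, ")"), "\n")
  cat(sprintf("  alpha = %.4g, B = %d (%d resamples redrawn)\n",
              x$alpha_star, x$n_bootstrap, x$n_redrawn))
  f <- x$frequencies
  for (m in names(f))
    cat(sprintf("  %-18s %5.1f%%\n", marker_labels(m), 100 * f[[m]]))
  invisible(x)
}

#' Decide the diagnostic panel from per-question selection frequencies
#'
#' A marker enters the shared diagnostic panel if and only if it was
#' selected in 100% of the bootstrap iterations for at least one of the
#' clinical questions; the panel is then used for all questions. The
#' rule is strict: a maximum frequency of 0.99 does not qualify.
#'
#' @param reports a list of `selection_report`s, or a numeric matrix /
#'   data.frame of selection frequencies with one row per question and
#'   one column per marker.
#' @return A `panel_decision`: list with `included_markers` and
#'   `rule_trace` (per-marker maximum frequency across questions).
#' @export
decide_panel <- function(reports) {
  if (inherits(reports, "selection_report")) reports <- list(reports)
  if (is.list(reports) && !is.data.frame(reports) &&
      all(vapply(reports, inherits, logical(1), "selection_report"))) {
    if (length(reports) == 0) stop("at least one report required")
    freq <- do.call(rbind, lapply(reports, `[[`, "frequencies"))
    rownames(freq) <- vapply(reports, function(r)
      if (is.null(r$question_id)) "" else r$question_id, character(1))
  } else {
    freq <- as.matrix(as.data.frame(reports))
    if (!is.numeric(freq)) stop("frequencies must be numeric")
  }
  rule_trace <- apply(freq, 2, max)
  included <- names(rule_trace)[rule_trace >= 1 - 1e-12]
  structure(list(included_markers = included, rule_trace = rule_trace,
                 frequencies = freq),
            class = "panel_decision")
}

#' @export
print.panel_decision <- function(x, ...) {
  cat("Diagnostic panel:",
      if (length(x$included_markers)) {
        paste(marker_labels(x$included_markers), collapse = ", ")
      } else "(empty)", "\n")
  cat("  max selection frequency per marker:\n")
  for (m in names(x$rule_trace))
    cat(sprintf("  %-18s %5.1f%%\n", marker_labels(m),
                100 * x$rule_trace[[m]]))
  invisible(x)
}

#' Serialize a selection report or panel decision to JSON
#' @param x a `selection_report` or `panel_decision`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  payload <- unclass(x)
  if (!is.null(payload$frequencies) && is.matrix(payload$frequencies))
    payload$frequencies <- as.data.frame(payload$frequencies)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
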
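#' Passing-Bablok method-comparison regression
#'
#' Rank-based regression for comparing two measurement procedures of the
#' same analyte, used here to derive transformation formulas aligning
#' plasma marker values measured with different assay kit lots. The
#' classical positive-correlation algorithm is implemented: the slope is
#' the shifted median of all pairwise slopes
#' \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)} over \eqn{i < j}, excluding
#' pairs with equal x and slopes exactly -1, with shift
#' \eqn{K = \#\{S_{ij} < -1\}}; the intercept is
#' \eqn{\mathrm{median}(y_i - b\,x_i)}. Confidence intervals use the
#' rank-based normal approximation.
#'
#' @param x original measurements (e.g. development-lot values).
#' @param y re-measurements to be mapped onto the `x` scale.
#' @param conf_level confidence level for the slope/intercept intervals.
#' @param marker optional marker name recorded in the model.
#' @return An object of class `passing_bablok`: a list with `slope`,
#'   `intercept`, `slope_ci`, `intercept_ci`, `n_pairs`, `marker`.
#' @examples
#' fit <- passing_bablok(1:5, 2 * (1:5) + 1)
#' fit$slope      # 2
#' fit$intercept  # 1
#' @export
passing_bablok <- function(x, y, conf_level = 0.95, marker = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  if (length(unique(x)) == 1) stop("all x values identical")

  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- dy[dx != 0] / dx[dx != 0]
  s <- s[s != -1]
  s <- sort(s)
  N <- length(s)
  if (N < 3) stop("fewer than 3 finite pairwise slopes")
  K <- sum(s < -1)

  slope <- if (N %% 2 == 1) s[(N + 1) / 2 + K] else
    mean(s[c(N / 2 + K, N / 2 + 1 + K)])

  w <- stats::qnorm(1 - (1 - conf_level) / 2) *
    sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1L, as.integer(round((N - w) / 2)))
  m2 <- min(N, N - m1 + 1L)
  slope_ci <- c(s[min(N, m1 + K)], s[max(1L, min(N, m2 + K))])

  intercept <- stats::median(y - slope * x)
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))

  structure(list(slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 n_pairs = n, conf_level = conf_level, marker = marker),
            class = "passing_bablok")
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat("Passing-Bablok regression", if (!is.null(x$marker))
    paste0("(", x$marker, ")"), "\n")
  cat(sprintf("  n = %d pairs\n", x$n_pairs))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n", x$slope,
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Apply an alignment model to marker values
#'
#' Affine transformation `intercept + slope * value` mapping one kit lot's
#' scale onto another's, as obtained by [passing_bablok()]. Aligned values
#' that come out non-positive are set to `NA` with a warning, since a
#' concentration cannot be non-positive.
#'
#' @param values numeric marker values.
#' @param model a `passing_bablok` fit (or any list with `slope` and
#'   `intercept`).
#' @return Aligned values.
#' @export
apply_alignment <- function(values, model) {
  out <- model$intercept + model$slope * values
  bad <- !is.na(out) & out <= 0
  if (any(bad)) {
    warning(sum(bad), " aligned value(s) non-positive; set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' Serialize an alignment model to JSON
#'
#' @param model a `passing_bablok` fit.
#' @param path output path.
#' @param direction free-text note on the mapping direction (which lot is
#'   mapped onto which), recorded to prevent double application.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(model, path, direction = NULL) {
  jsonlite::write_json(
    list(marker = model$marker, slope = model$slope,
         intercept = model$intercept, slope_ci = model$slope_ci,
         intercept_ci = model$intercept_ci, n_pairs = model$n_pairs,
         conf_level = model$conf_level, direction = direction),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' NfL age-correction specification
#'
#' Plasma NfL rises with age, so the models use an age-corrected value.
#' The published reference-curve coefficients are not redistributed here;
#' the default is the identity (no correction), with a configurable
#' log-linear reference form `nfl / exp(b0 + b1 * age)` expressing the
#' observed-to-age-expected ratio for users who supply coefficients.
#'
#' @param form `"identity"` or `"log_linear_reference"`.
#' @param b0 log-scale intercept of the reference curve.
#' @param b1 log-scale slope per year of age.
#' @return An `age_correction_spec` object.
#' @export
age_correction_spec <- function(form = c("identity", "log_linear_reference"),
                                b0 = NULL, b1 = NULL) {
  form <- match.arg(form)
  if (form == "log_linear_reference") {
    if (is.null(b0) || is.null(b1))
      stop("log_linear_reference form requires coefficients b0 and b1")
    if (any(!is.finite(c(b0, b1))))
      stop("coefficients must be finite")
  }
  structure(list(form = form, b0 = b0, b1 = b1),
            class = "age_correction_spec")
}

#' Correct plasma NfL for age
#'
#' @param nfl NfL concentration(s), pg/mL, positive.
#' @param age age(s) in years, in (0, 120).
#' @param spec an [age_correction_spec()].
#' @return Corrected values: unchanged under the identity form, the
#'   observed-to-expected ratio under the log-linear reference form.
#' @export
correct_nfl_for_age <- function(nfl, age, spec = age_correction_spec()) {
  stopifnot(inherits(spec, "age_correction_spec"))
  if (any(nfl <= 0)) stop("nfl must be positive")
  if (any(age <= 0 | age >= 120)) stop("age must be in (0, 120)")
  switch(spec$form,
         identity = nfl,
         log_linear_reference = nfl / exp(spec$b0 + spec$b1 * age))
}

#' A single piece of amyloid-status evidence
#'
#' @param modality one of `pet_visual`, `pet_centiloid`, `csf_innotest`,
#'   `csf_elecsys`, `csf_lumipulse_ratio`, `csf_lumipulse_ab42`,
#'   `csf_innotest_ab42`, `csf_lumipulse_spin`, `external_record`.
#' @param ... the modality-specific measurements: `read`
#'   (`"positive"`/`"negative"`, for `pet_visual` and `external_record`),
#'   `centiloid`, `ptau181` and `abeta42` (pg/mL, for the CSF
#'   ratio assays), `ratio` (for precomputed ratios), or `abeta42` alone
#'   for the Abeta42-only CSF rules.
#' @return An `amyloid_evidence` object.
#' @export
amyloid_evidence <- function(modality, ...) {
  modality <- match.arg(modality, names(.amyloid_rules))
  values <- list(...)
  needed <- .amyloid_rules[[modality]]$needs
  have <- names(values)
  miss <- needed[!vapply(needed, function(nm)
    nm %in% have || (nm == "ratio" && all(c("ptau181", "abeta42") %in% have)),
    logical(1))]
  if (length(miss) > 0)
    stop("modality ", modality, " requires: ", paste(miss, collapse = ", "))
  num <- unlist(values[vapply(values, is.numeric, logical(1))])
  if (any(num <= 0)) stop("measurements must be positive")
  structure(list(modality = modality, values = values),
            class = "amyloid_evidence")
}

# Rule table: each entry gives required fields, the precedence tier
# (PET before CSF), and the dichotomization rule.
.amyloid_rules <- list(
  pet_visual = list(needs = "read", tier = 1L,
    call = function(v) v$read),
  pet_centiloid = list(needs = "centiloid", tier = 1L,
    call = function(v) if (v$centiloid > 30) "positive" else "negative"),
  csf_innotest = list(needs = "ratio", tier = 2L,
    call = function(v) {
      r <- if (!is.null(v$ratio)) v$ratio else v$ptau181 / v$abeta42
      if (r > 0.06) "positive" else "negative"
    }),
  csf_elecsys = list(needs = "ratio", tier = 2L,
    call = function(v) {
      r <- if (!is.null(v$ratio)) v$ratio else v$ptau181 / v$abeta42
      if (r > 0.02) "positive" else "negative"
    }),
  csf_lumipulse_ratio = list(needs = "ratio", tier = 2L,
    call = function(v) if (v$ratio < 0.069) "positive" else "negative"),
  csf_lumipulse_ab42 = list(needs = "abeta42", tier = 2L,
    call = function(v) if (v$abeta42 < 725) "positive" else "negative"),
  csf_innotest_ab42 = list(needs = "abeta42", tier = 2L,
    call = function(v) if (v$abeta42 < 880.5) "positive" else "negative"),
  csf_lumipulse_spin = list(needs = "ratio", tier = 2L,
    call = function(v) if (v$ratio < 0.062) "positive" else "negative"),
  external_record = list(needs = "read", tier = 3L,
    call = function(v) v$read))

#' Adjudicate amyloid status from reference-standard evidence
#'
#' Dichotomizes a subject's amyloid status from amyloid-PET and/or CSF
#' measurements using the assay-specific cutoffs: a PET visual read (or,
#' when only a centiloid value is available, centiloid > 30) takes
#' precedence over CSF; CSF rules are Innotest P-tau181/Abeta42 > 0.06,
#' Elecsys P-tau181/Abeta42 > 0.02, Lumipulse Abeta42/40 < 0.069 (or
#' Abeta42 < 725 pg/mL when Abeta40 is unavailable), Innotest
#' Abeta42 < 880.5 pg/mL, and Lumipulse Abeta42/40 < 0.062 for the
#' alternative Lumipulse calibration. Conflicting evidence at the same tier is
#' resolved by the first-listed piece, with a warning.
#'
#' @param evidence a list of [amyloid_evidence()] objects (possibly empty).
#' @return `"positive"`, `"negative"`, or `"unknown"` when no evidence is
#'   available.
#' @examples
#' adjudicate_amyloid(list(amyloid_evidence("csf_innotest",
#'                                          ptau181 = 60, abeta42 = 800)))
#' @export
adjudicate_amyloid <- function(evidence) {
  if (inherits(evidence, "amyloid_evidence")) evidence <- list(evidence)
  if (length(evidence) == 0) return("unknown")
  stopifnot(all(vapply(evidence, inherits, logical(1), "amyloid_evidence")))
  tiers <- vapply(evidence, function(e) .amyloid_rules[[e$modality]]$tier,
                  integer(1))
  top <- evidence[tiers == min(tiers)]
  calls <- vapply(top, function(e)
    .amyloid_rules[[e$modality]]$call(e$values), character(1))
  if (length(unique(calls)) > 1)
    warning("conflicting same-precedence amyloid evidence; ",
            "first-listed wins (", top[[1]]$modality, ")")
  calls[1]
}
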
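# Clinician-facing interpretation graphics: UpSet summaries of
# normal/abnormal marker combinations, probability density plots with
# the three threshold lines, and the single-patient composite report.

.open_device <- function(file, width = 7, height = 5) {
  if (is.null(file)) return(FALSE)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 300),
         svg = grDevices::svg(file, width = width, height = height),
         pdf = grDevices::pdf(file, width = width, height = height),
         stop("unsupported figure format: .", ext))
  TRUE
}

#' Summarize normal/abnormal marker combinations (UpSet counts)
#'
#' Flags every subject's markers against the model's Youden cutoffs and
#' tabulates all `2^k` flag patterns (`A` = abnormal, `N` = normal, in
#' panel-marker order): subject counts, fractions of the question subset,
#' and the outcome-class composition within each pattern. Empty patterns
#' are carried with count 0. Patterns are ordered by descending count,
#' ties by the pattern's binary value.
#'
#' @param data question subset with the model's marker columns.
#' @param model a `question_model`.
#' @return An `upset_summary`: list with `combos` (data.frame `pattern`,
#'   `count`, `fraction`, `frac_positive`, `frac_negative`), `markers`,
#'   `n`, `question_id`.
#' @export
upset_summarize <- function(data, model) {
  stopifnot(inherits(model, "question_model"))
  cc <- stats::complete.cases(data[model$markers])
  d <- data[cc, , drop = FALSE]
  if (nrow(d) == 0) stop("empty subset")
  mt <- model$marker_thresholds
  flags <- sapply(seq_len(nrow(mt)), function(i) {
    v <- d[[mt$marker[i]]]
    if (mt$direction[i] == "higher_abnormal") v >= mt$cutoff[i] else
      v <= mt$cutoff[i]
  })
  flags <- matrix(flags, nrow = nrow(d))
  pattern <- apply(flags, 1, function(f)
    paste(ifelse(f, "A", "N"), collapse = ""))

  k <- nrow(mt)
  all_patterns <- apply(expand.grid(rep(list(c("N", "A")), k))[k:1], 1,
                        paste, collapse = "")
  counts <- table(factor(pattern, levels = all_patterns))
  y <- if ("outcome" %in% names(d)) as.integer(d$outcome) else
    rep(NA_integer_, nrow(d))
  frac_pos <- vapply(all_patterns, function(p) {
    sel <- pattern == p
    if (!any(sel)) NA_real_ else mean(y[sel] == 1)
  }, numeric(1))

  combos <- data.frame(pattern = all_patterns,
                       count = as.integer(counts),
                       fraction = as.integer(counts) / nrow(d),
                       frac_positive = frac_pos,
                       frac_negative = 1 - frac_pos,
                       stringsAsFactors = FALSE)
  binval <- vapply(strtoi(chartr("NA", "01", combos$pattern), base = 2L),
                   identity, integer(1))
  combos <- combos[order(-combos$count, binval), , drop = FALSE]
  rownames(combos) <- NULL
  structure(list(combos = combos, markers = mt$marker, n = nrow(d),
                 question_id = model$question_id),
            class = "upset_summary")
}

#' @export
print.upset_summary <- function(x, ...) {
  cat("UpSet summary",
      if (!is.null(x$question_id)) paste0("(", x$question_id, ")"),
      "- markers:", paste(x$markers, collapse = ", "), "\n")
  print(x$combos, row.names = FALSE)
  invisible(x)
}

#' Plot an UpSet summary
#'
#' Matrix-dot UpSet layout: stacked bars (outcome-class composition) on
#' top, the normal/abnormal dot matrix below (filled dot = abnormal).
#' An optional highlight box marks one pattern column, used to show
#' where an individual patient falls.
#'
#' @param x an `upset_summary`.
#' @param highlight optional flag pattern (e.g. `"ANA"`) to box.
#' @param class_labels labels for the negative/positive outcome classes.
#' @param file optional output file (`.png`, `.svg` or `.pdf`).
#' @param ... unused.
#' @return The summary, invisibly.
#' @export
plot.upset_summary <- function(x, highlight = NULL,
                               class_labels = c("negative", "positive"),
                               file = NULL, ...) {
  if (!is.null(highlight) && !highlight %in% x$combos$pattern)
    stop("highlight pattern not a valid combo: ", highlight)
  dev <- .open_device(file, 8, 5)
  if (dev) on.exit(grDevices::dev.off(), add = TRUE)

  cb <- x$combos
  k <- length(x$markers)
  nc <- nrow(cb)
  op <- graphics::par(mfrow = c(2, 1),
                      mar = c(0.5, 9, 2, 1), oma = c(0, 0, 0, 0))
  on.exit(graphics::par(op), add = TRUE)

  pos_cnt <- ifelse(is.na(cb$frac_positive), 0, cb$frac_positive) * cb$count
  h <- rbind(cb$count - pos_cnt, pos_cnt)
  mids <- graphics::barplot(h, col = c("grey80", "grey30"), border = NA,
                            names.arg = rep("", nc),
                            ylab = "subjects",
                            main = if (!is.null(x$question_id))
                              x$question_id else "")
  pct <- sprintf("%.0f%%", 100 * cb$fraction)
  graphics::text(mids, cb$count, pct, pos = 3, cex = 0.7, xpd = NA)
  graphics::legend("topright", bty = "n", fill = c("grey80", "grey30"),
                   legend = class_labels, cex = 0.8)

  graphics::par(mar = c(1, 9, 0.5, 1))
  graphics::plot(NA, xlim = range(mids) + c(-0.6, 0.6), ylim = c(0.5, k + 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = k:1, labels = marker_labels(x$markers),
                 las = 1, tick = FALSE, cex.axis = 0.9)
  for (j in seq_len(nc)) {
    f <- strsplit(cb$pattern[j], "")[[1]] == "A"
    graphics::points(rep(mids[j], k), k:1, pch = 21, cex = 1.6,
                     bg = ifelse(f, "grey20", "grey90"),
                     col = "grey40")
  }
  if (!is.null(highlight)) {
    j <- match(highlight, cb$pattern)
    w <- if (nc > 1) (mids[2] - mids[1]) * 0.45 else 0.5
    graphics::rect(mids[j] - w, 0.5, mids[j] + w, k + 0.5,
                   border = "firebrick", lwd = 2)
  }
  invisible(x)
}

# kernel density on [0, 1] with boundary reflection at both ends,
# renormalized to integrate to 1 on the grid
.reflected_density <- function(x, grid) {
  bw <- stats::bw.nrd0(x)
  aug <- c(x, -x, 2 - x)
  d <- stats::density(aug, bw = bw, from = -0.5, to = 1.5, n = 1024)
  f <- 3 * stats::approx(d$x, d$y, xout = grid, rule = 2)$y
  area <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  f / area
}

#' Probability density plot specification
#'
#' Smoothed (Gaussian kernel, Silverman bandwidth, boundary-reflected)
#' probability densities per outcome class on a \[0, 1\] grid, together
#' with the model's three probability thresholds.
#'
#' @param model a `question_model`.
#' @param data optional question subset; when omitted the model's stored
#'   development probabilities are used.
#' @param grid_n grid resolution.
#' @return A `density_spec`: list with `grid`, `densities` (per class),
#'   `thresholds`, `question_id`.
#' @export
density_spec <- function(model, data = NULL, grid_n = 201) {
  if (is.null(data)) {
    probs <- model$fitted_probs
    y <- model$outcome
    if (is.null(probs)) stop("no development probabilities stored; supply data")
  } else {
    cc <- stats::complete.cases(data[model$markers])
    d <- data[cc, , drop = FALSE]
    probs <- predict(model, d)
    y <- as.integer(d$outcome)
  }
  grid <- seq(0, 1, length.out = grid_n)
  dens <- list()
  for (cls in c(0, 1)) {
    p <- probs[y == cls]
    if (length(p) < 5) {
      warning("fewer than 5 probabilities in class ", cls,
              "; rug fallback (no density)")
      dens[[as.character(cls)]] <- list(points = p, density = NULL)
    } else {
      dens[[as.character(cls)]] <- list(points = p,
                                        density = .reflected_density(p, grid))
    }
  }
  structure(list(grid = grid, densities = dens,
                 thresholds = model$prob_thresholds,
                 question_id = model$question_id),
            class = "density_spec")
}

#' Plot class-wise probability densities with threshold lines
#'
#' @param x a `density_spec`.
#' @param patient_probability optional probability drawn as a vertical
#'   patient line.
#' @param class_labels labels for the negative/positive classes.
#' @param file optional output file (`.png`, `.svg` or `.pdf`).
#' @param ... unused.
#' @return The spec, invisibly.
#' @export
plot.density_spec <- function(x, patient_probability = NULL,
                              class_labels = c("negative", "positive"),
                              file = NULL, ...) {
  dev <- .open_device(file, 7, 4.5)
  if (dev) on.exit(grDevices::dev.off(), add = TRUE)
  cols <- c("steelblue", "firebrick")
  ymax <- max(1, unlist(lapply(x$densities, function(d) d$density)))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, ymax * 1.05),
                 xlab = "diagnostic probability", ylab = "density",
                 main = if (!is.null(x$question_id)) x$question_id else "")
  for (i in 1:2) {
    d <- x$densities[[i]]
    if (is.null(d$density)) graphics::rug(d$points, col = cols[i]) else
      graphics::lines(x$grid, d$density, col = cols[i], lwd = 2)
  }
  thr <- x$thresholds
  for (nm in c("sens90", "youden", "spec90")) {
    v <- thr[[nm]]
    if (is.finite(v)) {
      graphics::abline(v = v, lty = c(sens90 = 2, youden = 1, spec90 = 3)[nm],
                       col = "grey40")
      graphics::mtext(nm, side = 3, at = v, cex = 0.65, line = 0.1)
    }
  }
  if (!is.null(patient_probability))
    graphics::abline(v = patient_probability, col = "black", lwd = 2)
  graphics::legend("top", bty = "n", lwd = 2, col = cols,
                   legend = class_labels, cex = 0.8)
  invisible(x)
}

#' Composite single-patient report
#'
#' The clinical result interface for one patient and one clinical
#' question: a value-vs-threshold table with abnormal flags, the UpSet
#' plot of the development cohort with the patient's combination boxed,
#' and the density plot with the patient's probability as a vertical
#' line plus the likelihood-zone statement.
#'
#' @param model a `question_model`.
#' @param panel named raw marker values (see [classify_patient()]).
#' @param age age in years.
#' @param data development question subset used for the cohort
#'   background (UpSet counts, densities).
#' @param age_spec [age_correction_spec()] for NfL.
#' @param class_labels labels for the negative/positive classes.
#' @param file optional output file (`.png`, `.svg` or `.pdf`).
#' @return Invisibly, a list with the `patient_result`, the
#'   `upset_summary`, the `density_spec` and the report `table`.
#' @export
patient_report <- function(model, panel, age, data,
                           age_spec = age_correction_spec(),
                           class_labels = c("negative", "positive"),
                           file = NULL) {
  res <- classify_patient(model, panel, age, age_spec)
  ups <- upset_summarize(data, model)
  dsp <- density_spec(model, data)
  mt <- model$marker_thresholds
  tab <- data.frame(marker = marker_labels(mt$marker),
                    value = unname(res$values[mt$marker]),
                    threshold = mt$cutoff,
                    direction = mt$direction,
                    flag = ifelse(res$flags[mt$marker],
                                  "ABNORMAL", "normal"),
                    stringsAsFactors = FALSE)

  dev <- .open_device(file, 8, 10)
  if (dev) on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)

  graphics::layout(matrix(c(1, 2, 3, 4), ncol = 1),
                   heights = c(1.2, 1.6, 1.2, 1.6))
  graphics::par(mar = c(0.5, 2, 2, 1))
  graphics::plot.new()
  graphics::title(main = sprintf("%s - probability %.2f (%s likelihood)",
                                 model$question_id, res$probability,
                                 res$zone))
  for (i in seq_len(nrow(tab)))
    graphics::text(0.02, 0.9 - 0.25 * i, adj = 0, cex = 0.95,
                   sprintf("%-14s %8.3f   (cutoff %.3f, %s)  %s",
                           tab$marker[i], tab$value[i], tab$threshold[i],
                           tab$direction[i], tab$flag[i]))

  # UpSet panels (bars + dots) drawn into the next two layout cells
  graphics::par(mar = c(0.5, 9, 2, 1))
  cb <- ups$combos
  pos_cnt <- ifelse(is.na(cb$frac_positive), 0, cb$frac_positive) * cb$count
  mids <- graphics::barplot(rbind(cb$count - pos_cnt, pos_cnt),
                            col = c("grey80", "grey30"), border = NA,
                            names.arg = rep("", nrow(cb)),
                            ylab = "subjects")
  graphics::legend("topright", bty = "n", fill = c("grey80", "grey30"),
                   legend = class_labels, cex = 0.8)
  k <- length(ups$markers)
  graphics::par(mar = c(1, 9, 0.5, 1))
  graphics::plot(NA, xlim = range(mids) + c(-0.6, 0.6),
                 ylim = c(0.5, k + 0.5), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = k:1, labels = marker_labels(ups$markers),
                 las = 1, tick = FALSE, cex.axis = 0.9)
  for (j in seq_len(nrow(cb))) {
    f <- strsplit(cb$pattern[j], "")[[1]] == "A"
    graphics::points(rep(mids[j], k), k:1, pch = 21, cex = 1.5,
                     bg = ifelse(f, "grey20", "grey90"), col = "grey40")
  }
  j <- match(res$pattern, cb$pattern)
  w <- if (nrow(cb) > 1) (mids[2] - mids[1]) * 0.45 else 0.5
  graphics::rect(mids[j] - w, 0.5, mids[j] + w, k + 0.5,
                 border = "firebrick", lwd = 2)

  graphics::par(mar = c(4, 4, 2, 1))
  cols <- c("steelblue", "firebrick")
  ymax <- max(1, unlist(lapply(dsp$densities, function(d) d$density)))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, ymax * 1.05),
                 xlab = "diagnostic probability", ylab = "density")
  for (i in 1:2) {
    d <- dsp$densities[[i]]
    if (!is.null(d$density))
      graphics::lines(dsp$grid, d$density, col = cols[i], lwd = 2)
  }
  thr <- dsp$thresholds
  for (nm in c("sens90", "youden", "spec90"))
    if (is.finite(thr[[nm]])) graphics::abline(v = thr[[nm]], lty = 2,
                                               col = "grey40")
  graphics::abline(v = res$probability, lwd = 2)

  invisible(list(result = res, upset = ups, density = dsp, table = tab))
}
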
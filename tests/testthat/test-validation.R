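# single-marker stub whose probabilities are plogis(x)
identity_model <- function() stub_model(c("(Intercept)" = 0, x = 1))

test_that("transported discrimination matches a hand count", {
  m <- identity_model()
  d <- data.frame(x = qlogis(c(0.9, 0.8, 0.1)), outcome = c(1, 0, 0))
  r <- transported_discrimination(m, d, cutoff = 0.5)
  expect_equal(unclass(r$confusion_matrix)[1, ], c("1" = 1, "0" = 1))
  expect_equal(unclass(r$confusion_matrix)[2, ], c("1" = 0, "0" = 1))
  expect_equal(r$accuracy, 2 / 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0.5)

  d_onecls <- data.frame(x = rnorm(5), outcome = rep(1, 5))
  expect_error(transported_discrimination(m, d_onecls), "single outcome")
})

test_that("calibration recovers intercept and slope distortions", {
  m <- identity_model()
  set.seed(31)
  n <- 6000
  lp <- rnorm(n, 0, 1.5)
  d0 <- data.frame(x = lp, outcome = rbinom(n, 1, plogis(lp)))
  cal0 <- calibration_metrics(m, d0)
  expect_equal(cal0$citl, 0, tolerance = 0.12)
  expect_equal(cal0$cal_slope, 1, tolerance = 0.1)

  d1 <- data.frame(x = lp, outcome = rbinom(n, 1, plogis(lp + 1)))
  expect_equal(calibration_metrics(m, d1)$citl, 1, tolerance = 0.15)

  d2 <- data.frame(x = lp, outcome = rbinom(n, 1, plogis(2 * lp)))
  expect_equal(calibration_metrics(m, d2)$cal_slope, 2, tolerance = 0.2)

  dc <- data.frame(x = rep(1, 20), outcome = rep(c(0, 1), 10))
  expect_error(calibration_metrics(m, dc), "degenerate")
})

test_that("calibration curve bins by deciles and degrades gracefully", {
  m <- identity_model()
  set.seed(32)
  lp <- rnorm(1000, 0, 1.5)
  d <- data.frame(x = lp, outcome = rbinom(1000, 1, plogis(lp)))
  cc <- calibration_curve(m, d, bins = 10)
  expect_equal(nrow(cc$binned), 10)
  expect_true(all(cc$binned$n == 100))
  expect_equal(nrow(cc$smoothed), 100)

  # well-calibrated: binned points inside 3-SE binomial bands
  se <- sqrt(cc$binned$mean_predicted * (1 - cc$binned$mean_predicted) /
               cc$binned$n)
  expect_true(all(abs(cc$binned$observed - cc$binned$mean_predicted) <
                    3 * se + 0.02))

  dconst <- data.frame(x = rep(0.3, 50), outcome = rbinom(50, 1, 0.3))
  expect_warning(cc2 <- calibration_curve(m, dconst), "constant")
  expect_equal(nrow(cc2$binned), 1)
})

test_that("membership model quantifies case-mix difference", {
  set.seed(33)
  d <- sim_labeled(400, seed = 33)
  attr(d, "question") <- "Qx"
  same <- membership_auc(d, d, c("ptau181", "gfap"), folds = 5, seed = 1)
  expect_lt(abs(same$auc - 0.5), 0.1)

  shifted <- d
  shifted$ptau181 <- shifted$ptau181 + 5 * sd(d$ptau181)
  far <- membership_auc(d, shifted, c("ptau181", "gfap"),
                        folds = 5, seed = 1)
  expect_gt(far$auc, 0.95)

  # pooled out-of-fold AUC equals the rank-statistic oracle
  expect_equal(same$auc, oracle_auc(same$scores, same$labels),
               tolerance = 1e-10)

  # label-swap symmetry
  swapped <- membership_auc(d, shifted, c("ptau181", "gfap"),
                            folds = 5, seed = 1)
  expect_equal(far$auc, swapped$auc)
})

test_that("threshold recalculation detects shifts and scales", {
  co <- simulate_cohort(seed = 34)
  m <- fit_question_model(co, "Q2")
  q2 <- subset_for_question(co, "Q2")

  same <- recalculate_thresholds(q2, m)
  expect_equal(same$marker_thresholds$validation,
               same$marker_thresholds$development, tolerance = 1e-12)
  expect_true(all(same$marker_thresholds$rel_difference < 1e-12))

  doubled <- q2
  for (mk in m$markers) doubled[[mk]] <- 2 * doubled[[mk]]
  sc <- recalculate_thresholds(doubled, m)
  expect_equal(sc$marker_thresholds$validation,
               2 * sc$marker_thresholds$development, tolerance = 1e-12)
  expect_true(all(sc$marker_thresholds$flagged))
})

test_that("full validation report assembles and prints", {
  co <- simulate_cohort(seed = 35)
  val <- simulate_cohort(seed = 36, name = "val")
  m <- fit_question_model(co, "Q1")
  vr <- validate_model(m, val)
  expect_s3_class(vr, "validation_report")
  expect_equal(sum(vr$confusion_matrix), vr$n)
  expect_true(is.finite(vr$citl) && is.finite(vr$cal_slope))
  expect_output(print(vr), "External validation")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(vr))
})
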
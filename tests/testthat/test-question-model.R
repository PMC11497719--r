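test_that("logistic fit recovers a null model and flags separation", {
  set.seed(21)
  d <- sim_labeled(5000, beta = c(0.4, 0, 0, 0), seed = 21)
  fit <- fit_logistic(d, c("ptau181", "gfap", "nfl_age_corrected"))
  expect_lt(max(abs(fit$coefficients[-1] *
                      sapply(d[c("ptau181", "gfap", "nfl_age_corrected")],
                             sd))), 0.1)
  expect_lt(abs(fit$coefficients[1] - qlogis(mean(d$outcome))), 0.3)

  sep <- data.frame(ptau181 = c(1, 2, 5, 6), gfap = c(3, 7, 2, 9),
                    outcome = c(0, 0, 1, 1))
  expect_error(suppressWarnings(fit_logistic(sep, c("ptau181", "gfap"))),
               "separation on marker ptau181")
})

test_that("Youden cutoffs match hand examples and the exhaustive oracle", {
  y1 <- youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1), "higher_abnormal")
  expect_equal(y1$cutoff, 2.5)
  expect_equal(y1$j, 1)

  y2 <- youden_threshold(c(0.07, 0.06, 0.05, 0.04), c(0, 0, 1, 1),
                         "lower_abnormal")
  expect_equal(y2$cutoff, 0.055)
  expect_equal(y2$j, 1)

  set.seed(12)
  for (rep in 1:10) {
    scores <- round(rnorm(200), 2)  # rounding induces ties
    labels <- rbinom(200, 1, plogis(scores))
    if (length(unique(labels)) < 2) next
    for (dirn in c("higher_abnormal", "lower_abnormal"))
      expect_equal(youden_threshold(scores, labels, dirn)$cutoff,
                   oracle_youden(scores, labels, dirn))
  }

  expect_error(youden_threshold(rep(2, 6), c(0, 0, 0, 1, 1, 1)),
               "constant")
})

test_that("probability thresholds satisfy their coverage definitions", {
  set.seed(13)
  probs <- c(runif(400, 0.6, 1), runif(400, 0, 0.4))
  labels <- rep(c(1, 0), each = 400)
  pt <- probability_thresholds(probs, labels)
  expect_equal(pt$sens90, 0.64, tolerance = 0.03)
  expect_equal(pt$spec90, 0.36, tolerance = 0.03)
  expect_true(pt$inverted_zones)  # fully separated: no intermediate band

  # defining inequalities recounted directly on the sample
  expect_gte(mean(probs[labels == 1] >= pt$sens90), 0.90)
  expect_gte(mean(probs[labels == 0] < pt$spec90), 0.90)

  # overlapping classes give a proper intermediate band
  set.seed(14)
  p2 <- plogis(c(rnorm(500, 1), rnorm(500, -1)))
  l2 <- rep(c(1, 0), each = 500)
  pt2 <- probability_thresholds(p2, l2)
  expect_false(pt2$inverted_zones)
  expect_lt(pt2$sens90, pt2$spec90)

  expect_error(probability_thresholds(rep(0.4, 10), rep(c(0, 1), 5)),
               "constant")
})

test_that("cross-validated AUC equals the Mann-Whitney rank statistic", {
  # perfectly separating marker
  d <- data.frame(ptau181 = c(1:5, 11:15), gfap = rnorm(10, 100),
                  outcome = rep(c(0, 1), each = 5))
  expect_equal(cv_auc(d, "ptau181")$auc, 1.0)

  set.seed(15)
  d2 <- sim_labeled(300, seed = 15)
  r <- cv_auc(d2, c("ptau181", "gfap", "nfl_age_corrected"),
              folds = 5, seed = 2)
  expect_equal(r$auc, oracle_auc(r$scores, r$labels), tolerance = 1e-10)

  # null marker: CI straddles 0.5
  d3 <- sim_labeled(2000, beta = c(0, 0, 0, 0), seed = 16)
  r3 <- cv_auc(d3, "gfap")
  expect_gt(0.5, r3$ci[1])
  expect_lt(0.5, r3$ci[2])

  # monotone-transform invariance for a single marker
  d4 <- d2
  d4$ptau181 <- exp(d4$ptau181)
  expect_equal(cv_auc(d2, "ptau181")$auc, cv_auc(d4, "ptau181")$auc)
})

test_that("fitted question model is internally consistent", {
  co <- simulate_cohort(seed = 20)
  m <- fit_question_model(co, "Q2", seed = 3)
  expect_s3_class(m, "question_model")
  expect_equal(m$question_id, "Q2_abeta_predementia")
  expect_equal(nrow(m$marker_thresholds), 3)
  expect_true(m$cv_auc$auc > 0.5 && m$cv_auc$auc < 1)
  pt <- m$prob_thresholds
  expect_true(all(unlist(pt[c("youden")]) > 0 & unlist(pt[c("youden")]) < 1))

  # probability strictly increasing in a positive-coefficient marker
  base <- list(ptau181 = 2, gfap = 100, nfl = 15)
  stopifnot(m$coefficients["ptau181"] > 0)
  p_lo <- classify_patient(m, base, age = 65)$probability
  base$ptau181 <- 3
  p_hi <- classify_patient(m, base, age = 65)$probability
  expect_gt(p_hi, p_lo)

  # determinism given the seed
  m2 <- fit_question_model(co, "Q2", seed = 3)
  expect_identical(m$cv_auc, m2$cv_auc)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("patient classification respects zone boundaries and flags", {
  # thresholds set to exactly representable probabilities so the
  # boundary comparison is exact
  sm <- stub_model(c("(Intercept)" = 0, x = 1),
                   prob_thresholds = list(youden = 0.5,
                                          sens90 = plogis(-1),
                                          spec90 = plogis(1),
                                          inverted_zones = FALSE))
  # probability exactly at the spec90 cutoff is high (inclusive)
  p_at <- classify_patient(sm, list(x = 1), age = 60)
  expect_identical(p_at$probability, plogis(1))
  expect_equal(p_at$zone, "high")
  p_low <- classify_patient(sm, list(x = -1), age = 60)
  expect_equal(p_low$zone, "low")  # boundary inclusive on the low side
  p_mid <- classify_patient(sm, list(x = 0), age = 60)
  expect_equal(p_mid$zone, "indeterminate")

  expect_error(classify_patient(sm, list(gfap = 1), age = 60),
               "missing required marker")

  # all markers at control medians of a synthetic fit -> low, no flags
  co <- simulate_cohort(seed = 22)
  m <- fit_question_model(co, "Q4")
  q4 <- subset_for_question(co, "Q4")
  ctrl <- q4[q4$outcome == 0, ]
  res <- classify_patient(m, list(ptau181 = median(ctrl$ptau181),
                                  gfap = median(ctrl$gfap),
                                  nfl = median(ctrl$nfl)), age = 60)
  expect_equal(res$zone, "low")
  expect_false(any(res$flags))
})

test_that("serialized models reload and classify identically", {
  co <- simulate_cohort(seed = 23)
  m <- fit_question_model(co, "Q3")
  path <- withr::local_tempfile(fileext = ".json")
  write_question_model(m, path)
  m2 <- read_question_model(path)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)

  panel <- list(ptau181 = 2.6, gfap = 140, nfl = 19)
  r1 <- classify_patient(m, panel, age = 66)
  r2 <- classify_patient(m2, panel, age = 66)
  expect_equal(r1$probability, r2$probability, tolerance = 1e-12)
  expect_identical(r1$zone, r2$zone)
  expect_identical(r1$flags, r2$flags)
})
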
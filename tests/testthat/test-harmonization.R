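test_that("Passing-Bablok recovers exact linear relations", {
  f1 <- passing_bablok(1:5, 1:5)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)

  f2 <- passing_bablok(1:5, 2 * (1:5) + 1)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)

  # symmetric equivariance on exact linear data
  f3 <- passing_bablok(2 * (1:5) + 1, 1:5)
  expect_equal(f3$slope, 1 / f2$slope)

  expect_error(passing_bablok(1:2, 1:2), "at least 3")
  expect_error(passing_bablok(rep(2, 5), 1:5), "identical")
})

test_that("Passing-Bablok slope equals the pairwise-median oracle on noisy data", {
  set.seed(11)
  for (rep in 1:5) {
    x <- runif(35, 5, 50)
    y <- 1.3 * x + 5 + rnorm(35, 0, 2)
    fit <- passing_bablok(x, y)
    expect_equal(fit$slope, oracle_pb_slope(x, y))
  }

  # the 95% intervals attain close-to-nominal coverage of (1.3, 5)
  set.seed(7)
  cov_slope <- cov_int <- 0
  for (rep in 1:200) {
    x <- runif(35, 5, 50)
    y <- 1.3 * x + 5 + rnorm(35, 0, 2)
    fit <- passing_bablok(x, y)
    cov_slope <- cov_slope +
      (fit$slope_ci[1] <= 1.3 && 1.3 <= fit$slope_ci[2])
    cov_int <- cov_int +
      (fit$intercept_ci[1] <= 5 && 5 <= fit$intercept_ci[2])
  }
  expect_gte(cov_slope / 200, 0.85)
  expect_gte(cov_int / 200, 0.80)
})

test_that("alignment is affine and commutes with threshold recomputation", {
  model <- list(slope = 2, intercept = 1)
  expect_equal(apply_alignment(10, model), 21)
  expect_equal(apply_alignment(c(3, 7), list(slope = 1, intercept = 0)),
               c(3, 7))
  expect_warning(out <- apply_alignment(2, list(slope = 1, intercept = -5)),
                 "non-positive")
  expect_true(is.na(out))

  set.seed(3)
  scores <- rlnorm(80, 2, 0.7)
  labels <- rbinom(80, 1, plogis(scale(scores)))
  if (length(unique(labels)) == 2) {
    cut_raw <- youden_threshold(scores, labels)$cutoff
    cut_aligned <- youden_threshold(apply_alignment(scores, model),
                                    labels)$cutoff
    expect_equal(cut_aligned, model$intercept + model$slope * cut_raw)
  }
})

test_that("NfL age correction follows the configured reference form", {
  expect_equal(correct_nfl_for_age(20, 65), 20)
  spec <- age_correction_spec("log_linear_reference", b0 = log(20), b1 = 0)
  expect_equal(correct_nfl_for_age(20, 65, spec), 1.0)

  spec2 <- age_correction_spec("log_linear_reference", b0 = 1, b1 = 0.02)
  ages <- 40:90
  corrected <- correct_nfl_for_age(rep(25, length(ages)), ages, spec2)
  expect_true(all(diff(corrected) < 0))

  expect_error(age_correction_spec("log_linear_reference"), "coefficients")
  expect_error(correct_nfl_for_age(-1, 65), "positive")
  expect_error(correct_nfl_for_age(20, 130), "age")
})

test_that("amyloid adjudication applies the printed cutoff rules", {
  pos <- function(...) adjudicate_amyloid(list(...))
  expect_equal(pos(amyloid_evidence("csf_innotest",
                                    ptau181 = 60, abeta42 = 800)),
               "positive")  # ratio 0.075 > 0.06
  expect_equal(pos(amyloid_evidence("csf_innotest", ratio = 0.06)),
               "negative")  # strict >
  expect_equal(pos(amyloid_evidence("csf_elecsys", ratio = 0.015)),
               "negative")
  expect_equal(pos(amyloid_evidence("csf_elecsys", ratio = 0.021)),
               "positive")
  expect_equal(pos(amyloid_evidence("pet_centiloid", centiloid = 31)),
               "positive")
  expect_equal(pos(amyloid_evidence("pet_centiloid", centiloid = 30)),
               "negative")
  expect_equal(pos(amyloid_evidence("csf_lumipulse_ratio", ratio = 0.0689)),
               "positive")
  expect_equal(pos(amyloid_evidence("csf_lumipulse_ab42", abeta42 = 700)),
               "positive")
  expect_equal(pos(amyloid_evidence("csf_innotest_ab42", abeta42 = 880.4)),
               "positive")
  expect_equal(pos(amyloid_evidence("csf_innotest_ab42", abeta42 = 900)),
               "negative")
  expect_equal(pos(amyloid_evidence("csf_lumipulse_spin", ratio = 0.063)),
               "negative")
  expect_equal(adjudicate_amyloid(list()), "unknown")
})

test_that("PET precedence and same-tier conflicts are handled", {
  res <- adjudicate_amyloid(list(
    amyloid_evidence("pet_visual", read = "negative"),
    amyloid_evidence("csf_innotest", ratio = 0.075)))
  expect_equal(res, "negative")

  expect_warning(
    res2 <- adjudicate_amyloid(list(
      amyloid_evidence("csf_innotest", ratio = 0.075),
      amyloid_evidence("csf_elecsys", ratio = 0.015))),
    "conflicting")
  expect_equal(res2, "positive")

  expect_error(amyloid_evidence("csf_innotest"), "requires")
  expect_error(amyloid_evidence("pet_centiloid", centiloid = -3),
               "positive")
})
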
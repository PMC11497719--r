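test_that("lognormal moment matching round-trips exactly", {
  p0 <- lognormal_params_from_moments(1, 0)
  expect_equal(p0$mu, 0)
  expect_equal(p0$sigma, 0)

  p <- lognormal_params_from_moments(2.81, 1.08)
  implied_mean <- exp(p$mu + p$sigma^2 / 2)
  implied_sd <- sqrt((exp(p$sigma^2) - 1) * exp(2 * p$mu + p$sigma^2))
  expect_equal(implied_mean, 2.81, tolerance = 1e-12)
  expect_equal(implied_sd, 1.08, tolerance = 1e-12)

  expect_error(lognormal_params_from_moments(-1, 1), "positive")
})

test_that("default cohort reproduces the configured stratum sizes", {
  co <- simulate_cohort(seed = 51)
  expect_equal(nrow(co), 1199)
  tab <- table(co$group, co$amyloid)
  expect_equal(unname(tab["SCD", "negative"]), 259)
  expect_equal(unname(tab["SCD", "positive"]), 64)
  expect_equal(unname(tab["MCI", "negative"]), 116)
  expect_equal(unname(tab["MCI", "positive"]), 167)
  expect_equal(sum(co$group == "AD_dementia"), 320)
  expect_equal(sum(co$group == "FTD"), 162)
  expect_equal(sum(co$group == "DLB"), 111)
  expect_true(all(co$amyloid[co$group == "AD_dementia"] == "positive"))
  expect_true(all(co$age >= 18 & co$age <= 100))

  # identical seed, identical cohort
  co2 <- simulate_cohort(seed = 51)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  co3 <- simulate_cohort(seed = 52)
  expect_false(identical(co$ptau181, co3$ptau181))
})

test_that("group marginals match the configured moments", {
  cfg <- default_sim_config()
  ad <- cfg$groups[[which(vapply(cfg$groups, `[[`, "", "name") ==
                            "AD_dementia")]]
  set.seed(53)
  g <- simulate_group(ad, cfg, n = 30000)
  for (mk in c("ptau181", "gfap", "nfl")) {
    mm <- ad$markers[[mk]]
    se <- mm[["sd"]] / sqrt(30000)
    expect_lt(abs(mean(g[[mk]]) - mm[["mean"]]), 3 * se)
  }
  # copula correlation close to target on the rank scale
  rho <- cor(g$ptau181, g$gfap, method = "spearman")
  expect_lt(abs(rho - 0.3), 0.05)
})

test_that("amyloid mixtures follow the configured fractions", {
  cfg <- default_sim_config()
  ftd <- cfg$groups[[which(vapply(cfg$groups, `[[`, "", "name") == "FTD")]]
  set.seed(54)
  g <- simulate_group(ftd, cfg, n = 20000)
  se <- sqrt(0.17 * 0.83 / 20000)
  expect_lt(abs(mean(g$amyloid == "positive") - 0.17), 3 * se)
})

test_that("site shift closes the harmonization loop", {
  cfg <- default_sim_config()
  spec <- cfg$groups[[1]]
  set.seed(55)
  g <- simulate_group(spec, cfg, n = 35)
  original <- g$gfap
  shifted <- 3 + 1.2 * original
  fit <- passing_bablok(original, shifted)
  expect_equal(fit$slope, 1.2, tolerance = 1e-9)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)

  # shift applied through the cohort config, recovered within the CI
  cfg2 <- sim_config(groups = cfg$groups,
                     site_shift = list(gfap = c(slope = 1.2, intercept = 3)))
  co_plain <- simulate_cohort(cfg, seed = 56)
  co_shift <- simulate_cohort(cfg2, seed = 56)
  idx <- 1:35
  fit2 <- passing_bablok(co_plain$gfap[idx], co_shift$gfap[idx])
  expect_true(fit2$slope_ci[1] <= 1.2 && 1.2 <= fit2$slope_ci[2])
  expect_true(fit2$intercept_ci[1] <= 3 && 3 <= fit2$intercept_ci[2])
})

test_that("single-group and custom configurations are honoured", {
  cfg <- default_sim_config()
  solo <- sim_config(groups = cfg$groups[7])
  co <- simulate_cohort(solo, seed = 57)
  expect_equal(unique(co$group), "DLB")
  expect_equal(nrow(co), 111)

  expect_error(sim_config(groups = cfg$groups, correlation = 1.5),
               "positive-definite")

  # optional co-pathology shift only touches amyloid-positive subjects
  shifted <- sim_config(groups = cfg$groups[7],
                        abeta_pos_shift = c(ptau181 = 5))
  co_s <- simulate_cohort(shifted, seed = 57)
  pos <- co$amyloid == "positive"
  expect_equal(co_s$ptau181[pos], co$ptau181[pos] + 5)
  expect_equal(co_s$ptau181[!pos], co$ptau181[!pos])
})

test_that("age coupling hook feeds the age-correction operation", {
  cfg0 <- default_sim_config()
  cfg <- sim_config(groups = cfg0$groups, nfl_age_effect = 0.025)
  co <- simulate_cohort(cfg, seed = 58)
  # uncorrected NfL now rises with age; the matching correction removes it
  raw_cor <- cor(co$nfl, co$age, method = "spearman")
  expect_gt(raw_cor, 0.15)
  corr <- correct_nfl_for_age(co$nfl, co$age,
                              age_correction_spec("log_linear_reference",
                                                  b0 = 0, b1 = 0.025))
  expect_lt(abs(cor(corr, co$age, method = "spearman")), raw_cor)
})
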
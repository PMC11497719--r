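# small hand-built cohorts and labelled tables used across tests

hand_cohort_df <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    age = c(60, 66, 72, 64, 70, 58, 67),
    sex = c("female", "male", "male", "female", "male", "female", "male"),
    group = c("SCD", "MCI", "FTD", "AD_dementia", "DLB", "SCD", "MCI"),
    amyloid = c("negative", "positive", "negative", "positive",
                "positive", "unknown", "negative"),
    abeta_ratio = c(0.07, 0.05, 0.06, 0.045, 0.05, 0.065, 0.06),
    ptau181 = c(1.2, 2.5, 1.6, 3.1, 2.2, 1.3, 1.5),
    gfap = c(60, 120, 100, 160, 115, 70, 75),
    nfl = c(10, 18, 45, 21, 24, 11, 15),
    stringsAsFactors = FALSE)
}

hand_cohort <- function() {
  add_age_corrected_nfl(cohort(hand_cohort_df(), name = "hand"))
}

# labelled table drawn from a known logistic model on lognormal markers
sim_labeled <- function(n, beta = c(-3, 1.2, 0.01, 0.05), seed = 1) {
  set.seed(seed)
  d <- data.frame(ptau181 = rlnorm(n, 0.6, 0.5),
                  gfap = rlnorm(n, 4.6, 0.5),
                  nfl_age_corrected = rlnorm(n, 2.9, 0.6))
  lp <- beta[1] + beta[2] * d$ptau181 + beta[3] * d$gfap +
    beta[4] * d$nfl_age_corrected
  d$outcome <- rbinom(n, 1, plogis(lp))
  d
}

# fabricate a minimal question_model around known coefficients, for
# tests that need a frozen model with controlled probabilities
stub_model <- function(coefficients, markers = names(coefficients)[-1],
                       prob_thresholds = list(youden = 0.5, sens90 = 0.3,
                                              spec90 = 0.7,
                                              inverted_zones = FALSE)) {
  structure(list(question_id = "stub", markers = markers,
                 coefficients = coefficients,
                 marker_thresholds = data.frame(
                   marker = markers, cutoff = rep(1, length(markers)),
                   direction = rep("higher_abnormal", length(markers)),
                   stringsAsFactors = FALSE),
                 prob_thresholds = prob_thresholds,
                 zone_convention = "sensitivity_specificity"),
            class = "question_model")
}
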
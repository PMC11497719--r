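#' Log-scale parameters of a lognormal from natural-scale moments
#'
#' Method-of-moments inversion: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`, so the implied lognormal reproduces the
#' requested mean and SD exactly. An SD of zero returns the degenerate
#' point mass at `mean`.
#'
#' @param mean natural-scale mean (> 0).
#' @param sd natural-scale standard deviation (>= 0).
#' @return List with `mu` and `sigma`.
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  sigma2 <- log(1 + sd^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Per-group distribution specification
#'
#' Marginal marker distributions, demographics and amyloid mixture for
#' one diagnostic stratum of the synthetic generator. Marker marginals
#' are lognormal with moments matched to the supplied natural-scale mean
#' and SD, reflecting that concentration summaries in memory-clinic
#' cohorts are right-skewed with SDs approaching the means.
#'
#' @param name stratum name (used for subject ids).
#' @param group diagnostic group label.
#' @param n number of subjects.
#' @param markers named list of `c(mean, sd)` (or `list(mean=, sd=)`) per
#'   marker: `abeta_ratio`, `ptau181`, `gfap`, `nfl`.
#' @param age_mean,age_sd age distribution (years), truncated to
#'   \[18, 100\].
#' @param female_fraction probability of female sex.
#' @param amyloid fixed amyloid label for amyloid-stratified strata
#'   (`"positive"`/`"negative"`), or `NULL` for mixture groups.
#' @param abeta_positive_fraction amyloid-positivity probability for
#'   unstratified groups (ignored when `amyloid` is fixed).
#' @return A `group_spec` object.
#' @export
group_spec <- function(name, group, n, markers, age_mean, age_sd,
                       female_fraction, amyloid = NULL,
                       abeta_positive_fraction = NULL) {
  stopifnot(n >= 1, group %in% .diagnostic_groups(),
            female_fraction >= 0, female_fraction <= 1)
  markers <- lapply(markers, function(m) {
    m <- unlist(m)
    if (is.null(names(m))) names(m) <- c("mean", "sd")
    stopifnot(m[["mean"]] > 0, m[["sd"]] >= 0)
    m
  })
  miss <- setdiff(.raw_marker_cols(), names(markers))
  if (length(miss) > 0)
    stop("marker moments missing for: ", paste(miss, collapse = ", "))
  if (is.null(amyloid)) {
    if (is.null(abeta_positive_fraction))
      stop("unstratified group needs abeta_positive_fraction")
    stopifnot(abeta_positive_fraction >= 0, abeta_positive_fraction <= 1)
  }
  structure(list(name = name, group = group, n = as.integer(n),
                 markers = markers, age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction, amyloid = amyloid,
                 abeta_positive_fraction = abeta_positive_fraction),
            class = "group_spec")
}

#' Synthetic cohort configuration
#'
#' @param groups list of [group_spec()]s.
#' @param correlation inter-marker correlation on the Gaussian copula
#'   scale: a single pairwise value or a full positive-definite matrix
#'   over the four raw markers.
#' @param site_shift optional named list of `c(slope, intercept)` per
#'   marker, applied last as `intercept + slope * value` to emulate a
#'   different assay kit lot.
#' @param abeta_pos_shift optional named additive marker shift applied to
#'   amyloid-positive subjects of the mixture groups, to induce sharper
#'   co-pathology structure (default: none; the printed group summaries
#'   pool FTD/DLB over amyloid strata).
#' @param nfl_age_effect log-linear age effect on NfL per year (default
#'   0, i.e. markers independent of age within group); a non-zero value
#'   multiplies NfL by `exp(effect * (age - age_mean))`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(groups = NULL, correlation = 0.3,
                       site_shift = NULL, abeta_pos_shift = NULL,
                       nfl_age_effect = 0) {
  if (is.null(groups)) groups <- default_sim_config()$groups
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  k <- length(.raw_marker_cols())
  if (is.matrix(correlation)) {
    R <- correlation
    stopifnot(nrow(R) == k, ncol(R) == k, all(diag(R) == 1))
  } else {
    R <- matrix(correlation, k, k)
    diag(R) <- 1
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stop("correlation matrix must be positive-definite")
  structure(list(groups = groups, correlation = R,
                 site_shift = site_shift,
                 abeta_pos_shift = abeta_pos_shift,
                 nfl_age_effect = nfl_age_effect),
            class = "sim_config")
}

#' Default configuration from the bundled distribution table
#'
#' Reads the packaged per-stratum demographics, marker moments and
#' amyloid mixture fractions (seven strata, total n = 1199).
#'
#' @param path optional path to an alternative YAML configuration.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_defaults.yaml",
                        package = "plasmapanel")
  read_sim_config(path)
}

#' @rdname default_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g)
    group_spec(name = g$name, group = g$group, n = g$n_subjects,
               markers = g$markers,
               age_mean = g$age$mean, age_sd = g$age$sd,
               female_fraction = g$female_fraction,
               amyloid = g$amyloid,
               abeta_positive_fraction = g$abeta_positive_fraction))
  sim_config(groups = groups,
             correlation = if (is.null(y$correlation)) 0.3 else y$correlation)
}

# truncated-normal draw by inverse CDF on the truncated quantile range
.rtruncnorm <- function(n, mean, sd, lower = 18, upper = 100) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate one diagnostic stratum
#'
#' Markers are drawn from a Gaussian copula with the configured
#' correlation and lognormal marginals moment-matched to the stratum's
#' mean/SD; age is truncated-normal on \[18, 100\]; sex is Bernoulli on
#' the female fraction; the amyloid label is fixed for stratified groups
#' and Bernoulli on the positivity fraction otherwise.
#'
#' @param spec a [group_spec()].
#' @param config a [sim_config()] (its correlation and shift hooks are
#'   used).
#' @param n number of subjects (default `spec$n`).
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (so [simulate_cohort()] controls reproducibility with one seed).
#' @param id_offset integer offset for subject-id numbering.
#' @return A data.frame of subjects (not yet a validated cohort).
#' @export
simulate_group <- function(spec, config = sim_config(), n = spec$n,
                           seed = NULL, id_offset = 0L) {
  if (!is.null(seed)) set.seed(seed)
  mk <- .raw_marker_cols()
  L <- chol(config$correlation)
  Z <- matrix(stats::rnorm(n * length(mk)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- mk

  vals <- sapply(mk, function(m) {
    mm <- spec$markers[[m]]
    if (mm[["sd"]] == 0) return(rep(mm[["mean"]], n))
    p <- lognormal_params_from_moments(mm[["mean"]], mm[["sd"]])
    stats::qlnorm(U[, m], p$mu, p$sigma)
  })
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, mk))

  age <- .rtruncnorm(n, spec$age_mean, spec$age_sd)
  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  amyloid <- if (!is.null(spec$amyloid)) rep(spec$amyloid, n) else
    ifelse(stats::runif(n) < spec$abeta_positive_fraction,
           "positive", "negative")

  if (config$nfl_age_effect != 0)
    vals[, "nfl"] <- vals[, "nfl"] *
      exp(config$nfl_age_effect * (age - spec$age_mean))

  if (!is.null(config$abeta_pos_shift) && is.null(spec$amyloid)) {
    pos <- amyloid == "positive"
    for (m in names(config$abeta_pos_shift))
      vals[pos, m] <- vals[pos, m] + config$abeta_pos_shift[[m]]
  }

  data.frame(subject_id = sprintf("%s_%05d", spec$name,
                                  id_offset + seq_len(n)),
             age = age, sex = sex, group = spec$group, amyloid = amyloid,
             abeta_ratio = vals[, "abeta_ratio"],
             ptau181 = vals[, "ptau181"], gfap = vals[, "gfap"],
             nfl = vals[, "nfl"], stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Concatenates all configured strata (default: seven strata, n = 1199),
#' applies the optional site shift last, attaches age-corrected NfL
#' (identity correction by default) and returns a validated [cohort()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; a given seed yields an identical cohort.
#' @param name cohort name.
#' @param age_spec [age_correction_spec()] used for `nfl_age_corrected`.
#' @return A `cohort`.
#' @export
simulate_cohort <- function(config = default_sim_config(), seed = 1,
                            name = "synthetic", age_spec = age_correction_spec()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  parts <- lapply(config$groups, simulate_group, config = config)
  d <- do.call(rbind, parts)

  if (!is.null(config$site_shift)) {
    for (m in names(config$site_shift)) {
      sh <- unlist(config$site_shift[[m]])
      if (is.null(names(sh))) names(sh) <- c("slope", "intercept")
      d[[m]] <- sh[["intercept"]] + sh[["slope"]] * d[[m]]
    }
  }

  out <- cohort(d, name = name,
                provenance = list(generator = "gaussian-copula lognormal",
                                  seed = seed,
                                  site_shift = !is.null(config$site_shift)))
  add_age_corrected_nfl(out, age_spec)
}
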
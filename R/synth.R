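#' Planted correlation module
#'
#' Describes a block of metabolites whose log-abundances are
#' equicorrelated, with a correlation that may differ by intervention
#' group. Group-specific correlations are how differential co-regulation
#' (gain / loss of connectivity) is planted into synthetic cohorts.
#'
#' @param member_ids character vector of at least 3 metabolite ids.
#' @param rho_by_group named numeric vector of within-module pairwise
#'   correlations, one entry per intervention group, each in `[0, 1)`.
#' @return An object of class `planted_module`.
#' @export
planted_module <- function(member_ids, rho_by_group) {
  if (length(member_ids) < 3) stop_("a planted module needs >= 3 members")
  if (anyDuplicated(member_ids)) stop_("module members must be distinct")
  if (!all(names(rho_by_group) %in% INTERVENTION_GROUPS)) {
    stop_("rho_by_group names must be a subset of ",
          paste(INTERVENTION_GROUPS, collapse = "/"))
  }
  if (any(rho_by_group < 0 | rho_by_group >= 1)) {
    stop_("equicorrelation must lie in [0, 1)")
  }
  structure(list(member_ids = as.character(member_ids),
                 rho_by_group = rho_by_group),
            class = "planted_module")
}

#' Planted metabolite-by-intervention effect
#'
#' A true association between a metabolite exposure (its standardized
#' baseline level, or its standardized percent change) and the
#' percent-change glycemic outcome, with a slope that differs by
#' intervention group. The group differences are the interaction
#' contrasts the association scan is meant to recover.
#'
#' @param metabolite_id single metabolite id.
#' @param outcome `"FPG"` or `"HbA1c"`.
#' @param exposure `"baseline"` or `"change"`.
#' @param slope_by_group named numeric vector of true per-group slopes.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(metabolite_id, outcome = c("FPG", "HbA1c"),
                           exposure = c("baseline", "change"),
                           slope_by_group) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  if (!all(names(slope_by_group) %in% INTERVENTION_GROUPS)) {
    stop_("slope_by_group names must be intervention groups")
  }
  if (any(!is.finite(slope_by_group))) stop_("slopes must be finite")
  structure(list(metabolite_id = as.character(metabolite_id),
                 outcome = outcome, exposure = exposure,
                 slope_by_group = slope_by_group),
            class = "planted_effect")
}

# Table-1-style cohort moments used by the generator. These are the study
# conditions the synthetic cohorts emulate: 25 participants per arm, mean
# age 51 (SD 8), 84% female, group baseline BMI means 43.3/45.7/48.5
# (eligibility floor 33), baseline weight means 120/123/133 kg, mean
# fractional weight loss 0.12/0.19/0.35, and median baseline FPG 98/103/118
# mg/dL and HbA1c 5.7/5.9/7.2%. Median percent changes in the outcomes give
# the group intercepts of the outcome model.
synth_cohort_moments <- function() {
  list(
    age_mean = 51, age_sd = 8, age_range = c(21, 70),
    p_female = 0.84,
    bmi_mean = c(IMI = 43.3, BAND = 45.7, RYGB = 48.5), bmi_sd = 6,
    bmi_floor = 33,
    weight_mean = c(IMI = 120, BAND = 123, RYGB = 133), weight_sd = 20,
    fpg_median = c(IMI = 98, BAND = 103, RYGB = 118), fpg_sdlog = 0.15,
    hba1c_median = c(IMI = 5.7, BAND = 5.9, RYGB = 7.2), hba1c_sdlog = 0.08,
    fpg_intercept = c(IMI = (93 - 98) / 98, BAND = (92 - 103) / 103,
                      RYGB = (92 - 118) / 118),
    hba1c_intercept = c(IMI = (5.3 - 5.7) / 5.7, BAND = (5.4 - 5.9) / 5.9,
                        RYGB = (5.5 - 7.2) / 7.2),
    weight_loss_coef = 0.5,
    weight_loss_sd = 0.05
  )
}

# Default planted structure: a module with a strong gain of connectivity
# in RYGB (emulating the tightly co-regulated amino-acid module seen after
# bypass surgery), a module co-regulated in all arms, a module that loses
# connectivity in RYGB, and three interaction effects of the magnitude
# reported for known metabolites (baseline and change exposures, both
# outcomes). Tight modules use equicorrelation 0.85 so that every arm has
# detectable modules under power-6 soft thresholding.
default_planted_modules <- function() {
  list(
    planted_module(sprintf("known_%03d", 1:12),
                   c(IMI = 0.3, BAND = 0.3, RYGB = 0.85)),
    planted_module(sprintf("known_%03d", 21:30),
                   c(IMI = 0.85, BAND = 0.85, RYGB = 0.85)),
    planted_module(sprintf("known_%03d", 31:38),
                   c(IMI = 0.85, BAND = 0.85, RYGB = 0.3))
  )
}

default_planted_effects <- function() {
  list(
    planted_effect("known_001", "FPG", "baseline",
                   c(IMI = 0.1, BAND = 0.0, RYGB = 1.8)),
    planted_effect("known_021", "FPG", "change",
                   c(IMI = 0.0, BAND = 0.1, RYGB = -0.9)),
    planted_effect("known_040", "HbA1c", "baseline",
                   c(IMI = -0.1, BAND = 0.2, RYGB = 0.8))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the structure of the emulated study: 25
#' participants per arm (IMI, BAND, RYGB), two timepoints (150 samples),
#' 364 metabolites of which 153 are annotated as known, group-specific
#' correlated metabolite modules, planted metabolite-by-intervention
#' effects on the percent-change glycemic outcomes, and weight loss whose
#' magnitude depends on the arm.
#'
#' @param n_per_group participants per intervention arm.
#' @param n_metabolites total number of metabolite features.
#' @param n_known how many features carry a known annotation; known ids
#'   are `known_001` ... and unknowns `unknown_001` ....
#' @param modules list of [planted_module()] objects (memberships must be
#'   disjoint).
#' @param effects list of [planted_effect()] objects.
#' @param outcome_noise_sd residual SD of the percent-change outcomes.
#' @param weight_loss_mean_by_group named vector of mean fractional
#'   weight loss per arm.
#' @param missing_rate optional missing-at-random rate applied to the
#'   emitted abundance matrix (default 0).
#' @param seed integer RNG seed; a fixed seed makes the generator
#'   bit-reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_group = 25,
                         n_metabolites = 364,
                         n_known = 153,
                         modules = default_planted_modules(),
                         effects = default_planted_effects(),
                         outcome_noise_sd = 0.1,
                         weight_loss_mean_by_group =
                           c(IMI = 0.12, BAND = 0.19, RYGB = 0.35),
                         missing_rate = 0,
                         seed = 1L) {
  assert_scalar_number(n_per_group, "n_per_group", lower = 1)
  assert_scalar_number(n_metabolites, "n_metabolites", lower = 1)
  assert_scalar_number(n_known, "n_known", lower = 0)
  if (n_known > n_metabolites) stop_("n_known must be <= n_metabolites")
  assert_scalar_number(outcome_noise_sd, "outcome_noise_sd")
  if (outcome_noise_sd <= 0) stop_("outcome_noise_sd must be > 0")
  assert_scalar_number(missing_rate, "missing_rate", 0, 1)
  if (!all(INTERVENTION_GROUPS %in% names(weight_loss_mean_by_group))) {
    stop_("weight_loss_mean_by_group needs IMI, BAND and RYGB entries")
  }
  ids <- synth_feature_ids(n_metabolites, n_known)
  all_members <- unlist(lapply(modules, `[[`, "member_ids"))
  if (anyDuplicated(all_members)) {
    stop_("planted module memberships must be disjoint")
  }
  if (!all(all_members %in% ids$metabolite)) {
    stop_("planted module references unknown metabolite ids")
  }
  eff_ids <- vapply(effects, `[[`, character(1), "metabolite_id")
  if (!all(eff_ids %in% ids$metabolite)) {
    stop_("planted effect references unknown metabolite ids")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_metabolites = as.integer(n_metabolites),
         n_known = as.integer(n_known),
         modules = modules, effects = effects,
         outcome_noise_sd = outcome_noise_sd,
         weight_loss_mean_by_group =
           weight_loss_mean_by_group[INTERVENTION_GROUPS],
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_feature_ids <- function(n_metabolites, n_known) {
  data.frame(
    metabolite = c(sprintf("known_%03d", seq_len(n_known)),
                   sprintf("unknown_%03d", seq_len(n_metabolites - n_known))),
    known = rep(c(TRUE, FALSE), c(n_known, n_metabolites - n_known)),
    stringsAsFactors = FALSE
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Sample an equicorrelated abundance block
#'
#' Draws `n` samples of `m` metabolites whose latent Gaussian
#' log-abundances share a common pairwise correlation `rho`
#' (equicorrelation, positive semidefinite for `rho >= 0`), then maps
#' them to a positive scale by exponentiation. Used as the building block
#' for planted correlation modules.
#'
#' @param m number of metabolites (>= 2).
#' @param rho common pairwise correlation, in `[0, 1)`.
#' @param n number of samples.
#' @param seed optional integer seed; if `NULL`, uses the current RNG
#'   stream.
#' @param mu,sigma location and scale of the log-abundances.
#' @return An `n x m` matrix of positive abundances.
#' @export
sample_module_block <- function(m, rho, n, seed = NULL,
                                mu = log(1e4), sigma = 0.5) {
  if (m < 2) stop_("a module block needs m >= 2 metabolites")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop_("rho must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- equicorrelated_gaussian(n, m, rho)
  exp(mu + sigma * z)
}

# Latent n x m Gaussian with equicorrelation rho via a shared factor:
# Z = sqrt(rho) * g + sqrt(1 - rho) * e, unit marginal variance.
equicorrelated_gaussian <- function(n, m, rho) {
  g <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * m), n, m)
  sqrt(rho) * g + sqrt(1 - rho) * e
}

#' Generate a synthetic two-timepoint cohort
#'
#' Simulates a three-arm weight-loss cohort with the data structure the
#' downstream analysis assumes: a participant table with covariates and
#' baseline / one-year glycemic outcomes, a two-timepoint abundance
#' matrix with group-specific correlated metabolite modules, and the
#' ground truth needed for recovery tests.
#'
#' The percent-change outcomes are generated directly from the linear
#' predictor (group intercept + planted slopes on the standardized
#' exposures + a common weight-loss term + Gaussian noise), with the
#' exposures computed from sum-normalized abundances exactly as the scan
#' computes them, so the fitted interaction model is the generating
#' model. Follow-up outcome values are back-computed from the percent
#' change.
#'
#' @param config a [synth_config()].
#' @return A list with components `cohort` (data.frame, one row per
#'   participant), `matrix` (a [metab_matrix()], two samples per
#'   participant) and `truth` (planted effects, module memberships and
#'   generator coefficients).
#' @export
generate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) stop_("`config` must be a synth_config")
  set.seed(config$seed)
  mom <- synth_cohort_moments()
  npg <- config$n_per_group
  n_part <- 3L * npg
  groups <- factor(rep(INTERVENTION_GROUPS, each = npg),
                   levels = INTERVENTION_GROUPS)
  participant <- sprintf("P%03d", seq_len(n_part))

  age <- rnorm_trunc(n_part, mom$age_mean, mom$age_sd,
                     mom$age_range[1], mom$age_range[2])
  sex <- ifelse(stats::runif(n_part) < mom$p_female, "F", "M")
  bmi <- rnorm_trunc(n_part, mom$bmi_mean[as.character(groups)], mom$bmi_sd,
                     lower = mom$bmi_floor)
  weight0 <- rnorm_trunc(n_part, mom$weight_mean[as.character(groups)],
                         mom$weight_sd, lower = 60)
  loss <- rnorm_trunc(
    n_part,
    config$weight_loss_mean_by_group[as.character(groups)],
    mom$weight_loss_sd, lower = 0.02, upper = 0.6
  )
  weight1 <- weight0 * (1 - loss)
  weight_change <- (weight1 - weight0) / weight0  # = -loss, the covariate

  # Latent metabolite log-abundances: module members equicorrelated with a
  # group-specific rho, everything else independent. Both timepoints of a
  # group are independent draws from that group's correlation structure,
  # so pooled within-group networks see the planted modules.
  ids <- synth_feature_ids(config$n_metabolites, config$n_known)
  n_samp <- 2L * n_part
  mu_feat <- stats::rnorm(config$n_metabolites, log(1e4), 1)
  sigma_feat <- 0.5
  z <- matrix(stats::rnorm(n_samp * config$n_metabolites),
              n_samp, config$n_metabolites)
  colnames(z) <- ids$metabolite

  sample_group <- rep(as.character(groups), each = 2L)
  for (mod in config$modules) {
    idx <- match(mod$member_ids, ids$metabolite)
    for (g in INTERVENTION_GROUPS) {
      rows <- which(sample_group == g)
      rho <- mod$rho_by_group[g]
      if (is.na(rho)) rho <- 0
      z[rows, idx] <- equicorrelated_gaussian(length(rows), length(idx), rho)
    }
  }
  values <- exp(sweep(sigma_feat * z, 2, mu_feat, `+`))

  timepoint <- rep(c("baseline", "year1"), times = n_part)
  sample_meta <- data.frame(
    sample_id = paste0(rep(participant, each = 2L), "_", timepoint),
    participant = rep(participant, each = 2L),
    timepoint = timepoint,
    group = sample_group,
    stringsAsFactors = FALSE
  )
  rownames(values) <- sample_meta$sample_id

  # Exposures for planted effects, computed exactly as the scan will:
  # sum-normalize to known intensities, then standardize the baseline
  # level or the percent change across participants.
  known_sum <- rowSums(values[, ids$known, drop = FALSE])
  norm_values <- values / known_sum
  b_rows <- which(timepoint == "baseline")
  f_rows <- which(timepoint == "year1")

  linpred <- list(
    FPG = mom$fpg_intercept[as.character(groups)],
    HbA1c = mom$hba1c_intercept[as.character(groups)]
  )
  linpred <- lapply(linpred, function(lp) {
    lp + mom$weight_loss_coef * weight_change
  })
  for (eff in config$effects) {
    col <- eff$metabolite_id
    base <- norm_values[b_rows, col]
    x <- if (eff$exposure == "baseline") {
      base
    } else {
      (norm_values[f_rows, col] - base) / base
    }
    xs <- (x - mean(x)) / stats::sd(x)
    slopes <- eff$slope_by_group[as.character(groups)]
    slopes[is.na(slopes)] <- 0
    linpred[[eff$outcome]] <- linpred[[eff$outcome]] + slopes * xs
  }

  pct_fpg <- linpred$FPG + stats::rnorm(n_part, 0, config$outcome_noise_sd)
  pct_hba1c <- linpred$HbA1c + stats::rnorm(n_part, 0, config$outcome_noise_sd)

  fpg0 <- exp(stats::rnorm(n_part, log(mom$fpg_median[as.character(groups)]),
                           mom$fpg_sdlog))
  hba1c0 <- exp(stats::rnorm(n_part,
                             log(mom$hba1c_median[as.character(groups)]),
                             mom$hba1c_sdlog))
  fpg1 <- fpg0 * (1 + pct_fpg)
  hba1c1 <- hba1c0 * (1 + pct_hba1c)

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(values)) < config$missing_rate
    values[miss] <- NA_real_
  }

  cohort <- data.frame(
    participant = participant,
    group = as.character(groups),
    sex = sex,
    age = age,
    bmi_baseline = bmi,
    weight_baseline = weight0,
    weight_year1 = weight1,
    fpg_baseline = fpg0,
    fpg_year1 = fpg1,
    hba1c_baseline = hba1c0,
    hba1c_year1 = hba1c1,
    stringsAsFactors = FALSE
  )

  truth <- list(
    effects = config$effects,
    modules = lapply(config$modules, function(m) {
      list(member_ids = m$member_ids, rho_by_group = as.list(m$rho_by_group))
    }),
    group_intercepts = list(FPG = as.list(linpred_intercepts(mom, "FPG")),
                            HbA1c = as.list(linpred_intercepts(mom, "HbA1c"))),
    weight_loss_coef = mom$weight_loss_coef,
    outcome_noise_sd = config$outcome_noise_sd,
    seed = config$seed
  )

  list(
    cohort = cohort,
    matrix = metab_matrix(values, sample_meta, ids),
    truth = truth
  )
}

linpred_intercepts <- function(mom, outcome) {
  if (outcome == "FPG") mom$fpg_intercept else mom$hba1c_intercept
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort CSV, abundance-matrix CSV, annotation TSV and ground
#' truth JSON for a generated cohort.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_synth_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_csv <- file.path(dir, "cohort.csv")
  matrix_csv <- file.path(dir, "metabolites.csv")
  annot_tsv <- file.path(dir, "annotations.tsv")
  truth_json <- file.path(dir, "ground_truth.json")
  utils::write.csv(sim$cohort, cohort_csv, row.names = FALSE)
  write_metab_matrix(sim$matrix, matrix_csv, annot_tsv)
  truth <- sim$truth
  truth$effects <- lapply(truth$effects, function(e) {
    list(metabolite_id = e$metabolite_id, outcome = e$outcome,
         exposure = e$exposure, slope_by_group = as.list(e$slope_by_group))
  })
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA)
  invisible(c(cohort = cohort_csv, matrix = matrix_csv,
              annotations = annot_tsv, truth = truth_json))
}
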
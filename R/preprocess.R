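#' Normalize abundances to the summed intensity of known metabolites
#'
#' Divides every sample's abundances (known and unknown features alike)
#' by that sample's total intensity over known metabolites, the standard
#' sum-intensity normalization for untargeted GC-MS peak heights. After
#' normalization the known-feature values of each sample sum to 1, so
#' the operation is idempotent.
#'
#' @param x a [metab_matrix()] with at least one known metabolite
#'   present per sample.
#' @return A normalized [metab_matrix()].
#' @export
sum_normalize <- function(x) {
  if (!inherits(x, "metab_matrix")) stop_("`x` must be a metab_matrix")
  known <- x$feature_meta$known
  if (!any(known)) stop_("no known metabolites to normalize against")
  ksum <- rowSums(x$values[, known, drop = FALSE], na.rm = TRUE)
  bad <- which(!is.finite(ksum) | ksum <= 0)
  if (length(bad)) {
    stop_("zero or missing known-metabolite sum in sample(s): ",
          paste(x$sample_meta$sample_id[bad], collapse = ", "))
  }
  x$values <- x$values / ksum
  x
}

#' Filter metabolites by per-group presence
#'
#' Retains a metabolite only if, in every intervention group, it is
#' present (non-missing and positive) in at least `threshold` of that
#' group's samples. The retained set does not depend on sample order.
#'
#' @param x a [metab_matrix()] whose samples all carry a group label.
#' @param threshold minimum presence fraction per group (default 0.5).
#' @return The filtered [metab_matrix()]; the ids of dropped features
#'   are attached as attribute `"dropped"`.
#' @export
presence_filter <- function(x, threshold = 0.5) {
  if (!inherits(x, "metab_matrix")) stop_("`x` must be a metab_matrix")
  assert_scalar_number(threshold, "threshold", 0, 1)
  grp <- x$sample_meta$group
  if (any(is.na(grp) | !nzchar(grp))) stop_("every sample needs a group")
  counts <- table(grp)
  if (any(counts == 0)) stop_("empty group: ", names(counts)[counts == 0][1])
  present <- !is.na(x$values) & x$values > 0
  keep <- rep(TRUE, ncol(x$values))
  for (g in unique(grp)) {
    frac <- colMeans(present[grp == g, , drop = FALSE])
    keep <- keep & frac >= threshold
  }
  dropped <- x$feature_meta$metabolite[!keep]
  out <- subset_features(x, keep)
  attr(out, "dropped") <- dropped
  out
}

#' Percent change between baseline and follow-up
#'
#' `(followup - baseline) / baseline`, the outcome and exposure
#' transformation used throughout: negative values mean a decrease.
#'
#' @param baseline positive baseline value(s).
#' @param followup follow-up value(s), recycled against `baseline`.
#' @return Numeric vector of fractional changes.
#' @export
percent_change <- function(baseline, followup) {
  if (!is.numeric(baseline) || !is.numeric(followup)) {
    stop_("inputs must be numeric")
  }
  if (any(baseline <= 0, na.rm = TRUE)) {
    stop_("percent change requires baseline > 0")
  }
  (followup - baseline) / baseline
}

#' Standardize a vector to zero mean and unit variance
#'
#' @param x numeric vector with at least two distinct values.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop_("`x` must be numeric")
  if (anyNA(x)) stop_("`x` must not contain missing values")
  s <- stats::sd(x)
  if (length(unique(x)) < 2 || s == 0) {
    stop_("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

#' Regress clinical covariates out of every metabolite column
#'
#' Replaces each metabolite column by the residuals of an ordinary
#' least-squares fit on an intercept plus the given covariates. The
#' residuals are orthogonal to every covariate; applying the operation
#' twice equals applying it once (projection).
#'
#' @param x numeric matrix, samples x metabolites.
#' @param covariates data.frame of covariates (e.g. age, sex, BMI,
#'   weight loss), one row per sample, in sample order.
#' @return Matrix of residuals with the dimensions and dimnames of `x`.
#' @export
residualize <- function(x, covariates) {
  x <- as.matrix(x)
  if (nrow(covariates) != nrow(x)) {
    stop_("covariate rows must align with samples")
  }
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_("rank-deficient covariate design; collinear column(s): ",
          paste(drop_cols, collapse = ", "))
  }
  res <- qr.resid(qr_mm, x)
  dimnames(res) <- dimnames(x)
  res
}

# Impute missing abundances by half the metabolite's minimum observed
# value (limit-of-detection convention); keeps percent change defined.
impute_half_min <- function(values) {
  nas <- colSums(is.na(values))
  for (j in which(nas > 0)) {
    obs <- values[, j]
    if (all(is.na(obs))) stop_("metabolite with no observed values: ",
                               colnames(values)[j])
    values[is.na(obs), j] <- min(obs, na.rm = TRUE) / 2
  }
  values
}

#' Build the per-participant change table
#'
#' Collapses a two-timepoint abundance matrix and cohort table to one
#' row per participant: percent-change glycemic outcomes, fractional
#' weight change, scan covariates, and per-metabolite baseline levels
#' and percent changes. Abundances should already be normalized and
#' filtered; remaining missing values are imputed at half the observed
#' minimum.
#'
#' @param x a [metab_matrix()] (normalized, filtered).
#' @param cohort cohort data.frame from [generate_cohort()] or a file in
#'   the same layout.
#' @return An object of class `change_table`: a list with `data` (one
#'   row per participant: `participant`, `group`, `sex`, `age`, `bmi`,
#'   `weight_loss`, `pct_change_fpg`, `pct_change_hba1c`),
#'   `metab_baseline` and `metab_change` (participant x metabolite
#'   matrices) and `feature_meta`.
#' @export
build_change_table <- function(x, cohort) {
  if (!inherits(x, "metab_matrix")) stop_("`x` must be a metab_matrix")
  need <- c("participant", "group", "sex", "age", "bmi_baseline",
            "weight_baseline", "weight_year1", "fpg_baseline", "fpg_year1",
            "hba1c_baseline", "hba1c_year1")
  if (!all(need %in% names(cohort))) {
    stop_("cohort is missing column(s): ",
          paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  if (!all(x$sample_meta$participant %in% cohort$participant)) {
    stop_("samples reference participants absent from the cohort table")
  }
  vals <- impute_half_min(x$values)
  sm <- x$sample_meta
  b_idx <- match(paste0(cohort$participant, "@baseline"),
                 paste0(sm$participant, "@", sm$timepoint))
  f_idx <- match(paste0(cohort$participant, "@year1"),
                 paste0(sm$participant, "@", sm$timepoint))
  if (anyNA(b_idx) || anyNA(f_idx)) {
    stop_("every participant needs a baseline and a year1 sample")
  }
  base <- vals[b_idx, , drop = FALSE]
  foll <- vals[f_idx, , drop = FALSE]
  if (any(base <= 0)) stop_("non-positive baseline abundance after imputation")
  change <- (foll - base) / base
  rownames(base) <- rownames(change) <- cohort$participant

  data <- data.frame(
    participant = cohort$participant,
    group = cohort$group,
    sex = cohort$sex,
    age = cohort$age,
    bmi = cohort$bmi_baseline,
    weight_loss = percent_change(cohort$weight_baseline, cohort$weight_year1),
    pct_change_fpg = percent_change(cohort$fpg_baseline, cohort$fpg_year1),
    pct_change_hba1c = percent_change(cohort$hba1c_baseline,
                                      cohort$hba1c_year1),
    stringsAsFactors = FALSE
  )
  structure(
    list(data = data, metab_baseline = base, metab_change = change,
         feature_meta = x$feature_meta),
    class = "change_table"
  )
}

#' @export
print.change_table <- function(x, ...) {
  cat(sprintf("<change_table> %d participants x %d metabolites\n",
              nrow(x$data), ncol(x$metab_baseline)))
  invisible(x)
}
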
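#' Fit the metabolite-by-intervention interaction model
#'
#' Fits one ordinary least-squares model
#' `y ~ m + group + m:group + covariates` with the intervention group as
#' a factor (reference `IMI` by default) and derives, from the single
#' pooled fit, the within-group metabolite slopes (beta-star), the
#' pairwise between-group contrasts (beta-dagger, the interaction
#' effects), and their standard errors and two-sided t-tests via the
#' linear-combination rule on the coefficient covariance matrix. All
#' pairwise contrasts — including those between two non-reference groups
#' — come from the same fit; nothing is refit.
#'
#' @param y numeric outcome (percent change in FPG or HbA1c).
#' @param m numeric metabolite exposure (standardized baseline level or
#'   standardized percent change).
#' @param group factor or character of intervention arms.
#' @param covariates optional data.frame of adjustment covariates (sex,
#'   baseline age, BMI, weight loss), one row per observation.
#' @param reference reference group for the factor coding.
#' @return An object of class `interaction_fit` with components
#'   `beta_star` / `se_star` (named per group), `contrasts` (data.frame
#'   with `pair`, `estimate`, `se`, `t`, `p`), `model` (the underlying
#'   `lm`), `groups`, `reference` and `df_residual`.
#' @examples
#' set.seed(1)
#' g <- rep(c("IMI", "BAND", "RYGB"), each = 20)
#' m <- rnorm(60)
#' y <- ifelse(g == "RYGB", 2, 0) * m + rnorm(60, sd = 0.5)
#' fit <- fit_interaction(y, m, g)
#' fit$contrasts
#' @export
fit_interaction <- function(y, m, group, covariates = NULL,
                            reference = "IMI") {
  if (length(y) != length(m) || length(y) != length(group)) {
    stop_("y, m and group must have equal length")
  }
  group <- as.character(group)
  levs <- intersect(INTERVENTION_GROUPS, unique(group))
  if (length(levs) < 2) levs <- unique(group)
  if (!reference %in% levs) {
    stop_("reference group '", reference, "' not present in the data")
  }
  gf <- factor(group, levels = c(reference, setdiff(levs, reference)))
  for (g in levels(gf)) {
    mg <- m[gf == g]
    if (length(mg) < 3 || stats::sd(mg) == 0) {
      stop_("group '", g, "' needs >= 3 observations with exposure variance")
    }
  }
  dat <- data.frame(.y = y, .m = m, .group = gf)
  rhs <- ".m * .group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(y)) {
      stop_("covariates must have one row per observation")
    }
    dat <- cbind(dat, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  n_par <- length(levels(gf)) * 2 +
    if (is.null(covariates)) 0 else ncol(covariates)
  if (length(y) < n_par + 1) stop_("too few observations for the model")

  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop_("rank-deficient interaction design")
  V <- stats::vcov(fit)

  # Row of the coefficient-combination matrix giving group g's slope:
  # beta_m plus (for non-reference groups) the interaction coefficient.
  slope_row <- function(g) {
    L <- numeric(length(cf))
    names(L) <- names(cf)
    L[".m"] <- 1
    if (g != levels(gf)[1]) {
      term <- paste0(".m:.group", g)
      if (!term %in% names(cf)) stop_("missing interaction term for ", g)
      L[term] <- 1
    }
    L
  }
  est_se <- function(L) {
    c(est = sum(L * cf), se = sqrt(drop(t(L) %*% V %*% L)))
  }
  beta_star <- se_star <- stats::setNames(numeric(length(levels(gf))),
                                          levels(gf))
  for (g in levels(gf)) {
    r <- est_se(slope_row(g))
    beta_star[g] <- r["est"]
    se_star[g] <- r["se"]
  }

  pairs <- Filter(function(p) all(p %in% levels(gf)), CONTRAST_PAIRS)
  if (!length(pairs)) {
    pairs <- list(rev(levels(gf)[1:2]))
  }
  df <- stats::df.residual(fit)
  contrasts <- do.call(rbind, lapply(pairs, function(p) {
    L <- slope_row(p[1]) - slope_row(p[2])
    r <- est_se(L)
    tval <- if (r["se"] > 0) r["est"] / r["se"] else NA_real_
    data.frame(
      pair = paste(p[1], "vs", p[2]),
      estimate = unname(r["est"]),
      se = unname(r["se"]),
      t = unname(tval),
      p = if (is.na(tval)) NA_real_ else 2 * stats::pt(-abs(tval), df),
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(match(levels(gf), INTERVENTION_GROUPS))
  structure(
    list(beta_star = beta_star[ord], se_star = se_star[ord],
         contrasts = contrasts, model = fit,
         groups = levels(gf)[ord], reference = reference,
         df_residual = df, n = length(y)),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Metabolite-by-intervention interaction fit (n = %d, df = %d)\n",
              x$n, x$df_residual))
  cat("Within-group slopes (beta*):\n")
  print(round(rbind(estimate = x$beta_star, se = x$se_star), 4))
  cat("Pairwise contrasts (beta†):\n")
  print(format(x$contrasts, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.interaction_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$model)),
            class = "summary.interaction_fit")
}

#' @export
print.summary.interaction_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying model:\n")
  print(x$lm_summary)
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) stats::coef(object$model)

#' @export
vcov.interaction_fit <- function(object, ...) stats::vcov(object$model)

#' @export
residuals.interaction_fit <- function(object, ...) {
  stats::residuals(object$model)
}

#' @export
predict.interaction_fit <- function(object, ...) {
  stats::predict(object$model, ...)
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance measures with an estimated
#' proportion of true nulls. `pi0` is estimated on the lambda grid as
#' `#\{p > lambda\} / (m (1 - lambda))`, smoothed by a cubic smoothing
#' spline (3 df) and evaluated at the largest lambda, then clamped to
#' `(0, 1]`. For short p-value vectors (fewer than 100) the spline is
#' unstable and `pi0` falls back to 1, which reduces the q-values to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda grid for the null-proportion estimator.
#' @param pi0 optional fixed null proportion overriding estimation
#'   (e.g. `pi0 = 1` gives Benjamini-Hochberg).
#' @return Numeric vector of q-values, same order as `p`; the estimated
#'   `pi0` is attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (!length(p)) stop_("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop_("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                           numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  } else {
    assert_scalar_number(pi0, "pi0")
    if (pi0 <= 0 || pi0 > 1) stop_("pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * cummin(m / seq(m, 1) * p[o])[order(o)]
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Run a metabolome-wide interaction scan
#'
#' Fits the interaction model of [fit_interaction()] for every retained
#' metabolite against one percent-change glycemic outcome, using either
#' the standardized baseline metabolite level (prospective scan) or the
#' standardized percent change in the metabolite (repeated-measurement
#' scan) as the exposure, adjusting for sex, baseline age, BMI and
#' weight loss. Storey q-values are computed separately within each
#' pairwise-contrast family across metabolites. Metabolites whose fit
#' fails (e.g. constant exposure within a group) are flagged, not
#' dropped.
#'
#' @param ct a [build_change_table()] result.
#' @param outcome `"fpg"` or `"hba1c"`.
#' @param exposure `"baseline"` or `"change"`.
#' @param covariates character vector of covariate columns of
#'   `ct$data` to adjust for.
#' @param reference reference intervention group.
#' @return An object of class `metab_scan`: list with `records` (one
#'   row per metabolite: slopes, contrast estimates/SEs/p/q, known
#'   flag, `fit_ok`), `outcome`, `exposure`, `n`.
#' @export
run_scan <- function(ct, outcome = c("fpg", "hba1c"),
                     exposure = c("baseline", "change"),
                     covariates = c("sex", "age", "bmi", "weight_loss"),
                     reference = "IMI") {
  if (!inherits(ct, "change_table")) stop_("`ct` must be a change_table")
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  mat <- if (exposure == "baseline") ct$metab_baseline else ct$metab_change
  if (!ncol(mat)) stop_("no metabolites to scan")
  y <- ct$data[[paste0("pct_change_", outcome)]]
  covs <- ct$data[, covariates, drop = FALSE]
  group <- ct$data$group

  pair_names <- vapply(CONTRAST_PAIRS, function(p) paste(p[1], "vs", p[2]),
                       character(1))
  rows <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    rec <- list(metabolite = colnames(mat)[j],
                known = ct$feature_meta$known[j], fit_ok = TRUE)
    fit <- tryCatch(
      fit_interaction(y, standardize(mat[, j]), group, covs, reference),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rec$fit_ok <- FALSE
      rec$message <- conditionMessage(fit)
      for (g in INTERVENTION_GROUPS) {
        rec[[paste0("beta_", g)]] <- NA_real_
        rec[[paste0("se_", g)]] <- NA_real_
      }
      for (pn in pair_names) {
        key <- gsub(" ", "_", pn)
        rec[[paste0("contrast_", key)]] <- NA_real_
        rec[[paste0("contrast_se_", key)]] <- NA_real_
        rec[[paste0("p_", key)]] <- NA_real_
      }
    } else {
      for (g in names(fit$beta_star)) {
        rec[[paste0("beta_", g)]] <- unname(fit$beta_star[g])
        rec[[paste0("se_", g)]] <- unname(fit$se_star[g])
      }
      for (i in seq_len(nrow(fit$contrasts))) {
        key <- gsub(" ", "_", fit$contrasts$pair[i])
        rec[[paste0("contrast_", key)]] <- fit$contrasts$estimate[i]
        rec[[paste0("contrast_se_", key)]] <- fit$contrasts$se[i]
        rec[[paste0("p_", key)]] <- fit$contrasts$p[i]
      }
      rec$message <- ""
    }
    rows[[j]] <- rec
  }
  records <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))

  # Storey q within each contrast family across metabolites.
  for (pn in pair_names) {
    key <- gsub(" ", "_", pn)
    pcol <- paste0("p_", key)
    if (!pcol %in% names(records)) next
    ok <- which(!is.na(records[[pcol]]))
    qv <- rep(NA_real_, nrow(records))
    if (length(ok)) qv[ok] <- as.numeric(storey_qvalues(records[[pcol]][ok]))
    records[[paste0("q_", key)]] <- qv
  }
  structure(
    list(records = records, outcome = outcome, exposure = exposure,
         n = nrow(ct$data), reference = reference),
    class = "metab_scan"
  )
}

#' @export
print.metab_scan <- function(x, ...) {
  cat(sprintf(
    "Interaction scan: %%change %s ~ %s metabolite exposure (n = %d, %d metabolites)\n",
    toupper(x$outcome), x$exposure, x$n, nrow(x$records)
  ))
  qcols <- grep("^q_", names(x$records), value = TRUE)
  for (qc in qcols) {
    cat(sprintf("  %s: %d metabolites at q < 0.05\n",
                sub("^q_", "", qc), sum(x$records[[qc]] < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.metab_scan <- function(object, q_threshold = 0.05, ...) {
  qcols <- grep("^q_", names(object$records), value = TRUE)
  counts <- vapply(qcols, function(qc) {
    sum(object$records[[qc]] < q_threshold, na.rm = TRUE)
  }, numeric(1))
  data.frame(
    outcome = object$outcome, exposure = object$exposure,
    contrast = sub("^q_", "", qcols),
    n_significant = as.integer(counts),
    q_threshold = q_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Volcano table for one contrast of a scan
#'
#' @param scan a [run_scan()] result.
#' @param contrast contrast name, e.g. `"RYGB_vs_IMI"`.
#' @return data.frame with `metabolite`, `known`, `estimate`, `se`,
#'   `p`, `q`, ordered by p.
#' @export
volcano_table <- function(scan, contrast = "RYGB_vs_IMI") {
  r <- scan$records
  cols <- paste0(c("contrast_", "contrast_se_", "p_", "q_"), contrast)
  if (!all(cols %in% names(r))) stop_("unknown contrast: ", contrast)
  out <- data.frame(metabolite = r$metabolite, known = r$known,
                    estimate = r[[cols[1]]], se = r[[cols[2]]],
                    p = r[[cols[3]]], q = r[[cols[4]]],
                    stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Volcano plot of a scan contrast
#'
#' @param x a [run_scan()] result.
#' @param contrast contrast name.
#' @param q_threshold points with q below this are highlighted.
#' @param ... passed to [plot()].
#' @export
plot.metab_scan <- function(x, contrast = "RYGB_vs_IMI",
                            q_threshold = 0.05, ...) {
  v <- volcano_table(x, contrast)
  sig <- !is.na(v$q) & v$q < q_threshold
  plot(v$estimate, -log10(v$p),
       xlab = expression(beta^"†"), ylab = expression(-log[10](p)),
       pch = 19, col = ifelse(sig, "firebrick", "grey60"),
       main = sprintf("%s, %s exposure: %s", toupper(x$outcome), x$exposure,
                      gsub("_", " ", contrast)), ...)
  invisible(v)
}

#' Write a scan as a fixed-layout TSV
#'
#' Column order: metabolite, known flag, the three within-group slopes
#' and SEs, then per contrast the estimate, SE, p and q.
#'
#' @param scan a [run_scan()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(scan, path) {
  r <- scan$records
  pair_keys <- gsub(" ", "_", vapply(CONTRAST_PAIRS,
                                     function(p) paste(p[1], "vs", p[2]),
                                     character(1)))
  cols <- c("metabolite", "known",
            paste0("beta_", INTERVENTION_GROUPS),
            paste0("se_", INTERVENTION_GROUPS),
            paste0("contrast_", pair_keys),
            paste0("contrast_se_", pair_keys),
            paste0("p_", pair_keys),
            paste0("q_", pair_keys),
            "fit_ok")
  cols <- intersect(cols, names(r))
  out <- r[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
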
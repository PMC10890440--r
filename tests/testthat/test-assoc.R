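test_that("within-group slopes and contrasts obey the subtraction identity", {
  toy <- interaction_toy(c(IMI = 1.2, BAND = -0.4, RYGB = 3.1))
  fit <- fit_interaction(toy$y, toy$m, toy$group)
  expect_equal(unname(fit$beta_star),
               c(1.2, -0.4, 3.1), tolerance = 1e-10)
  est <- setNames(fit$contrasts$estimate, fit$contrasts$pair)
  expect_equal(unname(est["RYGB vs IMI"]),
               unname(fit$beta_star["RYGB"] - fit$beta_star["IMI"]),
               tolerance = 1e-10)
  expect_equal(unname(est["RYGB vs BAND"]),
               unname(fit$beta_star["RYGB"] - fit$beta_star["BAND"]),
               tolerance = 1e-10)
  expect_equal(unname(est["BAND vs IMI"]),
               unname(fit$beta_star["BAND"] - fit$beta_star["IMI"]),
               tolerance = 1e-10)
})

test_that("pooled fit matches the separate per-group OLS oracle", {
  set.seed(7)
  n_g <- 20
  g <- rep(c("IMI", "BAND", "RYGB"), each = n_g)
  x <- rnorm(3 * n_g)
  y <- ifelse(g == "RYGB", 1.5, ifelse(g == "BAND", 0.5, -0.2)) * x +
    rnorm(3 * n_g, sd = 0.7)
  fit <- fit_interaction(y, x, g)

  # Oracle: slope and Sxx from per-group OLS; the pooled residual
  # variance (same residuals as the saturated interaction model, df
  # n - 6) gives the standard errors by the delta rule.
  slopes <- sxx <- setNames(numeric(3), c("IMI", "BAND", "RYGB"))
  rss <- 0
  for (gr in names(slopes)) {
    xi <- x[g == gr]; yi <- y[g == gr]
    b <- cov(xi, yi) / var(xi)
    a <- mean(yi) - b * mean(xi)
    slopes[gr] <- b
    sxx[gr] <- sum((xi - mean(xi))^2)
    rss <- rss + sum((yi - a - b * xi)^2)
  }
  s2 <- rss / (3 * n_g - 6)
  expect_equal(fit$beta_star, slopes, tolerance = 1e-10)
  expect_equal(fit$se_star, sqrt(s2 / sxx), tolerance = 1e-10)

  est <- setNames(fit$contrasts$estimate, fit$contrasts$pair)
  se <- setNames(fit$contrasts$se, fit$contrasts$pair)
  p <- setNames(fit$contrasts$p, fit$contrasts$pair)
  d <- slopes["RYGB"] - slopes["IMI"]
  sd_d <- sqrt(s2 / sxx["RYGB"] + s2 / sxx["IMI"])
  expect_equal(unname(est["RYGB vs IMI"]), unname(d), tolerance = 1e-10)
  expect_equal(unname(se["RYGB vs IMI"]), unname(sd_d), tolerance = 1e-10)
  expect_equal(unname(p["RYGB vs IMI"]),
               unname(2 * pt(-abs(d / sd_d), 3 * n_g - 6)),
               tolerance = 1e-10)
})

test_that("a null with zero noise gives exactly zero contrasts", {
  toy <- interaction_toy(c(IMI = 2, BAND = 2, RYGB = 2), noise_scale = 0)
  fit <- suppressWarnings(fit_interaction(toy$y, toy$m, toy$group))
  expect_equal(fit$contrasts$estimate, rep(0, 3), tolerance = 1e-12)
})

test_that("contrasts are equivariant under exposure scaling", {
  set.seed(8)
  g <- rep(c("IMI", "BAND", "RYGB"), each = 15)
  x <- rnorm(45)
  y <- rnorm(45)
  covs <- data.frame(age = rnorm(45), wl = rnorm(45))
  f1 <- fit_interaction(y, x, g, covs)
  f3 <- fit_interaction(y, 3 * x, g, covs)
  expect_equal(f3$beta_star, f1$beta_star / 3, tolerance = 1e-10)
  expect_equal(f3$contrasts$estimate, f1$contrasts$estimate / 3,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  g <- rep(c("IMI", "RYGB"), each = 10)
  x <- c(rep(1, 10), rnorm(10))
  expect_error(fit_interaction(rnorm(20), x, g), "exposure variance")
  expect_error(fit_interaction(rnorm(20), rnorm(20), g, reference = "BAND"),
               "reference")
  expect_error(fit_interaction(rnorm(5), rnorm(5), c("IMI", "IMI", "IMI",
                                                     "RYGB", "RYGB")),
               ">= 3 observations")
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  for (m in c(1, 7, 60, 500)) {
    set.seed(m)
    p <- runif(m)^1.5
    q <- storey_qvalues(p, pi0 = 1)
    expect_equal(as.numeric(q), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("Storey q-values are monotone, bounded, and never below pi0 * BH", {
  expect_equal(as.numeric(storey_qvalues(rep(1, 10))), rep(1, 10))
  set.seed(4)
  p <- c(runif(150), rbeta(150, 0.3, 4))
  q <- storey_qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_true(pi0 > 0 && pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(q >= pi0 * p.adjust(p, "BH") - 1e-12))
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("a strong signal block keeps small q-values in the pi0 ~ 0.5 regime", {
  set.seed(5)
  p <- c(rep(0.001, 50), runif(50, 0.5, 1))
  q <- storey_qvalues(p)
  expect_true(all(q[1:50] < 0.05))
})

test_that("run_scan flags failed fits and computes per-family q-values", {
  eff <- planted_effect("known_001", "FPG", "baseline",
                        c(IMI = 0, RYGB = 2.5))
  cfg <- synth_config(n_per_group = 40, n_metabolites = 12, n_known = 10,
                      modules = list(), effects = list(eff),
                      outcome_noise_sd = 0.1, seed = 21)
  sim <- generate_cohort(cfg)
  ct <- build_change_table(presence_filter(sum_normalize(sim$matrix)),
                           sim$cohort)
  # sabotage one metabolite: constant within every group
  ct$metab_baseline[, "known_002"] <- 1
  sc <- run_scan(ct, "fpg", "baseline")
  expect_equal(nrow(sc$records), 12)
  bad <- sc$records[sc$records$metabolite == "known_002", ]
  expect_false(bad$fit_ok)
  expect_true(is.na(bad$p_RYGB_vs_IMI))
  # the planted metabolite has the smallest q in its contrast family
  qv <- sc$records$q_RYGB_vs_IMI
  expect_equal(sc$records$metabolite[which.min(qv)], "known_001")
})

test_that("a single-metabolite scan reduces to q = p", {
  set.seed(6)
  g <- rep(c("IMI", "BAND", "RYGB"), each = 10)
  vals <- matrix(exp(rnorm(60 * 1)), ncol = 1,
                 dimnames = list(NULL, "known_001"))
  x <- toy_metab_matrix(vals, known = TRUE,
                        groups = rep(c("IMI", "BAND", "RYGB"), each = 10))
  cohort <- data.frame(
    participant = sprintf("P%02d", 1:30),
    group = rep(c("IMI", "BAND", "RYGB"), each = 10),
    sex = sample(c("F", "M"), 30, TRUE), age = rnorm(30, 50, 5),
    bmi_baseline = rnorm(30, 45, 3),
    weight_baseline = rnorm(30, 120, 10), weight_year1 = rnorm(30, 100, 10),
    fpg_baseline = rnorm(30, 100, 5), fpg_year1 = rnorm(30, 95, 5),
    hba1c_baseline = rnorm(30, 6, 0.2), hba1c_year1 = rnorm(30, 5.6, 0.2),
    stringsAsFactors = FALSE
  )
  ct <- build_change_table(x, cohort)
  sc <- run_scan(ct, "fpg", "baseline")
  expect_equal(nrow(sc$records), 1)
  expect_equal(sc$records$q_RYGB_vs_IMI, sc$records$p_RYGB_vs_IMI,
               tolerance = 1e-12)
})

test_that("interaction_fit methods expose the underlying model", {
  set.seed(9)
  g <- rep(c("IMI", "BAND", "RYGB"), each = 12)
  x <- rnorm(36)
  y <- rnorm(36)
  fit <- fit_interaction(y, x, g)
  expect_s3_class(fit, "interaction_fit")
  expect_length(residuals(fit), 36)
  expect_equal(length(predict(fit)), 36)
  expect_true(all(c(".m", ".groupBAND") %in% names(coef(fit))))
  expect_output(print(fit), "beta")
  expect_s3_class(summary(fit), "summary.interaction_fit")
})
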
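test_that("adjacency is the soft-thresholded absolute correlation", {
  set.seed(1)
  x <- matrix(rnorm(50 * 5), 50, 5)
  colnames(x) <- paste0("m", 1:5)
  a <- adjacency_matrix(x, power = 6)
  expect_equal(a, abs(cor(x))^6 * (1 - diag(5)) + diag(5),
               tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))

  # perfectly correlated pair stays at 1 for any power
  y <- cbind(a1 = x[, 1], a2 = 2 * x[, 1] + 3)
  expect_equal(adjacency_matrix(y, power = 9)["a1", "a2"], 1,
               tolerance = 1e-12)

  xc <- cbind(x, const = 1)
  expect_error(adjacency_matrix(xc, 6), "const")
})

test_that("topological overlap matches the closed forms and the brute force", {
  ones <- matrix(1, 3, 3)
  expect_equal(tom_similarity(ones), ones, tolerance = 1e-12)

  zeros <- diag(3)
  expect_equal(tom_similarity(zeros), diag(3), tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:8) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("TOM is equivariant under feature permutation", {
  set.seed(3)
  x <- matrix(rnorm(40 * 8), 40, 8)
  colnames(x) <- paste0("m", 1:8)
  a <- adjacency_matrix(x, 4)
  tom <- tom_similarity(a)
  perm <- sample(8)
  tom_p <- tom_similarity(adjacency_matrix(x[, perm], 4))
  expect_equal(tom_p, tom[perm, perm], tolerance = 1e-12)
})

test_that("planted correlation blocks are recovered as modules", {
  set.seed(4)
  n <- 100
  block <- function(m, rho) {
    g <- rnorm(n)
    sqrt(rho) * g + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
  }
  x <- cbind(block(10, 0.8), block(10, 0.8), matrix(rnorm(n * 20), n, 20))
  colnames(x) <- sprintf("f%02d", 1:40)
  truth <- rep(c("b1", "b2", "noise"), c(10, 10, 20))
  tom <- tom_similarity(adjacency_matrix(x, power = 2))
  ma <- detect_modules(tom, cut_height = 0.75, min_size = 5)
  ari <- adjusted_rand_index(ma$assignment$module, truth)
  expect_gte(ari, 0.9)
  # cross-check our ARI against the mclust implementation
  skip_if_not_installed("mclust")
  expect_equal(ari,
               mclust::adjustedRandIndex(ma$assignment$module, truth),
               tolerance = 1e-12)
})

test_that("independent features are left unassigned, a global block is one module", {
  set.seed(5)
  x <- matrix(rnorm(100 * 30), 100, 30)
  colnames(x) <- sprintf("f%02d", 1:30)
  tom <- tom_similarity(adjacency_matrix(x, 6))
  ma <- suppressWarnings(detect_modules(tom, 0.75, 5))
  expect_gte(mean(ma$assignment$module == "grey"), 0.9)

  g <- rnorm(100)
  xb <- sqrt(0.9) * g + sqrt(0.1) * matrix(rnorm(100 * 20), 100, 20)
  colnames(xb) <- sprintf("f%02d", 1:20)
  mb <- detect_modules(tom_similarity(adjacency_matrix(xb, 2)), 0.75, 5)
  main <- names(which.max(table(mb$assignment$module)))
  expect_true(main != "grey")
  expect_gte(mean(mb$assignment$module == main), 0.9)
})

test_that("module labels are size-ranked colour names", {
  set.seed(6)
  n <- 120
  g1 <- rnorm(n); g2 <- rnorm(n)
  x <- cbind(
    sqrt(0.85) * g1 + sqrt(0.15) * matrix(rnorm(n * 12), n, 12),
    sqrt(0.85) * g2 + sqrt(0.15) * matrix(rnorm(n * 6), n, 6)
  )
  colnames(x) <- sprintf("f%02d", 1:18)
  ma <- detect_modules(tom_similarity(adjacency_matrix(x, 2)), 0.75, 5)
  sizes <- table(ma$assignment$module)
  expect_true(all(c("turquoise", "blue") %in% names(sizes)))
  expect_gte(sizes[["turquoise"]], sizes[["blue"]])
})

test_that("soft power selection falls back with a warning on non-scale-free data", {
  set.seed(7)
  x <- matrix(rnorm(60 * 15), 60, 15)
  expect_warning(p <- choose_soft_power(x), "falling back to 6")
  expect_equal(as.integer(p), 6L)
  expect_true(attr(p, "fallback"))
  # determinism
  p2 <- suppressWarnings(choose_soft_power(x))
  expect_identical(as.integer(p2), as.integer(p))
  expect_error(choose_soft_power(x[, 1:5]), "10 metabolites")
  expect_error(choose_soft_power(x[1:5, ]), "10 samples")
})

test_that("scale-free fit statistic reproduces a brute-force binned regression", {
  set.seed(8)
  n <- 200
  hub <- rnorm(n)
  x <- cbind(hub, 0.9 * hub + sqrt(1 - 0.81) * matrix(rnorm(n * 20), n, 20),
             matrix(rnorm(n * 30), n, 30))
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  r <- abs(cor(x)); diag(r) <- 0
  k <- colSums(r^3)
  fit <- metabshift:::scale_free_fit(k, n_bins = 10)

  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = 11)))
  bins <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & mk > 0
  lmfit <- lm(log10(freq[keep]) ~ log10(mk[keep]))
  expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit$signed_r2,
               -sign(coef(lmfit)[2]) * summary(lmfit)$r.squared,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hub selection maximizes intramodular connectivity with lexical ties", {
  set.seed(9)
  n <- 300
  center <- rnorm(n)
  leaves <- 0.9 * center + sqrt(1 - 0.81) * matrix(rnorm(n * 6), n, 6)
  x <- cbind(center, leaves)
  colnames(x) <- c("center", paste0("leaf", 1:6))
  a <- adjacency_matrix(x, 2)
  expect_equal(hub_metabolite(a, colnames(x)), "center")

  # argmax oracle on a random block
  y <- matrix(rnorm(80 * 6), 80, 6)
  colnames(y) <- sprintf("m%d", 1:6)
  ay <- adjacency_matrix(y, 2)
  conn <- rowSums(ay) - 1
  expect_equal(hub_metabolite(ay, colnames(y)),
               names(which.max(conn)))

  # two-member tie: both have identical connectivity, smaller id wins
  two <- adjacency_matrix(cbind(bb = rnorm(30), aa = rnorm(30)), 1)
  expect_equal(hub_metabolite(two, c("bb", "aa")), "aa")
  expect_error(hub_metabolite(a, character(0)), "empty")
})

test_that("MDC statistic is zero on identical data and antisymmetric", {
  set.seed(10)
  x <- matrix(rnorm(50 * 6), 50, 6)
  colnames(x) <- paste0("m", 1:6)
  expect_equal(mdc_statistic(x, x, colnames(x), 6), 0)
  y <- matrix(rnorm(40 * 6), 40, 6)
  colnames(y) <- colnames(x)
  expect_equal(mdc_statistic(x, y, colnames(x), 6),
               -mdc_statistic(y, x, colnames(x), 6), tolerance = 1e-12)
  expect_error(mdc_statistic(x, y, c("m1", "m2"), 6), ">= 3")
  expect_error(mdc_statistic(x, y, c("m1", "m2", "zz"), 6), "missing")
})

test_that("MDC magnitude matches the equicorrelation expectation at power 1", {
  set.seed(11)
  n <- 200
  g <- rnorm(n)
  xa <- sqrt(0.8) * g + sqrt(0.2) * matrix(rnorm(n * 5), n, 5)
  xb <- matrix(rnorm(n * 5), n, 5)
  colnames(xa) <- colnames(xb) <- paste0("m", 1:5)
  stat <- mdc_statistic(xa, xb, colnames(xa), power = 1)
  expect_lt(abs(stat - 10 * 0.8), 1)
})

test_that("the MDC permutation test calls GOC with the add-one p floor", {
  set.seed(12)
  n <- 100
  g <- rnorm(n)
  xa <- sqrt(0.8) * g + sqrt(0.2) * matrix(rnorm(n * 10), n, 10)
  xb <- matrix(rnorm(n * 10), n, 10)
  colnames(xa) <- colnames(xb) <- paste0("m", 1:10)
  res <- mdc_permutation_test(xa, xb, colnames(xa), power = 6,
                              n_perm = 100, seed = 1)
  expect_equal(res$call, "GOC")
  expect_equal(res$perm_p, 1 / 101, tolerance = 1e-12)
  expect_gt(res$statistic, 0)
  expect_gt(res$ratio, 1)

  # determinism under a fixed seed
  res2 <- mdc_permutation_test(xa, xb, colnames(xa), power = 6,
                               n_perm = 100, seed = 1)
  expect_identical(res$perm_p, res2$perm_p)

  # swapped groups give LOC
  swap <- mdc_permutation_test(xb, xa, colnames(xa), power = 6,
                               n_perm = 100, seed = 1)
  expect_equal(swap$call, "LOC")

  expect_error(mdc_permutation_test(xa[1:4, ], xb, colnames(xa),
                                    n_perm = 100), ">= 5")
  expect_error(mdc_permutation_test(xa, xb, colnames(xa), n_perm = 50),
               "n_perm")
})

test_that("permutation p-values are approximately uniform under exchangeability", {
  set.seed(13)
  n <- 30
  pvals <- replicate(200, {
    pool <- sqrt(0.5) * rnorm(2 * n) +
      sqrt(0.5) * matrix(rnorm(2 * n * 6), 2 * n, 6)
    colnames(pool) <- paste0("m", 1:6)
    xa <- pool[1:n, ]
    xb <- pool[(n + 1):(2 * n), ]
    mdc_permutation_test(xa, xb, colnames(pool), power = 2,
                         n_perm = 100)$perm_p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted gain-of-connectivity module survives the full chain", {
  # simulate -> residualize -> detect -> MDC over repeated seeds; power 2
  # suits a small panel where planted correlations are strong
  mod <- planted_module(sprintf("known_%03d", 1:12),
                        c(IMI = 0.3, BAND = 0.3, RYGB = 0.8))
  hits <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(n_per_group = 25, n_metabolites = 80, n_known = 60,
                        modules = list(mod), effects = list(), seed = 1000 + s)
    sim <- generate_cohort(cfg)
    filt <- presence_filter(sum_normalize(sim$matrix))
    net <- tryCatch(
      suppressWarnings(run_network(filt, sim$cohort, power = 2,
                                   n_perm = 100, seed = s)),
      error = function(e) NULL
    )
    if (is.null(net)) next
    rygb <- net$modules[["RYGB"]]$assignment
    planted_in <- rygb$module[rygb$metabolite %in% mod$member_ids]
    lab <- names(which.max(table(planted_in)))
    if (lab == "grey") next
    row <- net$mdc[net$mdc$module == lab & net$mdc$group_a == "RYGB" &
                     net$mdc$group_b == "IMI", ]
    if (nrow(row) == 1 && row$call == "GOC") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})
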
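#' Soft-thresholded correlation adjacency
#'
#' Unsigned weighted-network adjacency: `a_ij = |cor(x_i, x_j)|^power`,
#' with unit diagonal.
#'
#' @param x numeric matrix, samples x metabolites, no constant columns.
#' @param power soft-thresholding exponent (positive integer).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(x, power = 6) {
  x <- as.matrix(x)
  assert_scalar_number(power, "power", lower = 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_("constant column(s): ",
          paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  a <- abs(stats::cor(x))^power
  diag(a) <- 1
  a
}

# Scale-free topology fit: regress log10 frequency on log10 mean
# connectivity over connectivity bins. Returns the R^2 signed against the
# slope (positive only for the decreasing relationship scale-free
# topology implies).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(signed_r2 = 0, slope = NA_real_))
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(list(signed_r2 = 0, slope = NA_real_))
  bins <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) return(list(signed_r2 = 0, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-thresholding power
#'
#' Returns the smallest power in `powers` whose scale-free topology fit
#' (signed R-squared of the log-log regression of connectivity-bin
#' frequency on mean connectivity) reaches `target`; if none does, falls
#' back to 6 with a warning, the conventional default for correlation
#' networks of this size.
#'
#' @param x residualized samples x metabolites matrix (at least 10 of
#'   each).
#' @param powers candidate powers.
#' @param target scale-free fit target (default 0.8).
#' @return The chosen power (integer), with the per-power fit table
#'   attached as attribute `"fit_table"` and a logical attribute
#'   `"fallback"`.
#' @export
choose_soft_power <- function(x, powers = 1:20, target = 0.8) {
  x <- as.matrix(x)
  if (ncol(x) < 10) stop_("need at least 10 metabolites")
  if (nrow(x) < 10) stop_("need at least 10 samples")
  r <- abs(stats::cor(x))
  diag(r) <- 0
  fits <- data.frame(power = powers, signed_r2 = NA_real_, slope = NA_real_)
  chosen <- NA_integer_
  for (i in seq_along(powers)) {
    k <- colSums(r^powers[i])
    sf <- scale_free_fit(k)
    fits$signed_r2[i] <- sf$signed_r2
    fits$slope[i] <- sf$slope
    if (is.na(chosen) && !is.na(sf$signed_r2) && sf$signed_r2 >= target) {
      chosen <- powers[i]
    }
  }
  fallback <- is.na(chosen)
  if (fallback) {
    warning("no power reached scale-free fit R^2 >= ", target,
            "; falling back to 6", call. = FALSE)
    chosen <- 6L
  }
  structure(as.integer(chosen), fit_table = fits, fallback = fallback)
}

#' Topological overlap similarity
#'
#' For an adjacency matrix `A` with unit diagonal, the topological
#' overlap of nodes i and j is
#' `(sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the sum
#' over shared neighbours `u != i, j` and connectivity
#' `k_i = sum_{u != i} a_iu`. Nodes with high overlap share neighbours
#' as well as a direct edge; `1 - TOM` is the clustering dissimilarity.
#'
#' @param a symmetric adjacency matrix, entries in `[0, 1]`, unit
#'   diagonal.
#' @return Symmetric TOM matrix with unit diagonal and entries in
#'   `[0, 1]`.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || !isSymmetric(unname(a), tol = 1e-10)) {
    stop_("adjacency must be a symmetric square matrix")
  }
  if (any(a < 0 | a > 1)) stop_("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-10)) stop_("adjacency diagonal must be 1")
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a  # sum over u != i,j of a_iu a_uj (unit diagonal)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-abundance modules from topological overlap
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' dissimilarity height; clusters smaller than `min_size` are labelled
#' `"grey"` (unassigned). Modules are labelled by decreasing size with
#' the conventional colour names (`turquoise`, `blue`, `brown`, ...);
#' the colour-to-module mapping is cosmetic.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param cut_height static tree-cut height on the dissimilarity scale,
#'   in `(0, 1)`.
#' @param min_size minimum module size (>= 3).
#' @return An object of class `module_assignment`: data.frame
#'   `assignment` (`metabolite`, `module`), `sizes` (named module
#'   sizes), and the clustering `tree`.
#' @export
detect_modules <- function(tom, cut_height = 0.75, min_size = 5) {
  assert_scalar_number(cut_height, "cut_height")
  if (cut_height <= 0 || cut_height >= 1) {
    stop_("cut_height must lie in (0, 1)")
  }
  if (min_size < 3) stop_("min_size must be >= 3")
  ids <- colnames(tom) %||% sprintf("f%03d", seq_len(ncol(tom)))
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_size]
  # Rank retained clusters by decreasing size; ties broken by the
  # smallest member id for determinism.
  first_id <- vapply(big, function(cl) min(ids[raw == as.integer(cl)]),
                     character(1))
  ranked <- big[order(-as.integer(sizes[big]), first_id)]
  module <- rep("grey", length(raw))
  for (i in seq_along(ranked)) {
    module[raw == as.integer(ranked[i])] <- module_color_label(i)
  }
  if (all(module == "grey")) {
    warning("no module reached min_size; all features unassigned (grey)",
            call. = FALSE)
  }
  out_sizes <- table(module)
  structure(
    list(assignment = data.frame(metabolite = ids, module = module,
                                 stringsAsFactors = FALSE),
         sizes = out_sizes, tree = tree,
         cut_height = cut_height, min_size = min_size),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- sum(names(x$sizes) != "grey")
  cat(sprintf("<module_assignment> %d modules over %d metabolites\n",
              n_mod, nrow(x$assignment)))
  print(x$sizes)
  invisible(x)
}

#' Module members
#'
#' @param ma a [detect_modules()] result.
#' @param module module label.
#' @return Character vector of member metabolite ids.
#' @export
module_members <- function(ma, module) {
  ma$assignment$metabolite[ma$assignment$module == module]
}

#' Hub metabolite of a module
#'
#' The member with the largest intramodular connectivity (sum of
#' adjacency to the other members); ties are broken lexicographically by
#' metabolite id.
#'
#' @param a adjacency matrix with dimnames.
#' @param members character vector of at least 2 module member ids.
#' @return The hub metabolite id.
#' @export
hub_metabolite <- function(a, members) {
  if (!length(members)) stop_("empty module")
  if (length(members) < 2) stop_("a module needs >= 2 members")
  if (!all(members %in% colnames(a))) {
    stop_("module member(s) missing from the adjacency matrix")
  }
  sub <- a[members, members]
  conn <- rowSums(sub) - 1
  hubs <- names(conn)[conn == max(conn)]
  sort(hubs)[1]
}

#' Modular differential connectivity statistic
#'
#' Signed sum, over unordered member pairs of a module, of the
#' difference in soft-thresholded adjacency between two groups:
#' `sum_{i<j} (a_ij^A - a_ij^B)`, each adjacency computed within its
#' group's samples at the shared power. Positive values mean tighter
#' co-regulation in group A; the statistic is antisymmetric in the two
#' groups. The secondary connectivity ratio
#' `sum a_ij^A / sum a_ij^B` is available from
#' [mdc_permutation_test()].
#'
#' @param x_a,x_b samples x metabolites matrices for the two groups
#'   (columns must include the module members).
#' @param members module member ids (>= 3).
#' @param power soft-thresholding power shared by both groups.
#' @return The MDC statistic (single number).
#' @export
mdc_statistic <- function(x_a, x_b, members, power = 6) {
  if (length(members) < 3) stop_("MDC needs a module of >= 3 members")
  for (nm in list(a = x_a, b = x_b)) {
    if (!all(members %in% colnames(nm))) {
      stop_("module member(s) missing from a group's matrix")
    }
  }
  a_a <- adjacency_matrix(x_a[, members, drop = FALSE], power)
  a_b <- adjacency_matrix(x_b[, members, drop = FALSE], power)
  sum((a_a - a_b)[upper.tri(a_a)])
}

#' Permutation test for modular differential connectivity
#'
#' Pools the samples of both groups, permutes the group labels
#' (preserving group sizes), and recomputes the MDC statistic to build
#' the permutation null. The p-value uses the add-one estimator
#' `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, so with 1000
#' permutations the smallest attainable p is 1/1001. A gain of
#' connectivity (GOC) is called when the statistic is positive and
#' significant, a loss (LOC) when negative and significant.
#'
#' @param x_a,x_b samples x metabolites matrices for the two groups.
#' @param members module member ids (>= 3).
#' @param power shared soft-thresholding power.
#' @param n_perm number of permutations (>= 100; 1000 by default).
#' @param alpha significance level for the GOC/LOC call.
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `mdc_result`: `statistic`, `ratio`
#'   (connectivity ratio A/B), `perm_p`, `call` (`"GOC"`, `"LOC"` or
#'   `"none"`), `n_perm`, group sizes.
#' @export
mdc_permutation_test <- function(x_a, x_b, members, power = 6,
                                 n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (n_perm < 100) stop_("n_perm must be >= 100")
  n_a <- nrow(x_a)
  n_b <- nrow(x_b)
  if (n_a < 5 || n_b < 5) stop_("each group needs >= 5 samples")
  obs <- mdc_statistic(x_a, x_b, members, power)
  a_a <- adjacency_matrix(x_a[, members, drop = FALSE], power)
  a_b <- adjacency_matrix(x_b[, members, drop = FALSE], power)
  ratio <- sum(a_a[upper.tri(a_a)]) / sum(a_b[upper.tri(a_b)])

  pool <- rbind(x_a[, members, drop = FALSE], x_b[, members, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_a + n_b)
    tp <- mdc_statistic(pool[idx[seq_len(n_a)], , drop = FALSE],
                        pool[idx[(n_a + 1):(n_a + n_b)], , drop = FALSE],
                        members, power)
    if (abs(tp) >= abs(obs)) exceed <- exceed + 1L
  }
  perm_p <- (1 + exceed) / (n_perm + 1)
  call <- if (perm_p < alpha) {
    if (obs > 0) "GOC" else if (obs < 0) "LOC" else "none"
  } else "none"
  structure(
    list(statistic = obs, ratio = ratio, perm_p = perm_p, call = call,
         n_perm = n_perm, alpha = alpha, n_a = n_a, n_b = n_b,
         members = members),
    class = "mdc_result"
  )
}

#' @export
print.mdc_result <- function(x, ...) {
  cat(sprintf(
    "MDC = %.3f (ratio %.3f), perm p = %.4g (%d permutations): %s\n",
    x$statistic, x$ratio, x$perm_p, x$n_perm, x$call
  ))
  invisible(x)
}

#' Per-group module networks with differential connectivity
#'
#' The network stage of the pipeline: residualizes clinical covariates
#' out of the (log-scale) metabolite abundances, builds one weighted
#' correlation network per intervention group from the pooled
#' (baseline + year1) residualized samples, detects modules per group,
#' identifies hubs, and runs the modular differential connectivity
#' permutation test for each module of the first group of every
#' pairwise comparison.
#'
#' @param x a normalized, filtered [metab_matrix()].
#' @param cohort cohort data.frame (for the clinical covariates).
#' @param power soft-thresholding power, or `"auto"` to choose by
#'   scale-free fit on the pooled residualized matrix.
#' @param cut_height,min_size module detection parameters, see
#'   [detect_modules()].
#' @param n_perm,alpha MDC permutation test parameters.
#' @param seed integer seed for the permutation streams.
#' @return An object of class `metab_network`: per-group residualized
#'   matrices, adjacencies, `modules` (per-group
#'   [detect_modules()] results), `hubs`, `power`, and `mdc`
#'   (data.frame over comparisons x modules).
#' @export
run_network <- function(x, cohort, power = "auto", cut_height = 0.75,
                        min_size = 5, n_perm = 1000, alpha = 0.05,
                        seed = 1L) {
  if (!inherits(x, "metab_matrix")) stop_("`x` must be a metab_matrix")
  vals <- impute_half_min(x$values)
  logv <- log(vals)
  sm <- x$sample_meta
  idx <- match(sm$participant, cohort$participant)
  covs <- data.frame(
    age = cohort$age[idx],
    sex = cohort$sex[idx],
    bmi = cohort$bmi_baseline[idx],
    weight_loss = percent_change(cohort$weight_baseline,
                                 cohort$weight_year1)[idx]
  )
  resid_all <- residualize(logv, covs)

  if (identical(power, "auto")) {
    power <- choose_soft_power(resid_all)
  }
  groups <- INTERVENTION_GROUPS[INTERVENTION_GROUPS %in% sm$group]
  resid_by_group <- lapply(groups, function(g) {
    resid_all[sm$group == g, , drop = FALSE]
  })
  names(resid_by_group) <- groups

  adj <- lapply(resid_by_group, adjacency_matrix, power = as.integer(power))
  modules <- lapply(adj, function(a) {
    detect_modules(tom_similarity(a), cut_height, min_size)
  })
  hubs <- lapply(groups, function(g) {
    labs <- setdiff(names(modules[[g]]$sizes), "grey")
    vapply(labs, function(l) {
      hub_metabolite(adj[[g]], module_members(modules[[g]], l))
    }, character(1))
  })
  names(hubs) <- groups

  pairs <- Filter(function(p) all(p %in% groups), CONTRAST_PAIRS)
  mdc_rows <- list()
  for (p in pairs) {
    ma <- modules[[p[1]]]
    labs <- setdiff(names(ma$sizes), "grey")
    for (l in labs) {
      mem <- module_members(ma, l)
      res <- mdc_permutation_test(
        resid_by_group[[p[1]]], resid_by_group[[p[2]]], mem,
        power = as.integer(power), n_perm = n_perm, alpha = alpha,
        seed = derive_seed(seed, paste(p[1], p[2], l))
      )
      mdc_rows[[length(mdc_rows) + 1L]] <- data.frame(
        module = l, group_a = p[1], group_b = p[2],
        size = length(mem), statistic = res$statistic, ratio = res$ratio,
        perm_p = res$perm_p, call = res$call, stringsAsFactors = FALSE
      )
    }
  }
  mdc <- if (length(mdc_rows)) do.call(rbind, mdc_rows) else
    data.frame(module = character(), group_a = character(),
               group_b = character(), size = integer(),
               statistic = numeric(), ratio = numeric(),
               perm_p = numeric(), call = character(),
               stringsAsFactors = FALSE)

  structure(
    list(power = as.integer(power),
         power_fallback = isTRUE(attr(power, "fallback")),
         residuals = resid_by_group, adjacency = adj,
         modules = modules, hubs = hubs, mdc = mdc,
         comparisons = vapply(pairs, function(p) paste(p[1], "vs", p[2]),
                              character(1)),
         n_perm = n_perm, alpha = alpha, seed = seed),
    class = "metab_network"
  )
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("<metab_network> power %d; modules per group:\n", x$power))
  for (g in names(x$modules)) {
    n_mod <- sum(names(x$modules[[g]]$sizes) != "grey")
    cat(sprintf("  %s: %d modules (hubs: %s)\n", g, n_mod,
                paste(x$hubs[[g]], collapse = ", ")))
  }
  cat(sprintf("MDC comparisons: %d (%d significant)\n", nrow(x$mdc),
              sum(x$mdc$call != "none")))
  invisible(x)
}

#' Write per-group module tables and the MDC table
#'
#' @param net a [run_network()] result.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_network_tsv <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in names(net$modules)) {
    ma <- net$modules[[g]]$assignment
    a <- net$adjacency[[g]]
    conn <- vapply(seq_len(nrow(ma)), function(i) {
      mem <- module_members(net$modules[[g]], ma$module[i])
      if (length(mem) < 2) return(NA_real_)
      sum(a[ma$metabolite[i], setdiff(mem, ma$metabolite[i])])
    }, numeric(1))
    out <- data.frame(
      metabolite = ma$metabolite, module = ma$module,
      intramodular_connectivity = signif(conn, 6),
      hub = ma$metabolite %in% net$hubs[[g]],
      stringsAsFactors = FALSE
    )
    p <- file.path(dir, sprintf("modules_%s.tsv", g))
    utils::write.table(out, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  mdc <- net$mdc
  num <- vapply(mdc, is.numeric, logical(1))
  mdc[num] <- lapply(mdc[num], signif, digits = 6)
  p <- file.path(dir, "mdc.tsv")
  utils::write.table(mdc, p, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
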
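#' Pipeline configuration
#'
#' Collects all stage parameters for [run_pipeline()]. Either a
#' [synth_config()] (to simulate a cohort) or paths to an existing
#' cohort CSV + matrix CSV + annotation TSV must be supplied.
#'
#' @param synth a [synth_config()], or `NULL` when reading files.
#' @param cohort_csv,matrix_csv,annotation_tsv input paths when not
#'   simulating.
#' @param out_dir output directory.
#' @param seed master seed for every stochastic stage.
#' @param presence_threshold presence-filter fraction.
#' @param power soft-thresholding power or `"auto"`.
#' @param cut_height,min_size module detection parameters.
#' @param n_perm MDC permutation count.
#' @param alpha significance level for MDC calls.
#' @param q_threshold q-value cutoff for significant-hit counts.
#' @param gmt,pathway_edges optional pathway database paths; when given,
#'   the enrichment stage runs on the largest RYGB module's known
#'   members.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), cohort_csv = NULL,
                            matrix_csv = NULL, annotation_tsv = NULL,
                            out_dir = tempfile("metabshift_run_"),
                            seed = 1L, presence_threshold = 0.5,
                            power = "auto", cut_height = 0.75,
                            min_size = 5, n_perm = 1000, alpha = 0.05,
                            q_threshold = 0.05, gmt = NULL,
                            pathway_edges = NULL) {
  if (is.null(synth) &&
      (is.null(cohort_csv) || is.null(matrix_csv) || is.null(annotation_tsv))) {
    stop_("supply either a synth_config or cohort/matrix/annotation paths")
  }
  for (p in c(cohort_csv, matrix_csv, annotation_tsv, gmt, pathway_edges)) {
    if (!is.null(p) && !file.exists(p)) stop_("file not found: ", p)
  }
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(q_threshold, "q_threshold", 0, 1)
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  structure(
    list(synth = synth, cohort_csv = cohort_csv, matrix_csv = matrix_csv,
         annotation_tsv = annotation_tsv, out_dir = out_dir,
         seed = as.integer(seed), presence_threshold = presence_threshold,
         power = power, cut_height = cut_height, min_size = min_size,
         n_perm = n_perm, alpha = alpha, q_threshold = q_threshold,
         gmt = gmt, pathway_edges = pathway_edges),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), sum-intensity
#' normalization, presence filtering, change-table construction, the
#' four interaction scans (FPG and HbA1c outcomes x baseline and change
#' exposures), the per-group network stage with modular differential
#' connectivity over the three pairwise group comparisons, and —
#' when a pathway database is configured — pathway enrichment of the
#' largest RYGB module. All tabular outputs are tab-separated UTF-8
#' with fixed headers; a JSON manifest records inputs, seeds,
#' dimensions, per-stage warnings, significant-hit counts, the module /
#' MDC summary and an MD5 checksum per output file. Re-running with the
#' same configuration and seed reproduces every checksum.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_("`config` must be a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- list()
  note <- function(stage, msg) {
    warnings_log[[length(warnings_log) + 1L]] <<-
      list(stage = stage, message = msg)
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop_(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  # --- simulate / load ------------------------------------------------
  if (!is.null(config$synth)) {
    sim <- run_stage("simulate", {
      cfg <- config$synth
      cfg$seed <- config$seed
      generate_cohort(cfg)
    })
    cohort <- sim$cohort
    mat <- sim$matrix
    paths <- run_stage("simulate", write_synth_cohort(sim, config$out_dir))
    input_desc <- list(source = "synthetic", seed = config$seed)
  } else {
    cohort <- run_stage("load", utils::read.csv(config$cohort_csv,
                                                stringsAsFactors = FALSE))
    mat <- run_stage("load", read_metab_matrix(config$matrix_csv,
                                               config$annotation_tsv))
    input_desc <- list(source = "files", cohort_csv = config$cohort_csv,
                       matrix_csv = config$matrix_csv)
  }

  # --- preprocess -----------------------------------------------------
  norm <- run_stage("preprocess", sum_normalize(mat))
  filt <- run_stage("preprocess",
                    presence_filter(norm, config$presence_threshold))
  n_dropped <- length(attr(filt, "dropped"))
  ct <- run_stage("preprocess", build_change_table(filt, cohort))

  # --- scans ----------------------------------------------------------
  scan_specs <- expand.grid(outcome = c("fpg", "hba1c"),
                            exposure = c("baseline", "change"),
                            stringsAsFactors = FALSE)
  scans <- list()
  sig_counts <- list()
  for (i in seq_len(nrow(scan_specs))) {
    oc <- scan_specs$outcome[i]
    ex <- scan_specs$exposure[i]
    nm <- sprintf("scan_%s_%s", oc, ex)
    sc <- run_stage(nm, run_scan(ct, outcome = oc, exposure = ex))
    write_scan_tsv(sc, file.path(config$out_dir, paste0(nm, ".tsv")))
    scans[[nm]] <- sc
    s <- summary(sc, q_threshold = config$q_threshold)
    sig_counts[[nm]] <- stats::setNames(as.list(s$n_significant), s$contrast)
  }

  # --- network --------------------------------------------------------
  net <- run_stage("network", run_network(
    filt, cohort, power = config$power, cut_height = config$cut_height,
    min_size = config$min_size, n_perm = config$n_perm,
    alpha = config$alpha, seed = config$seed
  ))
  write_network_tsv(net, config$out_dir)
  module_summary <- lapply(net$modules, function(m) {
    as.list(m$sizes)
  })

  # --- enrichment (optional) -----------------------------------------
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- run_stage("enrich", {
      sets <- read_gmt(config$gmt)
      edges <- if (!is.null(config$pathway_edges)) {
        read_pathway_edges(config$pathway_edges)
      }
      known <- filt$feature_meta$metabolite[filt$feature_meta$known]
      rygb_mods <- net$modules[["RYGB"]]
      labs <- setdiff(names(rygb_mods$sizes), "grey")
      if (!length(labs)) {
        note("enrich", "no RYGB module to enrich; skipping")
        NULL
      } else {
        hits <- intersect(module_members(rygb_mods, labs[1]), known)
        et <- run_enrichment(hits, sets, background = known, edges = edges,
                             bh = TRUE)
        out <- as.data.frame(et)
        num <- vapply(out, is.numeric, logical(1))
        out[num] <- lapply(out[num], signif, digits = 6)
        utils::write.table(out, file.path(config$out_dir, "enrichment.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        et
      }
    })
  }

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "metabshift",
    version = as.character(utils::packageVersion("metabshift")),
    seed = config$seed,
    inputs = input_desc,
    dimensions = list(
      n_participants = nrow(cohort),
      n_samples = nrow(mat$values),
      n_metabolites = ncol(mat$values),
      n_known = sum(mat$feature_meta$known),
      n_retained = ncol(filt$values),
      n_dropped_by_filter = n_dropped
    ),
    parameters = list(
      presence_threshold = config$presence_threshold,
      power = net$power, power_fallback = net$power_fallback,
      cut_height = config$cut_height, min_size = config$min_size,
      n_perm = config$n_perm, alpha = config$alpha,
      q_threshold = config$q_threshold,
      exposure_standardized_after_percent_change = TRUE,
      weight_loss_units = "fractional change in body weight"
    ),
    scans = sig_counts,
    modules = module_summary,
    mdc_comparisons = as.list(net$comparisons),
    mdc = if (nrow(net$mdc)) {
      lapply(seq_len(nrow(net$mdc)), function(i) as.list(net$mdc[i, ]))
    } else list(),
    enrichment_top = if (!is.null(enrichment)) {
      as.list(as.data.frame(enrichment)[1, ])
    },
    warnings = warnings_log,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
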
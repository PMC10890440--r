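#' Sample-by-metabolite abundance container
#'
#' Bundles a numeric abundance matrix (samples in rows, metabolites in
#' columns) with its sample annotation (participant, timepoint,
#' intervention group) and feature annotation (metabolite id, known /
#' unknown flag). Every participant must contribute exactly one
#' `baseline` and one `year1` sample, and all present abundances must be
#' nonnegative; missing values are allowed.
#'
#' @param values numeric matrix, samples x metabolites, with rownames
#'   (sample ids) and colnames (metabolite ids).
#' @param sample_meta data.frame with columns `sample_id`, `participant`,
#'   `timepoint` (one of `"baseline"`, `"year1"`) and `group`, one row
#'   per row of `values`, in the same order.
#' @param feature_meta data.frame with columns `metabolite` and logical
#'   `known`, one row per column of `values`, in the same order.
#' @return An object of class `metab_matrix` (a list with the three
#'   components above).
#' @export
metab_matrix <- function(values, sample_meta, feature_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_("`values` must be a numeric matrix (samples x metabolites)")
  }
  if (nrow(sample_meta) != nrow(values)) {
    stop_("`sample_meta` must have one row per sample")
  }
  if (nrow(feature_meta) != ncol(values)) {
    stop_("`feature_meta` must have one row per metabolite")
  }
  required_s <- c("sample_id", "participant", "timepoint", "group")
  if (!all(required_s %in% names(sample_meta))) {
    stop_("`sample_meta` needs columns: ", paste(required_s, collapse = ", "))
  }
  if (!all(c("metabolite", "known") %in% names(feature_meta))) {
    stop_("`feature_meta` needs columns: metabolite, known")
  }
  if (!all(sample_meta$timepoint %in% c("baseline", "year1"))) {
    stop_("timepoint must be 'baseline' or 'year1'")
  }
  tab <- table(sample_meta$participant, sample_meta$timepoint)
  if (ncol(tab) != 2L || any(tab != 1L)) {
    stop_("each participant needs exactly one baseline and one year1 sample")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_("abundances must be nonnegative where present")
  }
  rownames(values) <- sample_meta$sample_id
  colnames(values) <- feature_meta$metabolite
  structure(
    list(
      values = values,
      sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE),
      feature_meta = as.data.frame(feature_meta, stringsAsFactors = FALSE)
    ),
    class = "metab_matrix"
  )
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf(
    "<metab_matrix> %d samples x %d metabolites (%d known)\n",
    nrow(x$values), ncol(x$values), sum(x$feature_meta$known)
  ))
  cat(sprintf(
    "  participants: %d; groups: %s\n",
    length(unique(x$sample_meta$participant)),
    paste(names(table(x$sample_meta$group)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

# Subset a metab_matrix by metabolite (columns), keeping annotations in step.
subset_features <- function(x, keep) {
  metab_matrix(
    x$values[, keep, drop = FALSE],
    x$sample_meta,
    x$feature_meta[keep, , drop = FALSE]
  )
}

#' Write a metabolite matrix as plain-text files
#'
#' Writes the abundance matrix as CSV (samples in rows, header row of
#' metabolite ids, first column `sample_id`) and a companion annotation
#' TSV holding the known-flag per metabolite and the sample-to-participant
#' / timepoint / group map.
#'
#' @param x a [metab_matrix()].
#' @param matrix_csv,annotation_tsv output paths.
#' @return Invisibly, the two paths.
#' @export
write_metab_matrix <- function(x, matrix_csv, annotation_tsv) {
  out <- data.frame(sample_id = x$sample_meta$sample_id,
                    x$values, check.names = FALSE)
  utils::write.csv(out, matrix_csv, row.names = FALSE)
  ann <- list(sample_meta = x$sample_meta, feature_meta = x$feature_meta)
  con <- file(annotation_tsv, "w")
  on.exit(close(con))
  writeLines("# sample annotations", con)
  utils::write.table(ann$sample_meta, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("# feature annotations", con)
  utils::write.table(ann$feature_meta, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(matrix_csv, annotation_tsv))
}

#' Read a metabolite matrix written by [write_metab_matrix()]
#'
#' @param matrix_csv,annotation_tsv paths written by [write_metab_matrix()].
#' @return A [metab_matrix()].
#' @export
read_metab_matrix <- function(matrix_csv, annotation_tsv) {
  raw <- utils::read.csv(matrix_csv, check.names = FALSE)
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- raw$sample_id
  lines <- readLines(annotation_tsv)
  brk <- which(lines == "# feature annotations")
  sm <- utils::read.table(text = lines[2:(brk - 1)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  fm <- utils::read.table(text = lines[(brk + 1):length(lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  metab_matrix(values, sm, fm)
}
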
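#' Pathway graph
#'
#' A pathway as a set of compound nodes plus undirected edges between
#' them (from a pathway-topology source). Self-loops are rejected and
#' every edge must reference a node of the pathway.
#'
#' @param id pathway identifier.
#' @param name human-readable pathway name.
#' @param nodes character vector of compound identifiers (nonempty).
#' @param edges optional two-column matrix or data.frame of undirected
#'   edges between nodes.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(id, name = id, nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (!length(nodes)) stop_("a pathway needs at least one node")
  if (is.null(edges) || !NROW(edges)) {
    edges <- matrix(character(), ncol = 2)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2])) stop_("self-loops are not allowed")
    if (!all(edges %in% nodes)) {
      stop_("edge references a compound absent from the pathway")
    }
  }
  structure(list(id = as.character(id), name = as.character(name),
                 nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s (%s): %d nodes, %d edges\n",
              x$id, x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read pathway memberships from a GMT file
#'
#' Standard tab-delimited gene-set format reused for metabolite sets:
#' one line per pathway — id, description, then member compounds.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of members; descriptions are
#'   kept in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("empty pathway database: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(desc, ids)
  sets
}

#' Read per-pathway edge lists
#'
#' Tab-separated file with columns `pathway_id`, `node_a`, `node_b`.
#'
#' @param path TSV file path.
#' @return data.frame with those three columns.
#' @export
read_pathway_edges <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("pathway_id", "node_a", "node_b")
  if (!all(need %in% names(e))) {
    stop_("edge file needs columns: ", paste(need, collapse = ", "))
  }
  e[need]
}

#' Fisher's exact (hypergeometric) over-representation p-value
#'
#' One-sided tail probability of observing at least the realized overlap
#' between the hit list and a pathway, on the 2x2 table restricted to
#' the background compounds (here, the known metabolites).
#'
#' @param hits character vector of hit compounds (must be a subset of
#'   `background`).
#' @param pathway_nodes compounds of the pathway.
#' @param background the background compound universe.
#' @return The upper-tail hypergeometric probability.
#' @export
fisher_enrichment <- function(hits, pathway_nodes, background) {
  hits <- unique(hits)
  background <- unique(background)
  if (!length(background)) stop_("empty background")
  if (!all(hits %in% background)) {
    stop_("hit(s) not in background: ",
          paste(setdiff(hits, background), collapse = ", "))
  }
  in_bg <- unique(pathway_nodes)[unique(pathway_nodes) %in% background]
  k <- sum(hits %in% in_bg)
  stats::phyper(k - 1, length(in_bg), length(background) - length(in_bg),
                length(hits), lower.tail = FALSE)
}

#' Topological importance of pathway compounds
#'
#' Node betweenness centrality (shortest-path count form, computed
#' within connected components), normalized so the importances sum to 1
#' within the pathway. If every centrality is zero (two-node pathways,
#' complete graphs, edge-free graphs) the importance falls back to
#' uniform `1/n`.
#'
#' @param graph a [pathway_graph()].
#' @return Named numeric vector of importances summing to 1.
#' @export
betweenness_importance <- function(graph) {
  if (!inherits(graph, "pathway_graph")) {
    stop_("`graph` must be a pathway_graph")
  }
  n <- length(graph$nodes)
  if (!nrow(graph$edges)) {
    return(stats::setNames(rep(1 / n, n), graph$nodes))
  }
  ig <- igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  )
  b <- igraph::betweenness(ig, directed = FALSE, weights = NA)
  b <- b[graph$nodes]
  if (sum(b) == 0) {
    return(stats::setNames(rep(1 / n, n), graph$nodes))
  }
  stats::setNames(as.numeric(b / sum(b)), graph$nodes)
}

#' Pathway impact score of a hit list
#'
#' Sum of the topological importance of the hit compounds divided by
#' the total importance of all compounds in the pathway (which is 1
#' after normalization), yielding a value in `[0, 1]`.
#'
#' @param hits character vector of hit compounds.
#' @param graph a [pathway_graph()].
#' @return The impact score.
#' @export
impact_score <- function(hits, graph) {
  imp <- betweenness_importance(graph)
  sum(imp[names(imp) %in% unique(hits)])
}

#' Pathway over-representation analysis
#'
#' Tests every pathway with at least one background member for
#' over-representation of the hit metabolites (one-sided Fisher's exact
#' test against the known-metabolite background) and computes the
#' topology-based impact score. Compounds are matched by exact
#' identifier after case-folding; hits that match no background
#' compound are reported in the `"unmatched"` attribute, never silently
#' dropped.
#'
#' @param hits character vector of hit metabolites.
#' @param pathways named list of member vectors (as from [read_gmt()])
#'   or a list of [pathway_graph()] objects.
#' @param background character vector of background compounds (the
#'   known metabolites).
#' @param edges optional edge data.frame from [read_pathway_edges()],
#'   used when `pathways` is a membership list.
#' @param bh if `TRUE`, append a Benjamini-Hochberg adjusted p column.
#' @return data.frame of class `enrichment_table`, sorted by
#'   `fisher_p`: `pathway`, `name`, `size` (pathway compounds in the
#'   background), `overlap`, `fisher_p`, `impact`.
#' @export
run_enrichment <- function(hits, pathways, background, edges = NULL,
                           bh = FALSE) {
  if (!length(pathways)) stop_("empty pathway database")
  if (!length(background)) stop_("empty background")
  fold <- function(x) tolower(trimws(as.character(x)))
  bg <- unique(fold(background))
  hits_f <- unique(fold(hits))
  unmatched <- unique(hits)[!(hits_f %in% bg)]
  hits_f <- hits_f[hits_f %in% bg]

  graphs <- if (length(pathways) && inherits(pathways[[1]], "pathway_graph")) {
    pathways
  } else {
    desc <- attr(pathways, "descriptions") %||%
      stats::setNames(names(pathways), names(pathways))
    lapply(names(pathways), function(id) {
      ed <- NULL
      if (!is.null(edges)) {
        sel <- edges$pathway_id == id
        if (any(sel)) ed <- as.matrix(edges[sel, c("node_a", "node_b")])
      }
      nm <- if (id %in% names(desc) && nzchar(desc[[id]])) desc[[id]] else id
      pathway_graph(id, nm, pathways[[id]], ed)
    })
  }

  rows <- list()
  for (g in graphs) {
    nodes_f <- fold(g$nodes)
    in_bg <- intersect(nodes_f, bg)
    if (!length(in_bg)) next
    overlap <- intersect(hits_f, in_bg)
    p <- fisher_enrichment(hits_f, nodes_f, bg)
    gf <- pathway_graph(g$id, g$name, nodes_f,
                        if (nrow(g$edges)) {
                          matrix(fold(g$edges), ncol = 2)
                        })
    imp <- impact_score(overlap, gf)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = g$id, name = g$name,
      size = length(in_bg), overlap = length(overlap),
      fisher_p = p, impact = imp, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop_("no pathway has background members")
  out <- do.call(rbind, rows)
  out <- out[order(out$fisher_p, out$pathway), ]
  rownames(out) <- NULL
  if (bh) out$bh_q <- stats::p.adjust(out$fisher_p, method = "BH")
  attr(out, "unmatched") <- unmatched
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Pathway enrichment: %d pathways\n", nrow(x)))
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  un <- attr(x, "unmatched")
  if (length(un)) {
    cat("Unmatched hits:", paste(un, collapse = ", "), "\n")
  }
  invisible(x)
}
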
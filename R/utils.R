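# Internal helpers shared across modules.

# Canonical intervention arms, in reporting order.
INTERVENTION_GROUPS <- c("IMI", "BAND", "RYGB")

# Pairwise contrasts in the reporting order used throughout: the surgical
# reference comparison first, then surgery-vs-surgery, then BAND vs IMI.
CONTRAST_PAIRS <- list(
  c("RYGB", "IMI"),
  c("RYGB", "BAND"),
  c("BAND", "IMI")
)

# Size-ranked module label palette (largest module first). The names echo
# the colour convention of weighted correlation network analysis; the
# mapping is cosmetic.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

module_color_label <- function(rank) {
  if (rank <= length(MODULE_COLORS)) MODULE_COLORS[rank]
  else sprintf("module%02d", rank)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted correlation modules. Returns 1 for
#' identical partitions (up to label permutation) and about 0 for
#' independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single number, the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream tag.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
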
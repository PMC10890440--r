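# Independent brute-force oracles and toy-data builders used across the
# suite. These deliberately avoid the package's own code paths.

# Toy dataset whose within-group OLS slopes are exact by construction:
# per group, x = (-2,-1,0,1,2) and a residual pattern orthogonal to both
# the intercept and x, so the slope equals the requested value exactly.
interaction_toy <- function(slopes, noise_scale = 0.01) {
  x0 <- c(-2, -1, 0, 1, 2)
  e0 <- c(2, -1, -2, -1, 2)  # sum(e0) = 0 and sum(e0 * x0) = 0
  g <- rep(names(slopes), each = length(x0))
  y <- unlist(lapply(unname(slopes), function(b) b * x0 + noise_scale * e0))
  list(y = y, m = rep(x0, length(slopes)), group = g)
}

# Triple-loop topological overlap oracle.
brute_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Shortest-path betweenness oracle: BFS distances and path counts from
# each endpoint, then the pair-dependency sum over interior nodes.
brute_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- vector("list", n)
  if (NROW(edges)) {
    for (i in seq_len(NROW(edges))) {
      a <- match(edges[i, 1], nodes)
      b <- match(edges[i, 2], nodes)
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  bfs <- function(s) {
    dist <- rep(Inf, n)
    cnt <- rep(0, n)
    dist[s] <- 0
    cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          cnt[w] <- cnt[w] + cnt[v]
          nxt <- c(nxt, w)
        } else if (dist[w] == dist[v] + 1) {
          cnt[w] <- cnt[w] + cnt[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, cnt = cnt)
  }
  b <- rep(0, n)
  if (n >= 3) {
    for (s in 1:(n - 1)) {
      fs <- bfs(s)
      for (t in (s + 1):n) {
        if (is.infinite(fs$dist[t])) next
        ft <- bfs(t)
        for (v in seq_len(n)) {
          if (v != s && v != t && fs$dist[v] + ft$dist[v] == fs$dist[t]) {
            b[v] <- b[v] + fs$cnt[v] * ft$cnt[v] / fs$cnt[t]
          }
        }
      }
    }
  }
  stats::setNames(b, nodes)
}

# Upper-tail hypergeometric probability by direct summation of the pmf
# written with binomial coefficients.
brute_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small metab_matrix builder: one participant per sample pair, explicit
# values, groups recycled.
toy_metab_matrix <- function(values, known, groups) {
  n_part <- nrow(values) / 2
  sm <- data.frame(
    sample_id = paste0("S", seq_len(nrow(values))),
    participant = rep(sprintf("P%02d", seq_len(n_part)), each = 2),
    timepoint = rep(c("baseline", "year1"), n_part),
    group = rep(groups, each = 2, length.out = nrow(values)),
    stringsAsFactors = FALSE
  )
  fm <- data.frame(metabolite = colnames(values), known = known,
                   stringsAsFactors = FALSE)
  metab_matrix(values, sm, fm)
}
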
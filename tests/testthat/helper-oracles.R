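# Independent oracles used by the tests. Each is a deliberately naive
# reference implementation, kept separate from the package code paths it
# checks.

# Brute-force edge betweenness on an undirected edge list: for every
# unordered node pair, enumerate all shortest paths by backtracking and
# credit each edge on them with 1/(number of shortest paths).
oracle_edge_betweenness <- function(edges) {
  edges <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  nodes <- unique(as.vector(edges))
  adj <- lapply(nodes, function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  names(adj) <- nodes
  ekey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  eb <- stats::setNames(numeric(nrow(edges)),
                        apply(edges, 1, function(e) ekey(e[1], e[2])))
  bfs_dist <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]
      q <- q[-1]
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          q <- c(q, w)
        }
      }
    }
    dist
  }
  all_paths <- function(s, t, dist) {
    if (s == t) return(list(t))
    preds <- Filter(function(w) dist[w] == dist[t] - 1, adj[[t]])
    out <- list()
    for (p in preds) {
      for (pp in all_paths(s, p, dist)) out[[length(out) + 1]] <- c(pp, t)
    }
    out
  }
  for (i in seq_along(nodes)) {
    dist <- bfs_dist(nodes[i])
    for (j in seq_along(nodes)) {
      if (i >= j || !is.finite(dist[nodes[j]])) next
      ps <- all_paths(nodes[i], nodes[j], dist)
      for (p in ps) {
        for (k in seq_len(length(p) - 1)) {
          eb[ekey(p[k], p[k + 1])] <- eb[ekey(p[k], p[k + 1])] + 1 / length(ps)
        }
      }
    }
  }
  eb
}

# Full hypergeometric enumeration of the two-sided Fisher exact p-value
# (probability-mass rule) for a 2x2 table (a, b; c, d).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Textbook Pearson correlation, written out long-hand.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small synthetic screen_counts fixture built directly from a count
# matrix for one cell line: first column T0, remaining columns tumours.
make_screen_fixture <- function(counts, genes_per_shrna) {
  n_rep <- ncol(counts) - 1L
  colnames(counts) <- c("L_T0", sprintf("L_tumor%d", seq_len(n_rep)))
  rownames(counts) <- sprintf("sh%02d", seq_len(nrow(counts)))
  screen_counts(
    counts,
    stats::setNames(genes_per_shrna, rownames(counts)),
    data.frame(sample_id = colnames(counts), cell_line = "L",
               timepoint = c("T0", rep("tumor", n_rep)),
               replicate = 0:n_rep, stringsAsFactors = FALSE)
  )
}
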
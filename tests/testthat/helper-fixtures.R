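# Small builders shared across test files.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# two-node single-edge network A-B
two_node_net <- function() ppi_network("A", "B")

# path graph A-B-C
path_net <- function() ppi_network(c("A", "B"), c("B", "C"))

# Erdos-Renyi ppi_network over n nodes with edge probability p
random_net <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("N%03d", seq_len(n))
  ppi_network(ids[el[, 1]], ids[el[, 2]], nodes = ids)
}

# uniform random scores aligned to a network, given provenance
random_abs_scores <- function(net, seed) {
  set.seed(seed)
  gene_scores(runif(length(net$nodes)), net$nodes, provenance = "absolute")
}

# independent brute-force step-up BH (oracle for bh_adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# independent brute-force preranked running sum (oracle for running-sum ES):
# walks every position explicitly and tracks the extreme deviation.
es_oracle <- function(ranked_scores, member_flags, weight) {
  N <- length(ranked_scores)
  m <- sum(member_flags)
  w <- abs(ranked_scores)^weight
  nr <- sum(w[member_flags])
  running <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (member_flags[i]) {
      running <- running + (if (nr > 0) w[i] / nr else 1 / m)
    } else {
      running <- running - 1 / (N - m)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}
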
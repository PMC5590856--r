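# Independent oracles used to verify the implementation, deliberately
# written by the dumbest correct route (brute force / triple loops).

# Floyd-Warshall all-pairs shortest paths on 1-based index edges.
fw_distances <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]
    j <- edges[r, 2]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Union-find: is the edge set a forest (acyclic)?
is_forest <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1])
    b <- find(edges[r, 2])
    if (a == b) return(FALSE)
    parent[a] <- b
  }
  TRUE
}

# Random connected graph: random spanning tree plus `extra` random edges.
# Node identifiers sort lexicographically in index order.
random_connected_net <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  tree <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L),
                            integer(1)))
  pool <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  more <- pool[sample.int(nrow(pool), min(extra, nrow(pool))), ,
               drop = FALSE]
  e <- rbind(tree, more)
  ppi_network(cbind(ids[e[, 1]], ids[e[, 2]]))
}

# Mann-Whitney AUC by explicit all-pairs comparison (ties count 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A small fixed tree with varied degrees (star chained to a path), used to
# exercise all probability bands of the evolutionary models.
varied_tree <- function() {
  pairs <- cbind(
    c("H", "H", "H", "H", "A", "B", "C", "D", "E"),
    c("A", "B", "C", "D", "E", "F", "G", "I", "J")
  )
  ppi_network(pairs)
}
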
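#' Random geometric network in the unit hypercube
#'
#' Drops `n` points uniformly in the `geo_dim`-dimensional unit hypercube
#' and connects every pair at Euclidean distance at most `radius`.
#' Interaction networks are hypothesized to have exactly this geometric
#' random structure, which is what makes geometric embedding predictive;
#' the generator therefore provides the canonical favourable fixture for
#' the pipeline. Latent coordinates are returned for diagnostics.
#'
#' @param n number of nodes (>= 2).
#' @param geo_dim latent space dimension (default 2).
#' @param radius connection radius (>= 0).
#' @param seed integer seed.
#' @return A [ppi_network()] with a `latent_coords` attribute (`n x
#'   geo_dim` matrix, rows in canonical node order).
#' @export
random_geometric_network <- function(n, geo_dim = 2L, radius, seed = 1L) {
  stopifnot(is_count(n), n >= 2, is_count(geo_dim), geo_dim >= 1)
  if (radius < 0) stop("`radius` must be nonnegative")
  pts <- with_seed(seed, matrix(stats::runif(n * geo_dim), n, geo_dim))
  dm <- as.matrix(stats::dist(pts))
  edges <- which(upper.tri(dm) & dm <= radius, arr.ind = TRUE)
  ids <- sprintf("P%05d", seq_len(n))
  net <- new_ppi_network(ids, canonical_edges(edges))
  attr(net, "latent_coords") <- pts
  net
}

#' Simulate a duplication-divergence network
#'
#' Forward growth model of the mechanism the evolutionary distance models
#' invert: starting from a triangle, a uniformly chosen target node is
#' duplicated; the duplicate retains each of the target's interactions
#' with probability `retain_p` (divergence), links back to its parent
#' with probability `parent_p`, and with probability `neo_p` gains one
#' neofunctionalized interaction with a partner chosen proportionally to
#' degree (scale-free preference). Duplicates that end up isolated are
#' discarded and growth continues until exactly `n` nodes are present.
#'
#' @param n target node count (>= 3).
#' @param retain_p probability a parent edge is retained (default 0.5).
#' @param parent_p probability of a duplicate-parent edge (default 0.3).
#' @param neo_p probability of one degree-preferring new edge
#'   (default 0.1).
#' @param seed integer seed.
#' @return A [ppi_network()] with `n` nodes.
#' @export
simulate_duplication_divergence <- function(n, retain_p = 0.5,
                                            parent_p = 0.3, neo_p = 0.1,
                                            seed = 1L) {
  stopifnot(is_count(n), n >= 3,
            retain_p >= 0, retain_p <= 1, parent_p >= 0, parent_p <= 1,
            neo_p >= 0, neo_p <= 1)
  with_seed(seed, {
    adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))  # seed triangle
    while (length(adj) < n) {
      parent <- sample.int(length(adj), 1L)
      nb <- adj[[parent]]
      kept <- nb[stats::runif(length(nb)) < retain_p]
      if (stats::runif(1L) < parent_p) kept <- c(kept, parent)
      if (stats::runif(1L) < neo_p) {
        deg <- lengths(adj)
        cand <- setdiff(seq_along(adj), c(kept, parent))
        if (length(cand) > 0L) {
          pick <- cand[sample.int(length(cand), 1L, prob = deg[cand])]
          kept <- c(kept, pick)
        }
      }
      kept <- unique(kept)
      if (length(kept) == 0L) next  # isolated duplicate: discard
      new_id <- length(adj) + 1L
      adj[[new_id]] <- kept
      for (v in kept) adj[[v]] <- c(adj[[v]], new_id)
    }
    edges <- do.call(rbind, lapply(seq_along(adj), function(v) {
      up <- adj[[v]][adj[[v]] > v]
      if (length(up) == 0L) NULL else cbind(v, up)
    }))
    new_ppi_network(sprintf("D%05d", seq_len(n)), canonical_edges(edges))
  })
}

#' Small worked-example network with hand-computed intermediates
#'
#' A fixed six-node network whose maximum connected component has five
#' nodes A-E: a path A-B-C-D-E plus the chord A-C, with F isolated. Using
#' the path as spanning tree, the component exhibits every model regime:
#' adjacent pairs, duplication-band pairs at distance 2-3, and one
#' neofunctionalization-band pair (A, E) at distance 4. The shortest-path
#' matrix and per-pair DANEOsf collapse probabilities (alpha = 0.3) were
#' computed by hand and ship as reference values.
#'
#' @return List with `net` (6-node [ppi_network()]), `component` (the
#'   5-node component), `mst` (the path spanning tree as an edge matrix),
#'   `sp` (5 x 5 shortest-path matrix for that tree) and `daneosf_probs`
#'   (5 x 5 matrix of collapse probabilities at alpha = 0.3).
#' @export
toy_fixture <- function() {
  net <- ppi_network(cbind(c("A", "B", "C", "D", "A"),
                           c("B", "C", "D", "E", "C")),
                     nodes = "F")
  component <- max_connected_component(net)
  mst <- canonical_edges(cbind(1:4, 2:5))  # path A-B-C-D-E
  sp <- abs(outer(1:5, 1:5, "-"))
  storage.mode(sp) <- "double"
  # degrees on the path: 1,2,2,2,1; max degree 2
  # SP in {2,3} -> 0.3; SP = 4 (pair A,E) -> (1*1/2^2)^4 = 1/256
  p <- matrix(0, 5, 5)
  p[sp == 1] <- 1
  p[sp == 2 | sp == 3] <- 0.3
  p[1, 5] <- p[5, 1] <- (1 / 4)^4
  list(net = net, component = component, mst = mst, sp = sp,
       daneosf_probs = p)
}
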
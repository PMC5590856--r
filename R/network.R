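#' Construct a protein-protein interaction network
#'
#' Builds a simple undirected graph from pairs of node identifiers.
#' Self-loops are dropped and duplicate pairs (in either order) are
#' collapsed, so the result satisfies the adjacency convention
#' \eqn{a_{ij} = 1} iff \eqn{(i,j)} is an edge and \eqn{a_{ii} = 0}.
#' Node indices are assigned by lexicographic (C-locale) sort of the
#' identifiers, which makes indexing deterministic across runs.
#'
#' @param pairs two-column character matrix or data frame of interacting
#'   node identifiers, one interaction per row.
#' @param nodes optional character vector of additional node identifiers
#'   (e.g. isolated proteins) to include in the node set.
#' @return An object of class `ppi_network`: a list with `node_ids`
#'   (canonically ordered identifiers), `edges` (integer matrix of index
#'   pairs, each row `i < j`), `n` (node count) and `m_edges` (edge count).
#' @examples
#' net <- ppi_network(cbind(c("A", "B"), c("B", "C")))
#' net$n
#' @export
ppi_network <- function(pairs, nodes = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) {
    stop("`pairs` must have exactly two columns of node identifiers")
  }
  storage.mode(pairs) <- "character"
  node_ids <- sort(unique(c(as.vector(pairs), as.character(nodes))),
                   method = "radix")
  if (length(node_ids) == 0L) stop("empty network: no nodes")
  idx <- matrix(match(pairs, node_ids), ncol = 2L)
  keep <- idx[, 1L] != idx[, 2L]
  edges <- canonical_edges(idx[keep, , drop = FALSE])
  new_ppi_network(node_ids, edges)
}

new_ppi_network <- function(node_ids, edges) {
  structure(
    list(node_ids = node_ids, edges = edges,
         n = length(node_ids), m_edges = nrow(edges)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n", x$n, x$m_edges))
  invisible(x)
}

#' Adjacency matrix of a network
#'
#' Dense 0/1 adjacency matrix with zero diagonal; rows and columns follow
#' the canonical node order.
#'
#' @param net a [ppi_network()].
#' @return An `n x n` integer matrix.
#' @export
adjacency_matrix <- function(net) {
  a <- matrix(0L, net$n, net$n, dimnames = list(net$node_ids, net$node_ids))
  a[net$edges] <- 1L
  a[net$edges[, 2:1, drop = FALSE]] <- 1L
  a
}

# igraph view of a network; vertex order matches canonical node order.
as_igraph <- function(net) {
  igraph::make_graph(t(net$edges), n = net$n, directed = FALSE)
}

#' Parse an interaction file into a network
#'
#' Reads either a generic two-column edge list (`dialect = "tsv"`, columns
#' separated by any whitespace, lines starting with `#` ignored) or a
#' MITAB-style tab-separated interaction file (`dialect = "mitab"`, raw
#' interactor identifiers taken from columns 1 and 2, the header line
#' starting with `#` ignored). Self-loops are dropped and duplicate pairs
#' collapsed; the counts are reported via [message()] and attached as the
#' `parse_stats` attribute.
#'
#' @param path path to the interaction file.
#' @param dialect `"tsv"` or `"mitab"`.
#' @return A [ppi_network()] with a `parse_stats` attribute
#'   (`lines_read`, `self_loops_dropped`, `duplicates_collapsed`).
#' @export
parse_edge_list <- function(path, dialect = c("tsv", "mitab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read interaction file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no interaction records in ", path)
  fields <- if (dialect == "tsv") {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, "\t", fixed = TRUE)
  }
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("line %d of %s has fewer than 2 columns",
                 line_no[which(nf < 2L)[1L]], path))
  }
  pairs <- cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
  n_loop <- sum(pairs[, 1L] == pairs[, 2L])
  net <- ppi_network(pairs)
  n_dup <- nrow(pairs) - n_loop - net$m_edges
  message(sprintf(
    "parsed %s: %d interaction lines, %d self-loops dropped, %d duplicates collapsed",
    basename(path), length(lines), n_loop, n_dup))
  attr(net, "parse_stats") <- list(lines_read = length(lines),
                                   self_loops_dropped = n_loop,
                                   duplicates_collapsed = n_dup)
  net
}

#' Write a network as a two-column TSV edge list
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @param origin optional character vector (one per edge) written as a third
#'   column, e.g. the evolutionary origin flags of an evolved network.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, origin = NULL) {
  df <- data.frame(a = net$node_ids[net$edges[, 1L]],
                   b = net$node_ids[net$edges[, 2L]])
  if (!is.null(origin)) {
    stopifnot(length(origin) == net$m_edges)
    df$origin <- origin
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the maximum connected component
#'
#' Real interaction networks are typically disconnected; embedding requires
#' finite pairwise distances, so only the largest connected component is
#' analysed. Ties in component size are broken by the component containing
#' the lexicographically smallest node identifier.
#'
#' @param net a [ppi_network()].
#' @return The induced subgraph on the largest component, as a
#'   [ppi_network()] with canonically re-indexed nodes.
#' @export
max_connected_component <- function(net) {
  if (net$n == 0L) stop("empty network")
  comp <- igraph::components(as_igraph(net))
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  # membership follows canonical node order, so the first node whose
  # component is a candidate identifies the lexicographically smallest id
  first_node <- which(comp$membership %in% cand)[1L]
  pick <- comp$membership[first_node]
  in_comp <- comp$membership == pick
  keep_ids <- net$node_ids[in_comp]
  remap <- match(seq_len(net$n), which(in_comp))
  e <- net$edges
  on_comp <- in_comp[e[, 1L]] & in_comp[e[, 2L]]
  new_ppi_network(keep_ids,
                  canonical_edges(cbind(remap[e[on_comp, 1L]],
                                        remap[e[on_comp, 2L]])))
}

is_connected_net <- function(net) {
  net$n == 1L || (net$m_edges >= net$n - 1L &&
                  igraph::is_connected(as_igraph(net)))
}

#' Draw a random minimum spanning tree
#'
#' All edges carry equal weight 1, so every spanning tree is minimal and the
#' MST is not unique. A randomised Prim traversal is used: starting from a
#' seeded random node, each step adds a uniformly random edge from the cut
#' between the tree and the rest of the graph. A fixed seed reproduces the
#' tree exactly; different seeds yield different valid trees, which is what
#' repeated cross-validation experiments rely on.
#'
#' @param net a connected [ppi_network()].
#' @param seed integer seed controlling tie-breaking.
#' @return Integer edge matrix with `n - 1` rows in canonical order.
#' @export
minimum_spanning_tree <- function(net, seed = 1L) {
  if (!is_connected_net(net)) {
    stop("network is disconnected; extract max_connected_component() first")
  }
  n <- net$n
  if (n == 1L) return(canonical_edges(matrix(integer(0), ncol = 2L)))
  e <- net$edges
  with_seed(seed, {
    in_tree <- logical(n)
    in_tree[sample.int(n, 1L)] <- TRUE
    chosen <- matrix(0L, n - 1L, 2L)
    for (s in seq_len(n - 1L)) {
      cut <- xor(in_tree[e[, 1L]], in_tree[e[, 2L]])
      idx <- which(cut)
      pick <- idx[sample.int(length(idx), 1L)]
      chosen[s, ] <- e[pick, ]
      in_tree[e[pick, 1L]] <- TRUE
      in_tree[e[pick, 2L]] <- TRUE
    }
    canonical_edges(chosen)
  })
}

#' Restrict a network to a subset of its edges
#'
#' Same node set, given edges only; used e.g. to materialize the MST as a
#' network for [mst_context()].
#'
#' @param net a [ppi_network()].
#' @param edges integer edge matrix.
#' @return A [ppi_network()].
#' @export
subnetwork <- function(net, edges) {
  new_ppi_network(net$node_ids, canonical_edges(edges))
}

#' Split a network into MST training edges and held-out test edges
#'
#' The spanning tree is the training sub-network; every other edge of the
#' component is reserved for testing, and every unordered non-tree pair is
#' a candidate interaction, so `n_candidates = n(n-1)/2 - (n-1)`.
#'
#' @param net a connected [ppi_network()].
#' @param mst edge matrix from [minimum_spanning_tree()].
#' @return An object of class `ppi_split`: list with `trn_edges`,
#'   `tst_edges`, `n_candidates` and `n`.
#' @export
split_train_test <- function(net, mst) {
  mst <- canonical_edges(mst)
  keys <- pair_key(net$edges, net$n)
  mkeys <- pair_key(mst, net$n)
  if (!all(mkeys %in% keys)) {
    stop("MST contains edges absent from the network")
  }
  if (nrow(mst) != net$n - 1L ||
      igraph::components(igraph::make_graph(t(mst), n = net$n,
                                            directed = FALSE))$no != 1L) {
    stop("`mst` is not a spanning tree of the network")
  }
  tst <- net$edges[!(keys %in% mkeys), , drop = FALSE]
  structure(
    list(trn_edges = mst, tst_edges = tst,
         n_candidates = net$n * (net$n - 1) / 2 - nrow(mst),
         n = net$n),
    class = "ppi_split"
  )
}

#' @export
print.ppi_split <- function(x, ...) {
  cat(sprintf("<ppi_split> %d train (MST), %d test, %s candidate pairs\n",
              nrow(x$trn_edges), nrow(x$tst_edges),
              format(x$n_candidates, big.mark = ",")))
  invisible(x)
}
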
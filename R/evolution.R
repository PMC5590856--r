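#' All-pairs shortest-path distance matrix
#'
#' Unweighted shortest paths (minimum edge counts) between every node pair,
#' computed by breadth-first search from each source. This matrix is both
#' the "minimum curvilinearity" baseline distance (when computed on the
#' MST) and the substrate for the evolutionary distance models.
#'
#' @param net a connected [ppi_network()].
#' @return A symmetric `n x n` numeric matrix with zero diagonal.
#' @export
all_pairs_shortest_path <- function(net) {
  d <- igraph::distances(as_igraph(net), algorithm = "unweighted")
  if (any(is.infinite(d))) {
    stop("network is disconnected: infinite distances cannot be embedded")
  }
  dimnames(d) <- NULL
  d
}

#' Static context of a minimum spanning tree
#'
#' Precomputes the quantities the evolutionary models are defined on:
#' shortest paths within the MST, node degrees in the MST, and the maximum
#' MST degree. All model probabilities are evaluated against this frozen
#' context; degrees are never updated as evolved edges accrue.
#'
#' @param mst_net the MST as a [ppi_network()] (same nodes, tree edges).
#' @return An object of class `mst_context`: list with `sp` (distance
#'   matrix), `deg` (integer degrees) and `max_deg`.
#' @export
mst_context <- function(mst_net) {
  if (mst_net$m_edges != mst_net$n - 1L) {
    stop("`mst_net` must be a spanning tree (n - 1 edges)")
  }
  deg <- tabulate(mst_net$edges, nbins = mst_net$n)
  structure(
    list(sp = all_pairs_shortest_path(mst_net), deg = deg,
         max_deg = max(deg)),
    class = "mst_context"
  )
}

#' Evolutionary model parameters
#'
#' @param model `"daneosf"` (duplication/neofunctionalization with a
#'   scale-free degree preference), `"lpa"` (linear preferential
#'   attachment) or `"rm"` (random mutation).
#' @param alpha duplication probability for node pairs at MST distance 2
#'   or 3 (DANEOsf); default 0.3.
#' @param beta mutation probability for any non-adjacent pair (RM);
#'   default 0.15.
#' @param mode `"evolved"` (default): shortest paths are recomputed on the
#'   evolved graph, so an added edge can shorten third-party distances;
#'   `"literal"`: each pair keeps either 1 (on Bernoulli success) or its
#'   original MST distance, exactly the branch values of the model
#'   definitions.
#' @param seed integer seed for the Bernoulli draws.
#' @return An object of class `evo_params`.
#' @export
evo_params <- function(model = c("daneosf", "lpa", "rm"), alpha = 0.3,
                       beta = 0.15, mode = c("evolved", "literal"),
                       seed = 1L) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1,
            is.numeric(beta), beta >= 0, beta <= 1)
  structure(list(model = model, alpha = alpha, beta = beta, mode = mode,
                 seed = as.integer(seed)),
            class = "evo_params")
}

#' Probability that an evolved pair collapses to distance 1
#'
#' Implements the three evolutionary distance models on a frozen MST
#' context. Writing `SP` for the MST shortest path, `deg` for MST degrees
#' and `D` for the maximum MST degree:
#' \describe{
#'   \item{daneosf}{1 if `SP = 1`; `alpha` (duplication/divergence) if
#'     `SP` is 2 or 3; `(deg(i) deg(j) / D^2)^SP` (degree-preferring
#'     neofunctionalization) if `SP > 3`.}
#'   \item{lpa}{1 if `SP = 1`; `0.5 deg(i) deg(j) / D^2` otherwise.}
#'   \item{rm}{1 if `SP = 1`; `beta` otherwise.}
#' }
#' Since `deg <= D`, every value lies in `[0, 1]`.
#'
#' @param sp shortest-path distance(s) in the MST (vectorized).
#' @param deg_i,deg_j MST degrees of the endpoints (vectorized).
#' @param max_deg maximum MST degree.
#' @param model,alpha,beta see [evo_params()].
#' @return Numeric vector of probabilities.
#' @export
edge_probability <- function(sp, deg_i, deg_j, max_deg,
                             model = c("daneosf", "lpa", "rm"),
                             alpha = 0.3, beta = 0.15) {
  model <- match.arg(model)
  ratio <- (deg_i * deg_j) / max_deg^2
  p <- switch(model,
    daneosf = ifelse(sp <= 1, 1, ifelse(sp <= 3, alpha, ratio^sp)),
    lpa     = ifelse(sp <= 1, 1, 0.5 * ratio),
    rm      = ifelse(sp <= 1, 1, beta)
  )
  as.numeric(p)
}

#' Full matrix of collapse probabilities on an MST context
#'
#' Evaluates [edge_probability()] for every node pair of the frozen MST
#' context; the diagonal is set to 0.
#'
#' @param ctx an [mst_context()].
#' @param params an [evo_params()] (or just a model name with default
#'   parameters).
#' @return Symmetric `n x n` probability matrix.
#' @export
edge_probability_matrix <- function(ctx, params) {
  if (is.character(params)) params <- evo_params(params)
  n <- length(ctx$deg)
  p <- edge_probability(ctx$sp, outer(ctx$deg, rep(1, n)),
                        outer(rep(1, n), ctx$deg), ctx$max_deg,
                        model = params$model, alpha = params$alpha,
                        beta = params$beta)
  p <- matrix(p, n, n)
  diag(p) <- 0
  p
}

#' Sample the evolved training network
#'
#' For every unordered non-adjacent pair of the MST, one Bernoulli draw is
#' made with [edge_probability()]; a success adds the edge ("elementary
#' prediction"). All probabilities are evaluated against the static
#' original MST, MST edges are always retained, and a fixed seed
#' reproduces the evolved graph exactly.
#'
#' @param mst_net the MST as a [ppi_network()].
#' @param ctx [mst_context()] of `mst_net`.
#' @param params [evo_params()].
#' @return A [ppi_network()] with an extra `edge_origin` field labelling
#'   each edge `"mst"`, `"duplication"`, `"neofunctionalization"` (DANEOsf
#'   bands), `"attachment"` (LPA) or `"mutation"` (RM).
#' @export
sample_evolved_network <- function(mst_net, ctx, params) {
  n <- mst_net$n
  p <- edge_probability_matrix(ctx, params)
  ut <- upper.tri(p)
  cand <- which(ut & ctx$sp > 1, arr.ind = TRUE)
  pc <- p[cand]
  hit <- with_seed(params$seed, stats::runif(length(pc)) < pc)
  added <- cand[hit, , drop = FALSE]
  edges <- canonical_edges(rbind(mst_net$edges, added))
  origin <- rep("mst", nrow(edges))
  if (nrow(added) > 0L) {
    akey <- pair_key(canonical_edges(added), n)
    pos <- match(akey, pair_key(edges, n))
    origin[pos] <- switch(params$model,
      daneosf = ifelse(ctx$sp[canonical_edges(added)] <= 3,
                       "duplication", "neofunctionalization"),
      lpa = "attachment",
      rm = "mutation")
  }
  out <- new_ppi_network(mst_net$node_ids, edges)
  out$edge_origin <- origin
  out
}

#' Evolutionary distance matrix of the evolved training sub-network
#'
#' Samples the evolved network under the chosen model and returns its
#' pairwise distance matrix. In `"evolved"` mode (default) shortest paths
#' are recomputed on the evolved graph; in `"literal"` mode each sampled
#' pair is set to 1 and every other pair keeps its MST shortest path.
#' Either way the evolved edge set is returned alongside, since the added
#' edges are themselves elementary interaction predictions.
#'
#' @inheritParams sample_evolved_network
#' @return List with `dist` (symmetric distance matrix) and `evolved`
#'   (the evolved [ppi_network()] with `edge_origin`).
#' @export
evolutionary_distance_matrix <- function(mst_net, ctx, params) {
  evolved <- sample_evolved_network(mst_net, ctx, params)
  if (params$mode == "literal") {
    d <- ctx$sp
    add <- evolved$edges[evolved$edge_origin != "mst", , drop = FALSE]
    if (nrow(add) > 0L) {
      d[add] <- 1
      d[add[, 2:1, drop = FALSE]] <- 1
    }
  } else {
    d <- all_pairs_shortest_path(evolved)
  }
  list(dist = d, evolved = evolved)
}
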
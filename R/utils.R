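# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Scalar key for an unordered pair (i < j) on n nodes; doubles are exact up to
# 2^53 so this is safe far beyond any network size handled here.
pair_key <- function(edges, n) {
  (as.numeric(edges[, 1L]) - 1) * n + as.numeric(edges[, 2L])
}

# Canonicalize an edge matrix: each row i < j, rows sorted by (i, j), no
# duplicates. Input may be empty.
canonical_edges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}
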
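#' Double-center a distance matrix
#'
#' Converts a squared-distance matrix to an inner-product (Gram) matrix:
#' \eqn{A = -\frac{1}{2} J D^{(2)} J} with \eqn{J = I - n^{-1} 1 1'},
#' where \eqn{D^{(2)}} is the entrywise square of `d`. Row and column sums
#' of the result are zero (the centering matrix annihilates constants).
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return Symmetric matrix of the same size.
#' @export
double_center <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
    stop("`d` must be a symmetric square matrix")
  }
  d2 <- d * d
  rmu <- rowMeans(d2)
  a <- -0.5 * (sweep(sweep(d2, 1L, rmu), 2L, rmu) + mean(d2))
  (a + t(a)) / 2
}

new_embedding <- function(coords, spectrum, backend, extra = NULL) {
  structure(c(list(coords = coords, spectrum = spectrum, backend = backend,
                   dim = ncol(coords)), extra),
            class = "ede_embedding")
}

#' @export
print.ede_embedding <- function(x, ...) {
  cat(sprintf("<ede_embedding> %d nodes in %d dimensions (%s)\n",
              nrow(x$coords), x$dim, x$backend))
  invisible(x)
}

# Deterministic sign convention: each coordinate column's largest-magnitude
# entry is made positive. For the SVD backend the matching right singular
# vectors are flipped in step so U S V' is preserved.
fix_column_signs <- function(u, v = NULL) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (length(i) && u[i, j] < 0) {
      u[, j] <- -u[, j]
      if (!is.null(v)) v[, j] <- -v[, j]
    }
  }
  if (is.null(v)) u else list(u = u, v = v)
}

#' Classical multidimensional scaling (Isomap) embedding
#'
#' Embeds a distance matrix into an `m`-dimensional geometric space:
#' double-center the squared distances, take the `m` algebraically largest
#' eigenpairs of the Gram matrix, and set coordinates
#' \eqn{X = E_m \Lambda_m^{1/2}}. Applied to graph shortest-path distances
#' this is the Isomap recipe. Graph distances are generally non-Euclidean,
#' so retained negative eigenvalues are clamped to zero before the square
#' root (their coordinate columns are zero). Column signs follow a fixed
#' convention so the embedding is deterministic.
#'
#' @param d symmetric distance matrix.
#' @param m target dimension, `1 <= m <= n - 1`.
#' @return An `ede_embedding` with `coords` (`n x m`) and `spectrum`
#'   (the `m` retained eigenvalues, descending, unclamped).
#' @export
embed_mds <- function(d, m = 5L) {
  n <- nrow(as.matrix(d))
  if (!is_count(m) || m < 1L || m > n - 1L) {
    stop("`m` must be an integer in [1, n - 1]")
  }
  m <- as.integer(m)
  a <- double_center(d)
  eig <- eigen(a, symmetric = TRUE)
  vals <- eig$values[seq_len(m)]
  vecs <- eig$vectors[, seq_len(m), drop = FALSE]
  coords <- fix_column_signs(vecs) %*% diag(sqrt(pmax(vals, 0)), m, m)
  new_embedding(coords, vals, "mds")
}

#' Non-centered SVD embedding
#'
#' Singular value decomposition of the distance matrix itself, with no
#' centering step: coordinates \eqn{X = U_m \Sigma_m^{1/2}}. This is the
#' backend behind non-centered minimum-curvilinearity style embeddings,
#' which on some networks outperform classical MDS.
#'
#' @inheritParams embed_mds
#' @return An `ede_embedding` with `coords`, `spectrum` (the `m` largest
#'   singular values, non-increasing) and `v` (matching right singular
#'   vectors, for low-rank reconstruction).
#' @export
embed_ncsvd <- function(d, m = 5L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is_count(m) || m < 1L || m > n - 1L) {
    stop("`m` must be an integer in [1, n - 1]")
  }
  m <- as.integer(m)
  s <- svd(d, nu = m, nv = m)
  uv <- fix_column_signs(s$u, s$v)
  coords <- uv$u %*% diag(sqrt(s$d[seq_len(m)]), m, m)
  new_embedding(coords, s$d[seq_len(m)], "ncsvd", extra = list(v = uv$v))
}

#' Euclidean distances between embedded node pairs
#'
#' @param emb an `ede_embedding`.
#' @param pairs two-column integer matrix of node index pairs.
#' @return Numeric vector of Euclidean distances, one per row of `pairs`.
#' @export
pairwise_euclidean <- function(emb, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  n <- nrow(emb$coords)
  if (nrow(pairs) == 0L) return(numeric(0))
  if (any(pairs < 1L) || any(pairs > n)) stop("node index out of range")
  diff <- emb$coords[pairs[, 1L], , drop = FALSE] -
    emb$coords[pairs[, 2L], , drop = FALSE]
  sqrt(rowSums(diff^2))
}

#' Full matrix of embedded Euclidean distances
#'
#' @param emb an `ede_embedding`.
#' @return Symmetric `n x n` matrix of pairwise Euclidean distances.
#' @export
euclidean_matrix <- function(emb) {
  as.matrix(stats::dist(emb$coords))
}
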
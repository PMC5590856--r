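#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Standard expectation-maximization for a `k`-component univariate
#' Gaussian mixture with maximum-likelihood (1/N-weighted) variances.
#' Component means are initialized at equally spaced sample quantiles with
#' a small seeded jitter, all variances at the pooled ML variance and
#' weights at `1/k`. Iteration stops when the log-likelihood improvement
#' drops below `tol` or after `max_iter` iterations; a variance floor
#' prevents component collapse onto single points.
#'
#' @param x numeric sample (distances).
#' @param k number of Gaussian components (default 3).
#' @param seed integer seed for the initialization jitter.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param var_floor lower bound on component variances (default 1e-6).
#' @return An object of class `gmm1d`: list with `k`, `weights`, `means`,
#'   `variances`, `loglik` (per-iteration trace), `n_iter`, `converged`.
#' @export
fit_gmm_em <- function(x, k = 3L, seed = 1L, max_iter = 500L, tol = 1e-8,
                       var_floor = 1e-6) {
  if (!is_count(k) || k < 1L) stop("`k` must be a positive integer")
  k <- as.integer(k)
  x <- as.numeric(x)
  if (length(unique(x)) < k) {
    stop("need at least `k` distinct sample values to fit ", k,
         " components")
  }
  n <- length(x)
  pooled <- max(mean((x - mean(x))^2), var_floor)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  mu <- with_seed(seed, mu + stats::rnorm(k, 0, sqrt(pooled) * 1e-3))
  sig2 <- rep(pooled, k)
  w <- rep(1 / k, k)

  loglik <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  lc <- matrix(0, n, k)
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step in log space for numerical stability
    for (i in seq_len(k)) {
      lc[, i] <- log(w[i]) + stats::dnorm(x, mu[i], sqrt(sig2[i]),
                                          log = TRUE)
    }
    lmax <- lc[, 1L]
    for (i in seq_len(k)[-1L]) lmax <- pmax(lmax, lc[, i])
    lse <- lmax + log(rowSums(exp(lc - lmax)))
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    resp <- exp(lc - lse)
    # M step (ML variance convention)
    nk <- pmax(colSums(resp), 1e-300)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (i in seq_len(k)) {
      sig2[i] <- max(sum(resp[, i] * (x - mu[i])^2) / nk[i], var_floor)
    }
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  ord <- order(mu)
  structure(
    list(k = k, weights = w[ord], means = mu[ord], variances = sig2[ord],
         loglik = loglik, n_iter = iter, converged = converged),
    class = "gmm1d"
  )
}

#' Gaussian mixture density
#'
#' @param x numeric vector of evaluation points.
#' @param mix a [fit_gmm_em()] model.
#' @return Mixture density values at `x`.
#' @export
dgmm <- function(x, mix) {
  d <- numeric(length(x))
  for (i in seq_len(mix$k)) {
    d <- d + mix$weights[i] * stats::dnorm(x, mix$means[i],
                                           sqrt(mix$variances[i]))
  }
  d
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("<gmm1d> %d components; means %s\n", x$k,
              paste(signif(x$means, 4), collapse = ", ")))
  invisible(x)
}

#' Fit edge and non-edge distance densities
#'
#' Learns the two class-conditional densities of embedded Euclidean
#' distance: `p(dist | edge)` is fitted on the distances of the training
#' (MST) edges only, preserving cross-validation hygiene; `p(dist |
#' nonedge)` is fitted on a seeded uniform sample of unordered pairs that
#' are not edges of the evolved training network (all such pairs if fewer
#' than `nonedge_sample`). The class prior `p(edge)` defaults to the
#' training-graph density `2(n-1) / (n(n-1))`, the fraction of edges
#' observable in the training network.
#'
#' @param emb `ede_embedding` covering all component nodes.
#' @param split [split_train_test()] result.
#' @param evolved_edges edge matrix of the evolved training network (its
#'   pairs are excluded from the non-edge sample); defaults to the MST
#'   edges alone.
#' @param k Gaussian components per mixture (default 3, matching the at
#'   most three modes seen in distance histograms).
#' @param nonedge_sample non-edge pairs to sample (default 100000).
#' @param seed integer seed for sampling and EM initialization.
#' @param p_edge optional prior override in (0, 1).
#' @return An object of class `density_model`: list with `edge_mix`,
#'   `nonedge_mix`, `p_edge`, `p_nonedge`.
#' @export
fit_density_model <- function(emb, split, evolved_edges = NULL, k = 3L,
                              nonedge_sample = 1e5, seed = 1L,
                              p_edge = NULL) {
  n <- split$n
  if (nrow(emb$coords) != n) stop("embedding does not cover all nodes")
  if (nonedge_sample < k) stop("`nonedge_sample` must be at least `k`")
  if (is.null(evolved_edges)) evolved_edges <- split$trn_edges
  edge_d <- pairwise_euclidean(emb, split$trn_edges)
  ne_pairs <- sample_nonedge_pairs(n, canonical_edges(evolved_edges),
                                   nonedge_sample, seed)
  nonedge_d <- pairwise_euclidean(emb, ne_pairs)
  if (is.null(p_edge)) p_edge <- 2 * (n - 1) / (n * (n - 1))
  stopifnot(p_edge > 0, p_edge < 1)
  structure(
    list(edge_mix = fit_gmm_em(edge_d, k = k, seed = seed + 1L),
         nonedge_mix = fit_gmm_em(nonedge_d, k = k, seed = seed + 2L),
         p_edge = p_edge, p_nonedge = 1 - p_edge),
    class = "density_model"
  )
}

# Seeded uniform sample of unordered pairs outside `exclude` (canonical
# edge matrix). Enumerates when the pair universe is small; otherwise
# rejection-samples pair keys, which is efficient because excluded pairs
# are a vanishing fraction of all pairs in sparse networks.
sample_nonedge_pairs <- function(n, exclude, size, seed) {
  total <- n * (n - 1) / 2
  n_free <- total - nrow(exclude)
  ex_keys <- pair_key(exclude, n)
  key_to_pair <- function(keys) {
    i <- floor((keys - 1) / n) + 1
    cbind(as.integer(i), as.integer(keys - (i - 1) * n))
  }
  if (n_free <= size || total <= 2e6) {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keys <- pair_key(ut, n)
    free <- keys[!(keys %in% ex_keys)]
    picked <- if (length(free) <= size) free else {
      with_seed(seed, sample(free, size))
    }
    return(key_to_pair(sort(picked)))
  }
  with_seed(seed, {
    picked <- numeric(0)
    while (length(picked) < size) {
      draw <- ceiling(stats::runif(2L * (size - length(picked))) * total)
      # map linear upper-triangle rank to (i, j) key
      j <- floor((1 + sqrt(8 * draw - 7)) / 2) + 1
      # adjust for floating point at triangle boundaries
      base <- (j - 1) * (j - 2) / 2
      bad <- draw <= base
      j[bad] <- j[bad] - 1
      base <- (j - 1) * (j - 2) / 2
      i <- draw - base
      keys <- (i - 1) * n + j
      keys <- keys[!(keys %in% ex_keys)]
      picked <- unique(c(picked, keys))
    }
    key_to_pair(sort(picked[seq_len(size)]))
  })
}

#' Bayesian confidence score for candidate interactions
#'
#' Posterior-odds-normalized probability that a pair at embedded distance
#' `dist` is an interaction:
#' \deqn{S = \frac{p(d|e)\,p(e)}{p(d|e)\,p(e) + p(d|ne)\,p(ne)}}
#' which is Bayes' rule with the shared `p(dist)` denominator cancelled.
#' If both weighted densities underflow to zero the score is the
#' uninformative 0.5.
#'
#' @param model a [fit_density_model()] result.
#' @param dist nonnegative distance(s); vectorized.
#' @return Scores in `[0, 1]`.
#' @export
confidence_score <- function(model, dist) {
  a <- dgmm(dist, model$edge_mix) * model$p_edge
  b <- dgmm(dist, model$nonedge_mix) * model$p_nonedge
  s <- a / (a + b)
  s[a + b == 0] <- 0.5
  s
}

#' Hard interaction prediction by distance threshold
#'
#' Predicts an interaction for every unordered non-training pair whose
#' embedded Euclidean distance is at most `epsilon`. Score ranking is the
#' recommended path; this thresholded variant is provided for
#' completeness.
#'
#' @param emb `ede_embedding`.
#' @param epsilon nonnegative distance threshold.
#' @param exclude edge matrix of pairs never predicted (typically the
#'   training MST edges); may be `NULL`.
#' @return Canonical edge matrix of predicted pairs.
#' @export
predict_by_threshold <- function(emb, epsilon, exclude = NULL) {
  stopifnot(epsilon >= 0)
  dm <- euclidean_matrix(emb)
  n <- nrow(dm)
  hit <- which(upper.tri(dm) & dm <= epsilon, arr.ind = TRUE)
  hit <- canonical_edges(hit)
  if (!is.null(exclude) && nrow(hit) > 0L) {
    hit <- hit[!(pair_key(hit, n) %in%
                   pair_key(canonical_edges(exclude), n)), , drop = FALSE]
  }
  hit
}
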
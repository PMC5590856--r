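#' Run one full prediction pass over a network
#'
#' End-to-end pipeline: extract the maximum connected component, draw a
#' seeded MST as the training sub-network, derive the distance matrix
#' (evolutionary model, or the MST shortest-path matrix for the
#' `"sp"` baseline), embed it, fit the edge/non-edge density model, score
#' every candidate pair with the Bayesian confidence, and evaluate the
#' ranking against the held-out test edges (or the whole network).
#'
#' @param net a [ppi_network()].
#' @param model `"daneosf"`, `"lpa"`, `"rm"`, or `"sp"` (the
#'   minimum-curvilinearity shortest-path baseline with no evolutionary
#'   step).
#' @param mode distance mode for evolutionary models, see [evo_params()].
#' @param backend `"mds"` or `"ncsvd"`, see [embed_mds()] /
#'   [embed_ncsvd()].
#' @param dim embedding dimension (default 5).
#' @param alpha,beta model parameters, see [evo_params()].
#' @param k mixture components, see [fit_density_model()].
#' @param nonedge_sample non-edge pairs sampled for the density fit.
#' @param seed integer seed driving the MST draw, the evolutionary
#'   sampling and the density fit.
#' @param eval_mode `"cross_validation"` (candidates are all non-MST
#'   pairs, positives the held-out test edges) or `"whole_network"`
#'   (candidates all pairs, positives all component edges).
#' @param keep_scores if `FALSE`, drop the per-pair score table from the
#'   result (saves memory on large networks).
#' @return An object of class `ede_run`: list with `eval` (an
#'   [evaluate_scores()] result), `scores` (data frame `node_i, node_j,
#'   euclidean_dist, confidence, label`, or `NULL`), `split`, `embedding`,
#'   `density_model`, `evolved` and `config`.
#' @examples
#' net <- random_geometric_network(80, radius = 0.2, seed = 1)
#' run <- ede_predict(net, model = "daneosf", seed = 1)
#' run$eval$auc_roc
#' @export
ede_predict <- function(net, model = c("daneosf", "lpa", "rm", "sp"),
                        mode = c("evolved", "literal"),
                        backend = c("mds", "ncsvd"), dim = 5L,
                        alpha = 0.3, beta = 0.15, k = 3L,
                        nonedge_sample = 1e5, seed = 1L,
                        eval_mode = c("cross_validation", "whole_network"),
                        keep_scores = TRUE) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  eval_mode <- match.arg(eval_mode)
  comp <- max_connected_component(net)
  mst <- minimum_spanning_tree(comp, seed = seed)
  split <- split_train_test(comp, mst)
  mst_net <- subnetwork(comp, mst)
  ctx <- mst_context(mst_net)
  if (model == "sp") {
    d <- ctx$sp
    evolved <- mst_net
  } else {
    params <- evo_params(model, alpha = alpha, beta = beta, mode = mode,
                         seed = seed)
    ed <- evolutionary_distance_matrix(mst_net, ctx, params)
    d <- ed$dist
    evolved <- ed$evolved
  }
  emb <- switch(backend, mds = embed_mds(d, dim), ncsvd = embed_ncsvd(d, dim))
  dmod <- fit_density_model(emb, split, evolved_edges = evolved$edges,
                            k = k, nonedge_sample = nonedge_sample,
                            seed = seed)
  sc <- score_candidates(emb, comp, split, dmod, eval_mode)
  res <- evaluate_scores(sc$scores, sc$labels, mode = eval_mode)
  scores_df <- NULL
  if (keep_scores) {
    scores_df <- data.frame(
      node_i = comp$node_ids[sc$pairs[, 1L]],
      node_j = comp$node_ids[sc$pairs[, 2L]],
      euclidean_dist = sc$dists, confidence = sc$scores,
      label = sc$labels)
    scores_df <- scores_df[order(-scores_df$confidence), ]
    rownames(scores_df) <- NULL
  }
  structure(
    list(eval = res, scores = scores_df, split = split, embedding = emb,
         density_model = dmod, evolved = evolved,
         config = list(model = model, mode = mode, backend = backend,
                       dim = dim, alpha = alpha, beta = beta, k = k,
                       nonedge_sample = nonedge_sample, seed = seed,
                       eval_mode = eval_mode)),
    class = "ede_run"
  )
}

#' @export
print.ede_run <- function(x, ...) {
  cat(sprintf("<ede_run> model %s (%s, %s, m=%d), seed %d\n",
              x$config$model, x$config$mode, x$config$backend,
              x$config$dim, x$config$seed))
  print(x$eval)
  invisible(x)
}

# Score the candidate universe of one run. Candidate pairs, their embedded
# distances, confidence scores and positive labels for the chosen
# evaluation mode.
score_candidates <- function(emb, comp, split, dmod, eval_mode) {
  dm <- euclidean_matrix(emb)
  n <- comp$n
  mask <- upper.tri(dm)
  if (eval_mode == "cross_validation") {
    mask[split$trn_edges] <- FALSE
    pos <- split$tst_edges
  } else {
    pos <- comp$edges
  }
  pairs <- which(mask, arr.ind = TRUE)
  dists <- dm[mask]
  labels <- pair_key(pairs, n) %in% pair_key(pos, n)
  list(pairs = pairs, dists = dists,
       scores = confidence_score(dmod, dists), labels = labels)
}

#' Repeated cross-validation experiment over several models
#'
#' Runs the full pipeline `repeats` times. In repeat `r` every model
#' shares the MST drawn with seed `seed + r`, so per-repeat AUCs are
#' genuinely paired and [paired_t_test()] comparisons between models are
#' valid. Evolutionary sampling and density fitting use seeds derived
#' deterministically from the repeat seed and the model index.
#'
#' @inheritParams ede_predict
#' @param models character vector of models to compare (subset of
#'   `"daneosf"`, `"lpa"`, `"rm"`, `"sp"`).
#' @param repeats number of repeated MST draws (default 15).
#' @return An object of class `ede_experiment`: list with `metrics` (data
#'   frame: one row per repeat x model), `summary` (per-model mean and sd
#'   of both AUCs), `t_tests` (named list of [paired_t_test()] results on
#'   AUC-ROC for every model pair) and `config`.
#' @export
run_ede <- function(net, models = c("daneosf", "sp"),
                    mode = c("evolved", "literal"),
                    backend = c("mds", "ncsvd"), dim = 5L, alpha = 0.3,
                    beta = 0.15, k = 3L, nonedge_sample = 1e5, seed = 1L,
                    repeats = 15L,
                    eval_mode = c("cross_validation", "whole_network")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  eval_mode <- match.arg(eval_mode)
  models <- match.arg(models, c("daneosf", "lpa", "rm", "sp"),
                      several.ok = TRUE)
  stopifnot(is_count(repeats), repeats >= 1)
  comp <- max_connected_component(net)
  rows <- list()
  for (r in seq_len(repeats)) {
    seed_r <- as.integer(seed + r)
    mst <- minimum_spanning_tree(comp, seed = seed_r)
    split <- split_train_test(comp, mst)
    mst_net <- subnetwork(comp, mst)
    ctx <- mst_context(mst_net)
    for (mi in seq_along(models)) {
      mdl <- models[mi]
      mseed <- seed_r + 1000L * mi
      if (mdl == "sp") {
        d <- ctx$sp
        evolved <- mst_net
      } else {
        ed <- evolutionary_distance_matrix(
          mst_net, ctx, evo_params(mdl, alpha = alpha, beta = beta,
                                   mode = mode, seed = mseed))
        d <- ed$dist
        evolved <- ed$evolved
      }
      emb <- switch(backend, mds = embed_mds(d, dim),
                    ncsvd = embed_ncsvd(d, dim))
      dmod <- fit_density_model(emb, split, evolved_edges = evolved$edges,
                                k = k, nonedge_sample = nonedge_sample,
                                seed = mseed)
      sc <- score_candidates(emb, comp, split, dmod, eval_mode)
      ev <- evaluate_scores(sc$scores, sc$labels, mode = eval_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, model = mdl, seed = seed_r,
        auc_roc = ev$auc_roc, auc_pr = ev$auc_pr,
        n_pos = ev$n_pos, n_neg = ev$n_neg)
    }
  }
  metrics <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(split(metrics, metrics$model),
    function(g) data.frame(
      model = g$model[1L],
      mean_auc_roc = mean(g$auc_roc), sd_auc_roc = stats::sd(g$auc_roc),
      mean_auc_pr = mean(g$auc_pr), sd_auc_pr = stats::sd(g$auc_pr))))
  summary_df <- summary_df[match(unique(models), summary_df$model), ]
  rownames(summary_df) <- NULL
  t_tests <- list()
  if (length(models) > 1L && repeats > 1L) {
    cmb <- utils::combn(unique(models), 2L)
    for (ci in seq_len(ncol(cmb))) {
      a <- metrics$auc_roc[metrics$model == cmb[1L, ci]]
      b <- metrics$auc_roc[metrics$model == cmb[2L, ci]]
      t_tests[[paste(cmb[1L, ci], "vs", cmb[2L, ci])]] <- paired_t_test(a, b)
    }
  }
  structure(
    list(metrics = metrics, summary = summary_df, t_tests = t_tests,
         config = list(models = models, mode = mode, backend = backend,
                       dim = dim, alpha = alpha, beta = beta, k = k,
                       nonedge_sample = nonedge_sample, seed = seed,
                       repeats = repeats, eval_mode = eval_mode)),
    class = "ede_experiment"
  )
}

#' @export
print.ede_experiment <- function(x, ...) {
  cat(sprintf("<ede_experiment> %d repeats, eval %s\n",
              x$config$repeats, x$config$eval_mode))
  print(x$summary, digits = 4)
  for (nm in names(x$t_tests)) {
    cat(sprintf("  paired t (%s): t = %.3f, p = %.3g\n", nm,
                x$t_tests[[nm]]$statistic, x$t_tests[[nm]]$p_value))
  }
  invisible(x)
}

#' Write run artefacts to an output directory
#'
#' Serializes one [ede_predict()] run: scores as TSV (`node_i, node_j,
#' euclidean_dist, confidence`), evaluation metrics and resolved
#' configuration as JSON, ROC/PR curve points as TSV, and the split
#' manifest `{n, trn, tst, candidates, seed}`.
#'
#' @param run an `ede_run` from [ede_predict()] (with `keep_scores =
#'   TRUE`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$scores)) {
    utils::write.table(
      run$scores[, c("node_i", "node_j", "euclidean_dist", "confidence")],
      file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  ev <- run$eval
  jsonlite::write_json(
    list(auc_roc = ev$auc_roc, auc_pr = ev$auc_pr, n_pos = ev$n_pos,
         n_neg = ev$n_neg, mode = ev$mode, config = run$config),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(ev$roc_points, file.path(dir, "roc_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$pr_points, file.path(dir, "pr_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = run$split$n, trn = nrow(run$split$trn_edges),
         tst = nrow(run$split$tst_edges),
         candidates = run$split$n_candidates, seed = run$config$seed),
    file.path(dir, "split.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
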
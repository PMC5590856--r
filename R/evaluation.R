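#' Area under the ROC curve
#'
#' Rank-based AUC over a scored candidate list: equal to the normalized
#' Mann-Whitney U statistic, i.e. the probability that a random positive
#' outranks a random negative, with tied scores contributing 1/2 through
#' rank averaging.
#'
#' @param scores numeric prediction scores.
#' @param labels logical vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Cumulative TP/FP counts at distinct-score thresholds, scanning the
# ranked list in decreasing score order; tied scores form one block.
ranked_blocks <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  list(tp = cumsum(l)[last], fp = cumsum(!l)[last])
}

#' ROC curve points
#'
#' @inheritParams auc_roc
#' @return Data frame with `fpr` and `tpr` columns, starting at (0, 0)
#'   and ending at (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  b <- ranked_blocks(scores, labels)
  data.frame(fpr = c(0, b$fp / max(sum(!labels), 1)),
             tpr = c(0, b$tp / max(sum(labels), 1)))
}

#' Precision-recall curve points
#'
#' @inheritParams auc_roc
#' @return Data frame with `recall` and `precision` columns.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  b <- ranked_blocks(scores, labels)
  data.frame(recall = b$tp / sum(labels),
             precision = b$tp / (b$tp + b$fp))
}

#' Area under the precision-recall curve
#'
#' Sweeps the same decreasing-score ranking as [auc_roc()] and integrates
#' precision over recall with step-wise interpolation (each recall
#' increment contributes the precision attained at that threshold). Linear
#' interpolation in PR space is known to be optimistic under the heavy
#' class skew of candidate-pair sets, so it is deliberately avoided.
#'
#' @inheritParams auc_roc
#' @return AUCPR in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L) {
    stop("need at least one positive and one negative")
  }
  p <- pr_curve(scores, labels)
  sum(diff(c(0, p$recall)) * p$precision)
}

#' Evaluate a scored candidate list
#'
#' Bundles ROC and precision-recall evaluation of one prediction run.
#' In `"cross_validation"` mode the candidate universe is every non-MST
#' pair and positives are the held-out test edges; in `"whole_network"`
#' mode candidates are all pairs and positives all original edges. The
#' caller supplies scores and labels for the chosen universe; `mode` is
#' recorded for provenance.
#'
#' @inheritParams auc_roc
#' @param mode `"cross_validation"` or `"whole_network"`.
#' @return An object of class `ede_eval`: list with `auc_roc`, `auc_pr`,
#'   `roc_points`, `pr_points`, `n_pos`, `n_neg`, `mode`.
#' @export
evaluate_scores <- function(scores, labels,
                            mode = c("cross_validation", "whole_network")) {
  mode <- match.arg(mode)
  labels <- as.logical(labels)
  structure(
    list(auc_roc = auc_roc(scores, labels),
         auc_pr = auc_pr(scores, labels),
         roc_points = roc_curve(scores, labels),
         pr_points = pr_curve(scores, labels),
         n_pos = sum(labels), n_neg = sum(!labels), mode = mode),
    class = "ede_eval"
  )
}

#' @export
print.ede_eval <- function(x, ...) {
  cat(sprintf("<ede_eval> %s: AUC-ROC %.4f, AUC-PR %.4f (%d pos / %d neg)\n",
              x$mode, x$auc_roc, x$auc_pr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired-sample t-test on ROC score vectors
#'
#' Classical paired t-test of the null hypothesis that the mean pairwise
#' difference between two methods' per-repeat AUCs is zero, with a
#' two-sided p-value from the t distribution on `n - 1` degrees of
#' freedom. Degenerate zero-variance differences are handled explicitly:
#' identical vectors give p = 1, a constant nonzero difference gives
#' p = 0.
#'
#' @param a,b equal-length numeric vectors (length >= 2) of per-repeat
#'   scores from paired experiments (same MST draw per entry).
#' @return List with `statistic`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least two paired observations")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    zero <- mean(d) == 0
    return(list(statistic = if (zero) 0 else sign(mean(d)) * Inf,
                p_value = if (zero) 1 else 0, df = n - 1L,
                mean_diff = mean(d)))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(statistic = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d))
}
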
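#' Nearest-template classification
#'
#' Assigns a clustered sample to the class whose template it is least
#' dissimilar to (mixed edge cover cost). With a `reject` threshold, samples
#' farther than the threshold from every template are returned as
#' `"unassigned"` — the signal that a new class template should be created.
#'
#' @param S a [clustered_sample()].
#' @param templates a `template_set` (or list of template nodes).
#' @param cfg a [dissimilarity_config()].
#' @param reject optional rejection threshold on the minimum dissimilarity.
#' @return List with `label` (template id or `"unassigned"`), `index`, and
#'   `D`, the per-template dissimilarities. Exact ties go to the smallest
#'   template index.
#' @export
nearest_template <- function(S, templates, cfg = dissimilarity_config(),
                             reject = NULL) {
  if (!length(templates)) stop("at least one template is required")
  D <- vapply(templates, function(t) sample_dissimilarity(t, S, cfg),
              numeric(1L))
  i <- which.min(D)  # first minimum = smallest index on ties
  if (!is.null(reject) && D[i] > reject)
    return(list(label = "unassigned", index = NA_integer_, D = D))
  list(label = templates[[i]]$id, index = i, D = D)
}

#' Disease-specific meta-clusters of a positive-class template
#'
#' Registers the meta-clusters of the positive template against those of the
#' negative template with a minimum-cost mixed edge cover on the complete
#' bipartite graph weighted by the configured dissimilarity. Meta-clusters
#' of the positive template left unmatched have no counterpart among the
#' negative class and are the disease-specific set `M+` (for a leukemia
#' cohort, the blast-like immunophenotypes).
#'
#' @param t_pos,t_neg template nodes (positive and negative class).
#' @param cfg a [dissimilarity_config()].
#' @return Integer vector of indices into `t_pos$clusters` (possibly empty),
#'   with the `mec_result` attached as attribute `mec`.
#' @export
disease_specific_metaclusters <- function(t_pos, t_neg,
                                          cfg = dissimilarity_config()) {
  if (!length(as_cluster_list(t_pos)) || !length(as_cluster_list(t_neg)))
    stop("both templates must be non-empty")
  mec <- mixed_edge_cover(t_pos, t_neg, cfg)
  structure(mec$unmatched_A, mec = mec)
}

#' Piecewise template score of a sample
#'
#' Scores a clustered sample `X` against a positive-class template `T+` and
#' a negative-class template `T-`. Two mixed edge covers are computed
#' independently (X vs `T+`, X vs `T-`). For each cluster `c_i`, `d` is the
#' average dissimilarity to its matched meta-cluster set and
#' `s = 2*lambda - d` the corresponding similarity (non-negative by the
#' cover's optimality bound `d <= 2*lambda`). With `M+` the
#' disease-specific meta-clusters of `T+` and `k` the number of clusters in
#' `X`:
#' \itemize{
#'   \item `f+ = s(c_i, mec+(c_i))` when the matched set meets `M+`;
#'     `-s/k` when matched only to shared meta-clusters; `0` when unmatched.
#'   \item `f- = -s(c_i, mec-(c_i))/k` when matched in `T-`; `lambda` when
#'     unmatched there.
#' }
#' The sample score is the abundance-weighted sum
#' \deqn{f(X) = \sum_i \frac{|c_i|}{|X|}\,\frac12\,(f^+(c_i) + f^-(c_i)),}
#' and the sample is called positive exactly when `f(X) > 0` (a zero score
#' is conservative and classifies as negative). The positive branch of `f+`
#' is not divided by `k`, so disease-matched clusters dominate: the design
#' trades false positives for fewer false negatives.
#'
#' @param X a [clustered_sample()].
#' @param t_pos,t_neg template nodes.
#' @param cfg a [dissimilarity_config()].
#' @param m_plus optional precomputed [disease_specific_metaclusters()]
#'   index set (recomputed from the templates when missing).
#' @return Object of class `score_report`: per-cluster data frame
#'   (`cluster`, `n_cells`, `d_pos`, `d_neg`, `f_pos`, `f_neg`), `score`,
#'   `predicted` (`"positive"`/`"negative"`), `lambda`, `m_plus` and the two
#'   `mec_result`s.
#' @export
score_sample <- function(X, t_pos, t_neg, cfg = dissimilarity_config(),
                         m_plus = NULL) {
  k <- length(X$clusters)
  if (k == 0L) stop("sample has no clusters")
  if (is.null(m_plus)) m_plus <- disease_specific_metaclusters(t_pos, t_neg,
                                                               cfg)
  p <- length(X$clusters[[1L]]$mean)
  lambda <- resolve_lambda(cfg, p)
  mec_pos <- mixed_edge_cover(X, t_pos, cfg)
  mec_neg <- mixed_edge_cover(X, t_neg, cfg)
  sizes <- vapply(X$clusters, function(cl) cl$size, integer(1L))
  n_total <- sum(sizes)
  f_pos <- f_neg <- d_pos <- d_neg <- numeric(k)
  for (i in seq_len(k)) {
    part_p <- mec_partners(mec_pos, i, "A")
    part_n <- mec_partners(mec_neg, i, "A")
    if (length(part_p)) {
      d_pos[i] <- mean(mec_pos$d[i, part_p])
      s <- 2 * lambda - d_pos[i]
      f_pos[i] <- if (length(intersect(part_p, m_plus))) s else -s / k
    } else {
      d_pos[i] <- NA_real_
      f_pos[i] <- 0
    }
    if (length(part_n)) {
      d_neg[i] <- mean(mec_neg$d[i, part_n])
      f_neg[i] <- -(2 * lambda - d_neg[i]) / k
    } else {
      d_neg[i] <- NA_real_
      f_neg[i] <- lambda
    }
  }
  score <- sum(sizes / n_total * 0.5 * (f_pos + f_neg))
  structure(list(
    clusters = data.frame(cluster = seq_len(k), n_cells = sizes,
                          d_pos = d_pos, d_neg = d_neg,
                          f_pos = f_pos, f_neg = f_neg),
    score = score,
    predicted = if (score > 0) "positive" else "negative",
    lambda = lambda, m_plus = as.integer(m_plus),
    mec_pos = mec_pos, mec_neg = mec_neg),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report: f(X) = %.4g -> %s (lambda = %.4g, |M+| = %d)\n",
              x$score, x$predicted, x$lambda, length(x$m_plus)))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Combine per-panel classification scores
#'
#' Plain arithmetic mean over the panels (tubes) the user selected; panel
#' choice is configuration, not automated.
#'
#' @param scores numeric vector, one score per panel.
#' @return Scalar mean.
#' @export
combine_panel_scores <- function(scores) {
  if (!length(scores)) stop("at least one panel score is required")
  mean(scores)
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integers.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Tally confusion counts from labels
#'
#' @param truth,predicted character vectors with values `"positive"` /
#'   `"negative"`.
#' @return A [confusion_counts()].
#' @export
tally_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(tp = sum(truth == "positive" & predicted == "positive"),
                   tn = sum(truth == "negative" & predicted == "negative"),
                   fp = sum(truth == "negative" & predicted == "positive"),
                   fn = sum(truth == "positive" & predicted == "negative"))
}

#' Precision, recall, specificity and F-value
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `specificity = TN/(FP+TN)`, `f_value = 2PR/(P+R)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param cc a [confusion_counts()].
#' @return Named numeric vector
#'   `c(precision, recall, specificity, f_value)`.
#' @export
classification_metrics <- function(cc) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(cc$tp, cc$tp + cc$fp)
  recall <- ratio(cc$tp, cc$tp + cc$fn)
  specificity <- ratio(cc$tn, cc$fp + cc$tn)
  f_value <- if (!is.na(precision) && !is.na(recall) &&
                 (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, specificity = specificity,
    f_value = f_value)
}

#' Empirical p-value against a null score distribution
#'
#' Add-one empirical tail probability
#' `p = (1 + #\{null >= score\}) / (1 + #null)`, suitable for null scores
#' taken from a control panel with no class-specific markers.
#'
#' @param score observed classification score.
#' @param null_scores numeric vector of scores under the null (length >= 1).
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(score, null_scores) {
  if (!length(null_scores)) stop("need at least one null score")
  (1 + sum(null_scores >= score)) / (1 + length(null_scores))
}
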
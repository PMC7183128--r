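# Preprocessing for real expression pipelines: a two-sample Gaussian
# generalized likelihood-ratio score per feature, top-k selection, and
# highest-scoring-probe-per-gene collapsing. Only the induced ranking is
# consumed downstream, so any order-preserving version of the statistic is
# pipeline-equivalent.

#' Two-sample Gaussian likelihood-ratio feature score
#'
#' Generalized LRT of a single Gaussian for all samples (H0) against
#' class-specific Gaussians (H1), with MLE variances:
#' `score = N ln(s2_H0) - n0 ln(s2_0) - n1 ln(s2_1)`, which equals twice
#' the difference of the maximized Gaussian log-likelihoods and is always
#' `>= 0`. Invariant under common affine maps of the feature.
#'
#' @param x numeric feature vector.
#' @param labels 0/1 vector, at least 2 samples per class.
#' @return non-negative score.
#' @export
lrt_score <- function(x, labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 < 2 || n1 < 2) stop("need at least 2 samples per class")
  N <- n0 + n1
  mle_var <- function(v) mean((v - mean(v))^2)
  s2_all <- mle_var(x)
  if (s2_all == 0) stop("constant feature")
  s2_0 <- mle_var(x[labels == 0L]); s2_1 <- mle_var(x[labels == 1L])
  if (s2_0 == 0 || s2_1 == 0) stop("zero within-class variance")
  max(0, N * log(s2_all) - n0 * log(s2_0) - n1 * log(s2_1))
}

#' Score and rank all features
#'
#' Features whose score is undefined (constant overall or within a class)
#' are excluded and reported in the `excluded` attribute.
#'
#' @param m labeled [expr_matrix()].
#' @return data frame of class `ranked_features` with columns `feature`,
#'   `score`, `rank`, in descending score order (ties by feature ID).
#' @export
rank_features <- function(m) {
  check_two_classes(m, min_per_class = 2L)
  feats <- colnames(m$values)
  scores <- rep(NA_real_, length(feats))
  for (k in seq_along(feats))
    scores[k] <- tryCatch(lrt_score(m$values[, k], m$labels),
                          error = function(e) NA_real_)
  excluded <- feats[is.na(scores)]
  keep <- !is.na(scores)
  ord <- order(-scores[keep], feats[keep], method = "radix")
  out <- data.frame(feature = feats[keep][ord], score = scores[keep][ord],
                    rank = seq_len(sum(keep)), stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("ranked_features", class(out))
  out
}

#' Select the top-k ranked features
#'
#' @param ranked a `ranked_features` data frame from [rank_features()].
#' @param k number of features, `0 <= k <= nrow(ranked)`.
#' @return character vector of the first `k` feature IDs in rank order.
#' @export
top_k <- function(ranked, k) {
  if (k > nrow(ranked)) stop("k (", k, ") exceeds ranked feature count (",
                             nrow(ranked), ")")
  utils::head(ranked$feature, k)
}

#' Collapse probes to one per gene by maximal LRT score
#'
#' For each gene the probe with the highest score is kept (ties broken by
#' the lexicographically smallest probe ID); probes without a gene mapping
#' are dropped.
#'
#' @param m [expr_matrix()] whose features are probes.
#' @param probe_map data frame from [read_probe_map()] (columns `probe_id`,
#'   `gene_id`, optional `mapped`).
#' @param scores named numeric vector of per-probe scores covering every
#'   mapped probe present in `m` (e.g. from [rank_features()]).
#' @return an [expr_matrix()] with one feature per distinct mapped gene,
#'   features renamed to gene IDs; the chosen probe per gene is recorded in
#'   the `probe_of` attribute.
#' @export
collapse_probes <- function(m, probe_map, scores) {
  pm <- as.data.frame(probe_map)
  if (!is.null(pm$mapped)) pm <- pm[pm$mapped, , drop = FALSE]
  pm <- pm[!is.na(pm$gene_id) & pm$probe_id %in% colnames(m$values), , drop = FALSE]
  if (!nrow(pm)) stop("no mapped probes present in the matrix")
  missing <- setdiff(pm$probe_id, names(scores))
  if (length(missing))
    stop("scores missing for mapped probe(s): ", paste(missing, collapse = ", "))
  pm$score <- scores[pm$probe_id]
  pm <- pm[order(pm$gene_id, -pm$score, pm$probe_id, method = "radix"), ]
  best <- pm[!duplicated(pm$gene_id), ]
  vals <- m$values[, best$probe_id, drop = FALSE]
  colnames(vals) <- best$gene_id
  out <- expr_matrix(vals, labels = m$labels)
  attr(out, "probe_of") <- stats::setNames(best$probe_id, best$gene_id)
  out
}
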
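# ROC/AUC computation and the repeated-split experiment drivers for
# classifier learning curves and MTM pair-detection benchmarks.

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney rank statistic with midrank tie handling; the
#' curve sweeps all distinct score thresholds (label 1 assigned when the
#' score strictly exceeds the threshold). The trapezoidal area under the
#' returned curve equals the rank AUC.
#'
#' @param scores numeric score vector (larger = more class-1).
#' @param labels 0/1 vector, both classes present.
#' @return list of class `roc_result`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  rk <- rank(scores)  # midranks
  auc <- (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(s, fromLast = TRUE)  # last index at each distinct score
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC = ", sprintf("%.4f", x$auc), " (", length(x$fpr),
      " curve points)\n", sep = "")
  invisible(x)
}

#' Balanced accuracy at an ROC operating point
#'
#' Under equal class weights, accuracy is `1 - 0.5 (FPR + FNR)`.
#'
#' @param fpr false-positive (type I error) rate.
#' @param fnr false-negative (type II error) rate.
#' @return accuracy in \[0, 1\].
#' @export
accuracy_at <- function(fpr, fnr) 1 - 0.5 * (fpr + fnr)

# deterministic per-repetition seed stream, kept below 2^31
derive_seed <- function(master, ...) {
  key <- c(master, ...)
  s <- 0
  for (v in key) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483629
  as.integer(s) + 1L
}

#' Learning-curve experiment: mean test AUC versus training size
#'
#' For each training size `n` and repetition: draw a stratified training
#' sample (`n/2` per class) and an independent stratified test sample,
#' train, score the test set, and record the AUC. Repetition seeds derive
#' deterministically from `seed`, so the output is independent of execution
#' order. Repetitions whose training fails (e.g. screening removed
#' everything) are recorded and skipped.
#'
#' @param config a [synthetic_config()] describing the population.
#' @param trainer function `(train_matrix) -> model` returning an object
#'   usable with `scorer`; defaults to LAS-HDMR with `params`.
#' @param scorer function `(model, values_matrix) -> scores`.
#' @param n_grid vector of total training sizes (split equally per class).
#' @param reps repetitions per size.
#' @param n_test per-class test sample count.
#' @param seed master seed.
#' @param params [hdmr_params()] used by the default trainer.
#' @return data frame: `n`, `mean_auc`, `sd_auc`, `reps_ok`.
#' @export
repeated_experiment <- function(config, n_grid, reps = 20L, n_test = 1000L,
                                seed = 1L, params = hdmr_params(),
                                trainer = NULL, scorer = hdmr_score) {
  trainer <- trainer %||% function(tr) train_las_hdmr(tr, params)
  rows <- lapply(n_grid, function(n) {
    aucs <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      tr_seed <- derive_seed(seed, n, r, 1)
      te_seed <- derive_seed(seed, n, r, 2)
      tr <- generate_expression(config, n %/% 2, n - n %/% 2, seed = tr_seed)$data
      te <- generate_expression(config, n_test, n_test, seed = te_seed)$data
      aucs[r] <- tryCatch({
        model <- trainer(tr)
        roc_auc(scorer(model, te$values), te$labels)$auc
      }, error = function(e) NA_real_)
    }
    ok <- !is.na(aucs)
    data.frame(n = n, mean_auc = mean(aucs[ok]), sd_auc = stats::sd(aucs[ok]),
               reps_ok = sum(ok))
  })
  do.call(rbind, rows)
}

#' ROC of MTM pair detection against the simulator's ground truth
#'
#' Pairs are scored by `-p_combined` (sweeping the p-value); positives are
#' the generator's true interacting pairs. Untestable pairs are excluded.
#'
#' @param mtm an `mtm_result` from [run_mtm()].
#' @param truth the `truth` element of [generate_expression()] (or a
#'   two-column matrix of interacting pair member IDs).
#' @return a `roc_result`.
#' @export
mtm_roc <- function(mtm, truth) {
  results <- if (inherits(mtm, "mtm_result")) mtm$results else as.data.frame(mtm)
  pairs <- if (is.list(truth) && !is.null(truth$true_interacting_pairs))
    truth$true_interacting_pairs else truth
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("empty positive set: no true interacting pairs")
  pos_keys <- paste0(pairs[, 1], "|", pairs[, 2])
  results <- results[results$testable, , drop = FALSE]
  keys <- paste0(results$gene_i, "|", results$gene_j)
  is_pos <- keys %in% pos_keys
  if (!any(is_pos)) stop("no true interacting pair was testable")
  roc_auc(-results$p_combined, as.integer(is_pos))
}

#' Averaged MTM detection ROC over repeated simulations
#'
#' Runs [run_mtm()] on `reps` fresh draws from `config` and reports the
#' per-repetition detection AUCs plus a vertically averaged ROC curve (mean
#' TPR on a fixed grid of 101 FPR points).
#'
#' @param config a [synthetic_config()] with a non-empty marker set.
#' @param n per-class sample count.
#' @param reps repetitions.
#' @param seed master seed.
#' @param fdr BH level passed to [run_mtm()] (does not affect the ROC).
#' @return list: `auc` (per-rep vector), `mean_auc`, `fpr_grid`, `mean_tpr`.
#' @export
mtm_detection_experiment <- function(config, n, reps = 5L, seed = 1L, fdr = 0.05) {
  fpr_grid <- seq(0, 1, length.out = 101L)
  tpr_mat <- matrix(NA_real_, reps, length(fpr_grid))
  aucs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sim <- generate_expression(config, n, n, seed = derive_seed(seed, n, r))
    roc <- mtm_roc(run_mtm(sim$data, fdr = fdr), sim$truth)
    aucs[r] <- roc$auc
    tpr_mat[r, ] <- stats::approx(roc$fpr, roc$tpr, xout = fpr_grid,
                                  ties = max, rule = 2)$y
  }
  list(auc = aucs, mean_auc = mean(aucs), fpr_grid = fpr_grid,
       mean_tpr = colMeans(tpr_mat))
}
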
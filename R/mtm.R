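# MTM (multiple test mixing) for class-differential pairwise interactions.
# A pair is declared interacting when independence is rejected in at least
# one class (per-class Pearson tests combined by Fisher's method, chi-square
# with 4 df) AND the two class covariance matrices differ (Box's M
# likelihood-ratio test with the chi-square adjustment, 3 df for bivariate
# two-group data). The two p-values are added (union bound, capped at 1) —
# a deliberately conservative combination.

P_CLAMP <- 1e-300  # floor before taking logs; guards |r| = 1 degeneracies

#' Pearson linear correlation test
#'
#' Two-sided test of zero correlation for Gaussian data:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against Student-t with `n - 2` df;
#' `|r| = 1` yields p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, neither constant.
#' @return list with `r` (sample correlation) and `p` (two-sided p-value).
#' @export
pearson_independence_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Fisher's method for two p-values
#'
#' `C = -2 (ln p0 + ln p1)` is chi-square with 4 degrees of freedom under
#' the null of two independent uniform p-values. Inputs are clamped at
#' `1e-300` before the logs. Vectorized.
#'
#' @param p0,p1 numeric p-value vectors in \[0, 1\].
#' @return list with `C` (statistic) and `p` (upper chi-square(4) tail).
#' @export
fisher_combine <- function(p0, p1) {
  C <- -2 * (log(pmax(p0, P_CLAMP)) + log(pmax(p1, P_CLAMP)))
  list(C = C, p = stats::pchisq(C, df = 4, lower.tail = FALSE))
}

# Box's M pieces shared by the scalar and vectorized paths (p = 2 features,
# g = 2 groups -> 3 df, scale factor c1 = (13/18) * (sum 1/(n_y-1) - 1/(N-2))
box_m_p <- function(logdet0, logdet1, logdet_pool, n0, n1) {
  N <- n0 + n1
  M <- (N - 2) * logdet_pool - (n0 - 1) * logdet0 - (n1 - 1) * logdet1
  M <- pmax(M, 0)  # tiny negatives from rounding
  c1 <- (2 * 4 + 3 * 2 - 1) / (6 * 3) * (1 / (n0 - 1) + 1 / (n1 - 1) - 1 / (N - 2))
  stats::pchisq((1 - c1) * M, df = 3, lower.tail = FALSE)
}

#' Covariance-equality likelihood-ratio test for a bivariate pair
#'
#' Box's M statistic with Box's chi-square adjustment:
#' `M = (N - g) ln|S_pool| - sum_y (n_y - 1) ln|S_y|`, with the pooled
#' covariance `S_pool = sum_y (n_y - 1) S_y / (N - g)`; the p-value is the
#' upper chi-square tail with `p(p+1)(g-1)/2 = 3` df at `(1 - c1) M`.
#'
#' @param X0,X1 per-class `n_y x 2` matrices with `n_y >= 4`.
#' @return p-value for equality of the two class covariance matrices.
#' @export
cov_equality_p <- function(X0, X1) {
  X0 <- as.matrix(X0); X1 <- as.matrix(X1)
  if (ncol(X0) != 2L || ncol(X1) != 2L) stop("bivariate test: need 2 columns")
  n0 <- nrow(X0); n1 <- nrow(X1)
  if (n0 < 4 || n1 < 4) stop("need at least 4 samples per class")
  S0 <- stats::cov(X0); S1 <- stats::cov(X1)
  d0 <- det(S0); d1 <- det(S1)
  if (d0 <= 0 || d1 <= 0) stop("singular class covariance")
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  box_m_p(log(d0), log(d1), log(det(Sp)), n0, n1)
}

#' Flag outliers by the 3-scaled-MAD rule
#'
#' Removes entries farther than 3 scaled MADs from the median, with scaled
#' MAD `= 1.4826 * median(|x - median(x)|)`. A zero MAD removes nothing.
#'
#' @param values numeric vector.
#' @return list with `kept` (values retained) and `removed` (indices
#'   removed, possibly empty).
#' @export
remove_outliers <- function(values) {
  med <- stats::median(values)
  smad <- 1.4826 * stats::median(abs(values - med))
  if (smad == 0) return(list(kept = values, removed = integer(0)))
  out <- which(abs(values - med) > 3 * smad)
  list(kept = if (length(out)) values[-out] else values, removed = out)
}

# per-column logical keep-mask under the 3-scaled-MAD rule
outlier_mask <- function(X) {
  med <- apply(X, 2, stats::median)
  smad <- 1.4826 * apply(sweep(X, 2, med), 2, function(z) stats::median(abs(z)))
  dev <- abs(sweep(X, 2, med))
  keep <- sweep(dev, 2, 3 * smad) <= 0
  keep[, smad == 0] <- TRUE
  keep
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up adjustment with an explicit test count `m` (which may
#' exceed the number of p-values supplied, e.g. when untestable pairs are
#' excluded from the vector but should still be counted).
#'
#' @param pvals numeric vector of p-values.
#' @param m total number of tests (default `length(pvals)`).
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' MTM test for a single feature pair
#'
#' Applies per-class, per-feature outlier removal (pairwise deletion: a
#' sample flagged in either member is dropped from this pair's tests only),
#' the per-class Pearson tests with Fisher combination, the
#' covariance-equality test on the cleaned pair data, and the union-bound
#' combination `p_combined = min(1, p_fisher + p_cov)`.
#'
#' @param m labeled [expr_matrix()].
#' @param i,j feature IDs of the pair.
#' @param outlier_policy `"pairwise"` (default), `"global"` is handled by
#'   the caller via prior row deletion, `"none"` disables removal.
#' @return list of class `pair_test`: pair IDs, per-class correlations and
#'   p-values, `C`, `p_fisher`, `p_cov`, `p_combined`, per-class used sample
#'   counts, and `testable` (FALSE when cleaning leaves < 4 samples in a
#'   class, a member is constant, or a class covariance is singular).
#' @export
mtm_pair_test <- function(m, i, j, outlier_policy = c("pairwise", "none")) {
  outlier_policy <- match.arg(outlier_policy)
  check_two_classes(m)
  res <- list(gene_i = i, gene_j = j, rho_0 = NA_real_, rho_1 = NA_real_,
              p_indep_0 = NA_real_, p_indep_1 = NA_real_, C = NA_real_,
              p_fisher = NA_real_, p_cov = NA_real_, p_combined = NA_real_,
              n_used_0 = NA_integer_, n_used_1 = NA_integer_, testable = FALSE)
  class(res) <- "pair_test"
  cleaned <- list()
  for (y in c(0L, 1L)) {
    X <- m$values[m$labels == y, c(i, j), drop = FALSE]
    if (outlier_policy == "pairwise" && nrow(X) > 0L) {
      keep <- outlier_mask(X)
      X <- X[keep[, 1] & keep[, 2], , drop = FALSE]
    }
    cleaned[[y + 1L]] <- X
    res[[paste0("n_used_", y)]] <- nrow(X)
  }
  ok <- tryCatch({
    t0 <- pearson_independence_p(cleaned[[1]][, 1], cleaned[[1]][, 2])
    t1 <- pearson_independence_p(cleaned[[2]][, 1], cleaned[[2]][, 2])
    fc <- fisher_combine(t0$p, t1$p)
    pc <- cov_equality_p(cleaned[[1]], cleaned[[2]])
    res$rho_0 <- t0$r; res$rho_1 <- t1$r
    res$p_indep_0 <- t0$p; res$p_indep_1 <- t1$p
    res$C <- fc$C; res$p_fisher <- fc$p; res$p_cov <- pc
    res$p_combined <- min(1, fc$p + pc)
    TRUE
  }, error = function(e) FALSE)
  res$testable <- ok
  res
}

# Vectorized pairwise-deletion statistics for one class. Returns p x p
# matrices of pairwise n, correlation, unbiased variances/covariance.
pairwise_class_stats <- function(X, use_mask = TRUE) {
  M <- if (use_mask) outlier_mask(X) * 1 else matrix(1, nrow(X), ncol(X))
  Z <- X * M
  N <- crossprod(M)
  Sx <- crossprod(Z, M)          # sum of x_i over samples kept for (i, j)
  Sxx <- crossprod(Z * Z, M)
  Sxy <- crossprod(Z)
  denom <- pmax(N - 1, 1)
  cov_xy <- (Sxy - Sx * t(Sx) / pmax(N, 1)) / denom
  var_x <- (Sxx - Sx^2 / pmax(N, 1)) / denom
  var_y <- t(var_x)
  r <- cov_xy / sqrt(pmax(var_x * var_y, .Machine$double.xmin))
  r <- pmin(pmax(r, -1), 1)
  list(N = N, r = r, var_x = var_x, var_y = var_y, cov = cov_xy)
}

# two-sided Pearson p from correlation matrix and pairwise counts
pearson_p_matrix <- function(r, N) {
  p <- matrix(NA_real_, nrow(r), ncol(r))
  ok <- N >= 4
  rr <- r[ok]; nn <- N[ok]
  tt <- rr * sqrt(pmax(nn - 2, 0) / pmax(1 - rr^2, .Machine$double.xmin))
  pv <- 2 * stats::pt(-abs(tt), df = nn - 2)
  pv[abs(rr) >= 1] <- 0
  p[ok] <- pv
  p
}

#' Run the MTM sweep over all feature pairs
#'
#' Enumerates all unordered feature pairs, applies [mtm_pair_test()]'s
#' statistics to each via a vectorized path (identical results), and
#' BH-adjusts the combined p-values over the testable pairs (untestable
#' pairs — too few cleaned samples, constant members, or a singular class
#' covariance — are excluded from the BH denominator and reported with
#' `testable = FALSE`).
#'
#' @param m labeled [expr_matrix()] with one feature per gene.
#' @param fdr BH false-discovery-rate level for the significance call.
#' @param outlier_policy `"pairwise"` (per-pair deletion of per-feature,
#'   per-class 3-scaled-MAD outliers), `"global"` (drop any sample flagged
#'   for any feature from the whole sweep), or `"none"`.
#' @return A list of class `mtm_result`: `results` (data frame, one row per
#'   pair: `gene_i`, `gene_j`, per-class `rho`/`p_indep`/`n_used`, `C`,
#'   `p_fisher`, `p_cov`, `p_combined`, `q_bh`, `testable`, `significant`),
#'   `m_tested` (BH denominator), `n_pairs` (pairs enumerated), and `fdr`.
#' @export
run_mtm <- function(m, fdr = 0.05,
                    outlier_policy = c("pairwise", "global", "none")) {
  outlier_policy <- match.arg(outlier_policy)
  check_two_classes(m, min_per_class = 4L)
  feats <- colnames(m$values)
  p <- length(feats)
  if (p < 2L) stop("need at least two features")
  n_pairs <- pair_count(p)
  vals <- m$values
  labels <- m$labels
  if (outlier_policy == "global") {
    drop_row <- rep(FALSE, nrow(vals))
    for (y in c(0L, 1L)) {
      idx <- which(labels == y)
      keep <- outlier_mask(vals[idx, , drop = FALSE])
      drop_row[idx[rowSums(!keep) > 0]] <- TRUE
    }
    vals <- vals[!drop_row, , drop = FALSE]
    labels <- labels[!drop_row]
  }
  use_mask <- outlier_policy == "pairwise"
  s0 <- pairwise_class_stats(vals[labels == 0L, , drop = FALSE], use_mask)
  s1 <- pairwise_class_stats(vals[labels == 1L, , drop = FALSE], use_mask)
  p0 <- pearson_p_matrix(s0$r, s0$N)
  p1 <- pearson_p_matrix(s1$r, s1$N)
  fc <- fisher_combine(p0, p1)
  det0 <- s0$var_x * s0$var_y - s0$cov^2
  det1 <- s1$var_x * s1$var_y - s1$cov^2
  w0 <- s0$N - 1; w1 <- s1$N - 1
  detp <- ((w0 * s0$var_x + w1 * s1$var_x) * (w0 * s0$var_y + w1 * s1$var_y) -
             (w0 * s0$cov + w1 * s1$cov)^2) / (s0$N + s1$N - 2)^2
  testable <- s0$N >= 4 & s1$N >= 4 & det0 > 0 & det1 > 0 &
    s0$var_x > 0 & s0$var_y > 0 & s1$var_x > 0 & s1$var_y > 0
  p_cov <- matrix(NA_real_, p, p)
  p_cov[testable] <- box_m_p(log(det0[testable]), log(det1[testable]),
                             log(detp[testable]), s0$N[testable], s1$N[testable])
  p_comb <- pmin(1, fc$p + p_cov)
  ut <- upper.tri(p_cov)
  ii <- row(p_cov)[ut]; jj <- col(p_cov)[ut]
  results <- data.frame(
    gene_i = feats[ii], gene_j = feats[jj],
    rho_0 = s0$r[ut], rho_1 = s1$r[ut],
    p_indep_0 = p0[ut], p_indep_1 = p1[ut],
    n_used_0 = as.integer(s0$N[ut]), n_used_1 = as.integer(s1$N[ut]),
    C = fc$C[ut], p_fisher = fc$p[ut], p_cov = p_cov[ut],
    p_combined = p_comb[ut], testable = testable[ut] & !is.na(p_comb[ut]),
    stringsAsFactors = FALSE)
  m_tested <- sum(results$testable)
  results$q_bh <- NA_real_
  if (m_tested > 0)
    results$q_bh[results$testable] <-
      bh_adjust(results$p_combined[results$testable], m = m_tested)
  results$significant <- !is.na(results$q_bh) & results$q_bh <= fdr
  structure(list(results = results, m_tested = m_tested, n_pairs = n_pairs,
                 fdr = fdr, outlier_policy = outlier_policy),
            class = "mtm_result")
}

#' @export
print.mtm_result <- function(x, ...) {
  cat("MTM sweep: ", x$n_pairs, " pairs enumerated, ", x$m_tested,
      " testable, ", sum(x$results$significant), " significant at BH ",
      x$fdr, "\n", sep = "")
  invisible(x)
}

#' Number of unordered feature pairs
#'
#' @param n_features feature count.
#' @return `n (n - 1) / 2`, as a double (exact well beyond 2^31 pairs).
#' @export
pair_count <- function(n_features) {
  n <- as.numeric(n_features)
  n * (n - 1) / 2
}

#' Build the gene-pair interaction graph
#'
#' Each gene is scored by the minimum combined p-value over its incident
#' pairs; the `top_n` genes by that score are kept and all tested pairs
#' among them become edges weighted `-ln(p_combined)`.
#'
#' @param mtm an `mtm_result` (or its `results` data frame).
#' @param top_n number of genes to keep.
#' @return list with `genes` (data frame: `gene`, `min_p`) and `edges`
#'   (data frame: `gene_i`, `gene_j`, `weight`).
#' @export
pair_graph <- function(mtm, top_n) {
  results <- if (inherits(mtm, "mtm_result")) mtm$results else as.data.frame(mtm)
  results <- results[results$testable %||% rep(TRUE, nrow(results)), , drop = FALSE]
  if (!nrow(results)) stop("no testable pairs")
  long <- data.frame(gene = c(results$gene_i, results$gene_j),
                     p = rep(results$p_combined, 2L))
  min_p <- tapply(long$p, long$gene, min)
  gdf <- data.frame(gene = names(min_p), min_p = as.numeric(min_p),
                    stringsAsFactors = FALSE)
  gdf <- gdf[order(gdf$min_p, gdf$gene, method = "radix"), ]
  keep <- utils::head(gdf$gene, top_n)
  sub <- results[results$gene_i %in% keep & results$gene_j %in% keep, , drop = FALSE]
  edges <- data.frame(gene_i = sub$gene_i, gene_j = sub$gene_j,
                      weight = -log(pmax(sub$p_combined, P_CLAMP)),
                      stringsAsFactors = FALSE)
  edges$weight[sub$p_combined >= 1] <- 0
  list(genes = gdf[gdf$gene %in% keep, ], edges = edges)
}
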
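# Block-covariance synthetic expression generator. Features come in four
# types: global marker blocks (class-0 N(0, s0^2 Sigma0), class-1
# N(mu, s1^2 Sigma1) with equicorrelation Sigma_y and a synergetic
# [1, 1/2, ..., 1/k] or marginal [1, 0, ..., 0] mean), heterogeneous marker
# blocks (dysregulated only in one of c class-1 subclasses), low-variance
# non-markers (class-0 distribution in both classes, block-correlated), and
# high-variance non-markers (independent two-component Gaussian mixtures
# p N(0, s0^2) + (1 - p) N(1, s1^2) with p drawn once per feature).

#' Configure the synthetic expression generator
#'
#' @param n_global,n_hetero,n_lv,n_hv feature counts for global markers,
#'   heterogeneous markers, low-variance and high-variance non-markers;
#'   marker counts must be divisible by `block_size`.
#' @param block_size within-block feature count `k`.
#' @param subclass_count number of class-1 subclasses `c` for heterogeneous
#'   markers.
#' @param var0,var1 class-0 and class-1 marker variance scales (sigma0^2,
#'   sigma1^2).
#' @param rho0,rho1 within-block equicorrelations; must lie in
#'   `(-1/(k-1), 1)` so the equicorrelation matrix is positive definite.
#' @param mean_type `"synergetic"` (class-1 block mean `[1, 1/2, ..., 1/k]`)
#'   or `"marginal"` (`[1, 0, ..., 0]`).
#' @param seed integer seed; all randomness in [generate_expression()]
#'   derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_global = 0L, n_hetero = 0L, n_lv = 0L, n_hv = 0L,
                             block_size = 10L, subclass_count = 2L,
                             var0 = 0.25, var1 = 0.64,
                             rho0 = 0.5, rho1 = 0.5,
                             mean_type = c("synergetic", "marginal"),
                             seed = 1L) {
  mean_type <- match.arg(mean_type)
  k <- as.integer(block_size)
  if (k < 1L) stop("block_size must be >= 1")
  for (nm in c("n_global", "n_hetero", "n_lv", "n_hv")) {
    v <- get(nm)
    if (v < 0 || v != as.integer(v)) stop(nm, " must be a non-negative integer")
  }
  if (n_global %% k != 0L) stop("n_global must be divisible by block_size")
  if (n_hetero %% k != 0L) stop("n_hetero must be divisible by block_size")
  if (var0 <= 0 || var1 <= 0) stop("var0 and var1 must be positive")
  lo <- if (k > 1L) -1 / (k - 1) else -1
  for (nm in c("rho0", "rho1")) {
    r <- get(nm)
    if (r <= lo || r >= 1)
      stop(nm, " = ", r, " outside the positive-definite range (", signif(lo, 3),
           ", 1) for block_size ", k)
  }
  if (subclass_count < 1L) stop("subclass_count must be >= 1")
  structure(list(n_global = as.integer(n_global), n_hetero = as.integer(n_hetero),
                 n_lv = as.integer(n_lv), n_hv = as.integer(n_hv),
                 total_features = as.integer(n_global + n_hetero + n_lv + n_hv),
                 block_size = k, subclass_count = as.integer(subclass_count),
                 var0 = var0, var1 = var1, rho0 = rho0, rho1 = rho1,
                 mean_type = mean_type, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: |F| = ", x$total_features, " (", x$n_global,
      " global, ", x$n_hetero, " hetero, ", x$n_lv, " LV, ", x$n_hv,
      " HV), k = ", x$block_size, ", c = ", x$subclass_count,
      ", var0/var1 = ", x$var0, "/", x$var1, ", rho0/rho1 = ", x$rho0, "/",
      x$rho1, ", ", x$mean_type, " mean, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# upper-triangular Cholesky factor of the k x k equicorrelation matrix
equicorr_chol <- function(k, rho) {
  S <- matrix(rho, k, k); diag(S) <- 1
  chol(S)
}

# n draws from N(mean, scale^2 * Sigma) given chol(Sigma)
rmvn_chol <- function(n, mean, scale, R) {
  k <- length(mean)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% R
  sweep(Z * scale, 2, mean, `+`)
}

block_mean <- function(k, mean_type) {
  if (mean_type == "synergetic") 1 / seq_len(k) else c(1, rep(0, k - 1L))
}

#' Generate a synthetic labeled expression matrix with ground truth
#'
#' Draws exactly `n0` class-0 and `n1` class-1 samples under the block
#' model configured by `config`. Heterogeneous blocks: class-1 samples are
#' assigned to one of `c` subclasses uniformly at random; each
#' heterogeneous block is tied to one subclass (blocks cycle through the
#' subclasses), and only the class-1 samples of that subclass draw the
#' block from the class-1 marker distribution — the rest look like class 0.
#'
#' @param config a [synthetic_config()].
#' @param n0,n1 per-class sample counts.
#' @param seed optional override of `config$seed`.
#' @return list with `data` (labeled [expr_matrix()], class-0 samples
#'   first) and `truth` (list: `marker_type` per feature, `block_id` per
#'   feature (`NA` for HV), `subclass_of_block`, `subclass` per class-1
#'   sample, and `true_interacting_pairs` — a two-column matrix of
#'   within-block marker pairs, empty when the two class covariances agree).
#' @export
generate_expression <- function(config, n0, n1, seed = config$seed) {
  if (!inherits(config, "synthetic_config")) stop("config must be a synthetic_config")
  if (n0 < 1L || n1 < 1L) stop("need at least one sample per class")
  k <- config$block_size
  n <- n0 + n1
  mu1 <- block_mean(k, config$mean_type)
  s0 <- sqrt(config$var0); s1 <- sqrt(config$var1)
  withr::with_seed(seed, {
    R0 <- equicorr_chol(k, config$rho0)
    R1 <- equicorr_chol(k, config$rho1)
    cols <- list(); types <- character(0); block_ids <- integer(0)
    blk <- 0L
    subclass <- sample.int(config$subclass_count, n1, replace = TRUE)
    subclass_of_block <- integer(0)
    # global marker blocks
    for (b in seq_len(config$n_global %/% k)) {
      blk <- blk + 1L
      X <- matrix(0, n, k)
      X[seq_len(n0), ] <- rmvn_chol(n0, rep(0, k), s0, R0)
      X[n0 + seq_len(n1), ] <- rmvn_chol(n1, mu1, s1, R1)
      cols <- c(cols, list(X))
      types <- c(types, rep("global", k)); block_ids <- c(block_ids, rep(blk, k))
    }
    # heterogeneous marker blocks
    n_hblocks <- config$n_hetero %/% k
    for (b in seq_len(n_hblocks)) {
      blk <- blk + 1L
      sc <- ((b - 1L) %% config$subclass_count) + 1L
      subclass_of_block <- c(subclass_of_block, stats::setNames(sc, blk))
      X <- matrix(0, n, k)
      X[seq_len(n0), ] <- rmvn_chol(n0, rep(0, k), s0, R0)
      hot <- which(subclass == sc)
      cold <- setdiff(seq_len(n1), hot)
      if (length(hot))
        X[n0 + hot, ] <- rmvn_chol(length(hot), mu1, s1, R1)
      if (length(cold))
        X[n0 + cold, ] <- rmvn_chol(length(cold), rep(0, k), s0, R0)
      cols <- c(cols, list(X))
      types <- c(types, rep("hetero", k)); block_ids <- c(block_ids, rep(blk, k))
    }
    # low-variance non-markers: class-0 marker distribution in both classes
    n_lv_left <- config$n_lv
    while (n_lv_left > 0L) {
      blk <- blk + 1L
      kk <- min(k, n_lv_left); n_lv_left <- n_lv_left - kk
      Rb <- if (kk == k) R0 else equicorr_chol(kk, config$rho0)
      X <- rmvn_chol(n, rep(0, kk), s0, Rb)
      cols <- c(cols, list(X))
      types <- c(types, rep("lv", kk)); block_ids <- c(block_ids, rep(blk, kk))
    }
    # high-variance non-markers: independent per-feature Gaussian mixtures
    if (config$n_hv > 0L) {
      pmix <- stats::runif(config$n_hv)
      comp <- matrix(stats::runif(n * config$n_hv), n, config$n_hv)
      from0 <- sweep(comp, 2, pmix) <= 0
      X <- matrix(stats::rnorm(n * config$n_hv), n, config$n_hv)
      X <- ifelse(from0, X * s0, X * s1 + 1)
      cols <- c(cols, list(X))
      types <- c(types, rep("hv", config$n_hv))
      block_ids <- c(block_ids, rep(NA_integer_, config$n_hv))
    }
    values <- do.call(cbind, cols)
  })
  feature_ids <- sprintf("F%04d", seq_len(ncol(values)))
  colnames(values) <- feature_ids
  rownames(values) <- sprintf("S%04d", seq_len(n))
  labels <- c(rep(0L, n0), rep(1L, n1))
  data <- expr_matrix(values, labels = labels)
  # ground truth: within-block marker pairs interact iff the class-conditional
  # bivariate covariances differ and the correlations are not both zero
  cov_differ <- (config$var0 != config$var1) || (config$rho0 != config$rho1)
  both_rho_zero <- (config$rho0 == 0 && config$rho1 == 0)
  pairs <- matrix(character(0), 0L, 2L)
  if (cov_differ && !both_rho_zero && k > 1L) {
    marker <- types %in% c("global", "hetero")
    for (b in unique(block_ids[marker])) {
      in_blk <- feature_ids[marker & !is.na(block_ids) & block_ids == b]
      if (length(in_blk) > 1L) pairs <- rbind(pairs, pairs_among(in_blk))
    }
  }
  truth <- list(marker_type = stats::setNames(types, feature_ids),
                block_id = stats::setNames(block_ids, feature_ids),
                subclass_of_block = subclass_of_block,
                subclass = subclass,
                true_interacting_pairs = pairs)
  list(data = data, truth = truth)
}

#' Preset generator configurations for the benchmark scenarios
#'
#' All four scenarios share `var0 = 0.25`, `var1 = 0.64`, `k = 10`, `c = 2`
#' and differ in the class-1 mean type and the within-block correlations:
#' (1) synergetic, `rho0 = rho1 = 0.5`; (2) synergetic, `rho0 = 0.1`,
#' `rho1 = 0.9`; (3) marginal, `rho0 = rho1 = 0.5`; (4) marginal,
#' `rho0 = 0.1`, `rho1 = 0.9`.
#'
#' The `"classifier"` preset uses 60 features, all heterogeneous markers.
#' The `"mtm"` preset uses 5000 features — 20 global markers, 80
#' heterogeneous markers, 2000 high-variance non-markers, remainder
#' low-variance; `total_features` rescales it keeping the 20 + 80 markers,
#' 40% of the total as HV non-markers, and the remainder LV.
#'
#' @param id scenario number in 1..4.
#' @param preset `"classifier"` or `"mtm"`.
#' @param total_features optional size override for the `"mtm"` preset.
#' @param overrides named list of [synthetic_config()] arguments applied
#'   after the preset.
#' @param seed generator seed.
#' @return a [synthetic_config()].
#' @export
scenario <- function(id, preset = c("classifier", "mtm"), total_features = NULL,
                     overrides = list(), seed = 1L) {
  preset <- match.arg(preset)
  if (!(length(id) == 1L && id %in% 1:4)) stop("scenario id must be 1, 2, 3 or 4")
  base <- list(block_size = 10L, subclass_count = 2L, var0 = 0.25, var1 = 0.64,
               seed = seed)
  base$mean_type <- if (id %in% c(1, 2)) "synergetic" else "marginal"
  if (id %in% c(1, 3)) { base$rho0 <- 0.5; base$rho1 <- 0.5 }
  else { base$rho0 <- 0.1; base$rho1 <- 0.9 }
  if (preset == "classifier") {
    base$n_global <- 0L; base$n_hetero <- 60L; base$n_lv <- 0L; base$n_hv <- 0L
  } else {
    total <- as.integer(total_features %||% 5000L)
    if (total < 100L) stop("mtm preset needs at least the 100 marker features")
    base$n_global <- 20L; base$n_hetero <- 80L
    base$n_hv <- as.integer(round(0.4 * total))
    base$n_lv <- total - 100L - base$n_hv
    if (base$n_lv < 0L) { base$n_hv <- total - 100L; base$n_lv <- 0L }
  }
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  do.call(synthetic_config, base)
}
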
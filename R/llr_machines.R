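# Regularized Gaussian discriminant log-likelihood-ratio machines for
# feature subsets of size 1 or 2. These are the "external mechanism" the
# HDMR classifiers consume: each machine reports
#   L(x_u) = log N(x_u; mu1, Sigma1_reg) - log N(x_u; mu0, Sigma0_reg),
# without a class-prior term (the decision threshold T absorbs it).

#' Fit a per-feature or per-pair Gaussian log-likelihood-ratio machine
#'
#' Class-conditional means and unbiased covariances are estimated and then
#' shrunk toward the scaled identity: `Sigma_reg = (1 - lambda) * Sigma +
#' lambda * (tr(Sigma)/p) * I`. With `kind = "linear"` the raw class
#' covariances are first pooled with weights `(n_y - 1)/(n0 + n1 - 2)`
#' (RLDA-style, one shared covariance); with `kind = "quadratic"` each class
#' keeps its own (RQDA-style). A variance floor of `1e-8` times each
#' feature's overall sample variance (or `1e-8` absolute for constant
#' features) keeps the covariances positive definite.
#'
#' @param train a labeled [expr_matrix()] with at least 2 samples per class.
#' @param u character vector of 1 or 2 feature IDs.
#' @param kind `"linear"` (pooled covariance) or `"quadratic"` (per class).
#' @param lambda shrinkage intensity in \[0, 1\].
#' @return An object of class `gaussian_llr` holding `u`, `kind`, `lambda`,
#'   per-class means `mu0`/`mu1` and regularized covariances
#'   `sigma0`/`sigma1` (equal for `kind = "linear"`), plus cached inverses.
#' @export
fit_gaussian_llr <- function(train, u, kind = c("quadratic", "linear"), lambda = 0) {
  kind <- match.arg(kind)
  check_two_classes(train, min_per_class = 2L)
  if (!(length(u) %in% 1:2)) stop("feature subset must have 1 or 2 members")
  if (!all(u %in% colnames(train$values)))
    stop("unknown feature(s): ", paste(setdiff(u, colnames(train$values)), collapse = ", "))
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda >= 0 && lambda <= 1))
    stop("lambda must be a single value in [0, 1]")
  X <- train$values[, u, drop = FALSE]
  y <- train$labels
  p <- length(u)
  X0 <- X[y == 0L, , drop = FALSE]; X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S0 <- stats::cov(X0); S1 <- stats::cov(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  if (kind == "linear") {
    Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
    S0 <- S1 <- Sp
  }
  shrink <- function(S) (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  S0 <- shrink(S0); S1 <- shrink(S1)
  # variance floor relative to the overall spread of each feature
  overall_var <- apply(X, 2, stats::var)
  floor_ <- ifelse(overall_var > 0, 1e-8 * overall_var, 1e-8)
  fix <- function(S) {
    d <- pmax(diag(S), floor_)
    diag(S) <- d
    if (p == 2L) {
      # cap |correlation| so the 2x2 matrix stays strictly PD
      rmax <- (1 - 1e-6) * sqrt(d[1] * d[2])
      S[1, 2] <- S[2, 1] <- sign(S[1, 2]) * min(abs(S[1, 2]), rmax)
    }
    S
  }
  if (all(overall_var == 0))
    stop("zero total variance for feature subset: ", paste(u, collapse = ", "))
  S0 <- fix(S0); S1 <- fix(S1)
  m <- structure(list(u = u, kind = kind, lambda = lambda,
                      mu0 = mu0, mu1 = mu1, sigma0 = S0, sigma1 = S1),
                 class = "gaussian_llr")
  finalize_machine(m)
}

# cache inverses and log-determinants for fast scoring
finalize_machine <- function(m) {
  p <- length(m$u)
  prep <- function(S) {
    S <- as.matrix(S)
    if (p == 1L) list(inv = 1 / S[1, 1], logdet = log(S[1, 1]))
    else {
      dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
      list(inv = matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / dt,
           logdet = log(dt))
    }
  }
  m$prep0 <- prep(m$sigma0)
  m$prep1 <- prep(m$sigma1)
  m
}

#' @export
print.gaussian_llr <- function(x, ...) {
  cat("gaussian_llr machine on {", paste(x$u, collapse = ", "), "}, kind = ",
      x$kind, ", lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

# vectorized MVN log-density for p in {1, 2} given a prepped machine side
mvn_logpdf_prep <- function(X, mu, prep) {
  p <- length(mu)
  if (p == 1L) {
    z <- X[, 1] - mu[1]
    -0.5 * (log(2 * pi) + prep$logdet + z * z * prep$inv)
  } else {
    z1 <- X[, 1] - mu[1]; z2 <- X[, 2] - mu[2]
    q <- prep$inv[1, 1] * z1 * z1 + 2 * prep$inv[1, 2] * z1 * z2 +
      prep$inv[2, 2] * z2 * z2
    -0.5 * (2 * log(2 * pi) + prep$logdet + q)
  }
}

#' Evaluate the log-likelihood ratio of a machine at one or many points
#'
#' Returns `log N(x_u; mu1, Sigma1) - log N(x_u; mu0, Sigma0)`. The
#' class-prior log-ratio is deliberately excluded; the decision threshold
#' `T` plays that role downstream.
#'
#' @param machine a `gaussian_llr` from [fit_gaussian_llr()].
#' @param x a numeric vector of length `|u|` (a single point), or an
#'   `n x |u|` matrix of points. For univariate machines a vector is a
#'   vector of points.
#' @return numeric vector of LLR values, one per point.
#' @export
llr_score <- function(machine, x) {
  p <- length(machine$u)
  if (is.null(dim(x))) {
    if (p == 2L) {
      if (length(x) != 2L) stop("expected a point of length 2")
      x <- matrix(x, 1L, 2L)
    } else x <- matrix(x, ncol = 1L)
  }
  if (ncol(x) != p) stop("point dimension ", ncol(x), " != machine dimension ", p)
  if (!all(is.finite(x))) stop("non-finite values in x")
  unname(mvn_logpdf_prep(x, machine$mu1, machine$prep1) -
           mvn_logpdf_prep(x, machine$mu0, machine$prep0))
}

#' Assemble the second-order HDMR feature vector V(x)
#'
#' Single-feature coordinates are the machines' LLRs `S(X_f)`; each pair
#' coordinate is the excess of the pair LLR over its two marginals,
#' `S(X_fi,fj) = L(x_fi,fj) - S(X_fi) - S(X_fj)`, which vanishes when the
#' pair machine factorizes into the two marginal machines.
#'
#' @param x named numeric vector of feature values for one sample (names are
#'   feature IDs), or a samples x features matrix with column names.
#' @param single_machines named list of univariate `gaussian_llr` machines
#'   (names = feature IDs).
#' @param pair_machines named list of bivariate machines (names = canonical
#'   pair keys, members joined by `"|"`).
#' @return For a single sample, a list with named numeric vectors
#'   `single_terms` and `pair_terms`. For a matrix input, a numeric matrix
#'   with one row per sample and one column per term (features first, then
#'   pairs).
#' @export
build_V <- function(x, single_machines, pair_machines = list()) {
  single_input <- is.null(dim(x))
  if (single_input) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  feats <- names(single_machines)
  if (is.null(feats) && length(single_machines))
    stop("single_machines must be a named list")
  missing <- setdiff(feats, colnames(x))
  if (length(missing)) stop("sample lacks feature(s): ", paste(missing, collapse = ", "))
  n <- nrow(x)
  S_single <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  for (f in feats) S_single[, f] <- llr_score(single_machines[[f]], x[, f])
  pk <- names(pair_machines)
  S_pair <- matrix(0, n, length(pk), dimnames = list(NULL, pk))
  for (key in pk) {
    mc <- pair_machines[[key]]
    u <- mc$u
    if (!all(u %in% feats))
      stop("pair ", key, " needs single machines for both members ",
           "(the pair term subtracts both marginal LLRs)")
    S_pair[, key] <- llr_score(mc, x[, u, drop = FALSE]) -
      S_single[, u[1]] - S_single[, u[2]]
  }
  if (single_input)
    list(single_terms = S_single[1, ], pair_terms = S_pair[1, ])
  else cbind(S_single, S_pair)
}
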
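# Shared fixtures and independent oracles for the test suite.

# brute-force multivariate normal log-density (generic solve/det; used as the
# independent oracle for the machines' cached-inverse fast path)
oracle_mvn_logpdf <- function(x, mu, S) {
  x <- as.numeric(x); mu <- as.numeric(mu)
  p <- length(mu)
  z <- x - mu
  -0.5 * (p * log(2 * pi) + log(det(as.matrix(S))) +
            drop(t(z) %*% solve(S, z)))
}

# labeled matrix with prescribed per-class sample sets (one feature per column)
toy_matrix <- function(class0, class1, feature_ids = NULL) {
  X0 <- as.matrix(class0); X1 <- as.matrix(class1)
  vals <- rbind(X0, X1)
  if (!is.null(feature_ids)) colnames(vals) <- feature_ids
  expr_matrix(vals, labels = c(rep(0L, nrow(X0)), rep(1L, nrow(X1))))
}

# two-sample univariate fixture whose fitted moments are exact round numbers:
# class 0 = {mu0 - a0, mu0 + a0} has mean mu0 and unbiased variance 2 a0^2
two_point_classes <- function(mu0, mu1, var0, var1, feature = "g1") {
  a0 <- sqrt(var0 / 2); a1 <- sqrt(var1 / 2)
  toy_matrix(matrix(c(mu0 - a0, mu0 + a0), 2, 1),
             matrix(c(mu1 - a1, mu1 + a1), 2, 1), feature)
}

# vectors of length n with sample correlation exactly r (n >= 3)
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  xc <- scale(x)[, 1]
  ec <- residuals(lm(e ~ xc)); ec <- scale(ec)[, 1]
  y <- r * xc + sqrt(1 - r^2) * ec
  list(x = x, y = y)
}

# random small labeled Gaussian matrix
random_matrix <- function(n0, n1, p, seed = 1) {
  set.seed(seed)
  toy_matrix(matrix(rnorm(n0 * p), n0, p), matrix(rnorm(n1 * p), n1, p),
             paste0("g", seq_len(p)))
}

# samples x 2 matrix with exactly the requested sample mean and covariance
exact_moments_2d <- function(n, mu, S, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 2), n, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))   # whiten: sample cov = I
  sweep(Z %*% chol(S), 2, mu, `+`)
}
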
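test_that("Pearson test matches the t-distribution closed form and cor.test", {
  # exact r = 0.5 at n = 10: t = 0.5 sqrt(8 / 0.75) ~ 1.633, p ~ 0.141
  xy <- exact_corr_pair(10, 0.5, seed = 7)
  res <- pearson_independence_p(xy$x, xy$y)
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-0.5 * sqrt(8 / 0.75), df = 8), tolerance = 1e-12)
  expect_equal(res$p, 0.14111328, tolerance = 1e-6)

  # perfect correlation degenerates to p = 0; r = 0 gives p = 1
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_independence_p(x, x), list(r = 1, p = 0))
  xy0 <- exact_corr_pair(12, 0, seed = 8)
  expect_equal(pearson_independence_p(xy0$x, xy0$y)$p, 1, tolerance = 1e-12)

  # independent oracle: cor.test on random draws
  set.seed(9)
  for (rep in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    ct <- cor.test(a, b)
    res <- pearson_independence_p(a, b)
    expect_equal(res$p, unname(ct$p.value), tolerance = 1e-10)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_error(pearson_independence_p(1:3, 2:4), "at least 4")
  expect_error(pearson_independence_p(rep(1, 5), rnorm(5)), "constant")
})

test_that("Fisher combination matches the chi-square(4) survival function", {
  expect_equal(fisher_combine(1, 1), list(C = 0, p = 1))
  fc <- fisher_combine(0.5, 0.5)
  expect_equal(fc$C, -2 * log(0.25), tolerance = 1e-12)
  expect_equal(fc$p, exp(-fc$C / 2) * (1 + fc$C / 2), tolerance = 1e-12)
  expect_equal(fc$p, 0.5966, tolerance = 1e-4)
  # monotone decreasing in each argument; vectorized; robust at p = 0
  ps <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(fisher_combine(ps, 0.3)$p) > 0))
  expect_true(is.finite(fisher_combine(0, 0.5)$C))
})

test_that("covariance-equality test reproduces the Box's M closed form", {
  # exact sample covariances: S0 = I, S1 = diag(4, 4), n0 = n1 = 21
  X0 <- exact_moments_2d(21, c(0, 0), diag(2), seed = 11)
  X1 <- exact_moments_2d(21, c(0, 0), diag(c(4, 4)), seed = 12)
  M <- 40 * log(det(2.5 * diag(2))) - 20 * log(1) - 20 * log(16)
  c1 <- (13 / 18) * (1 / 20 + 1 / 20 - 1 / 40)
  expect_equal(cov_equality_p(X0, X1),
               pchisq((1 - c1) * M, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # equal sample covariances -> M = 0 -> p = 1
  expect_equal(cov_equality_p(X0, X0 + 5), 1)  # shift does not change cov
  expect_error(cov_equality_p(X0[1:3, ], X1), "at least 4")
  sing <- cbind(1:10, 2 * (1:10))
  expect_error(cov_equality_p(sing, X1), "singular")
})

test_that("outlier flagging implements the 3-scaled-MAD rule", {
  v <- c(1:10, 1000)
  res <- remove_outliers(v)
  expect_identical(res$removed, 11L)  # cutoff = 6 + 3 * 1.4826 * 3 ~ 19.3
  expect_identical(res$kept, as.numeric(1:10))
  same <- remove_outliers(rep(2, 6))
  expect_length(same$removed, 0)  # MAD = 0 guard
  tight <- remove_outliers(c(-1, -0.5, 0, 0.5, 1))
  expect_length(tight$removed, 0)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  p_eq <- rep(0.03, 5)
  expect_equal(bh_adjust(p_eq), p_eq)
  set.seed(13)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
  expect_true(all(q >= p))
  # explicit m larger than the vector (untestable pairs still counted)
  expect_equal(bh_adjust(c(0.01, 0.02), m = 4), p.adjust(c(0.01, 0.02, 1, 1),
                                                         method = "BH")[1:2])
})

test_that("single-pair MTM combines the two p-values by the capped sum", {
  set.seed(17)
  m <- random_matrix(25, 25, 4, seed = 17)
  res <- mtm_pair_test(m, "g1", "g2")
  expect_true(res$testable)
  expect_equal(res$p_combined, min(1, res$p_fisher + res$p_cov))
  expect_gte(res$p_combined, max(res$p_fisher, res$p_cov))
  expect_equal(res$C, -2 * (log(res$p_indep_0) + log(res$p_indep_1)),
               tolerance = 1e-12)
  # tiny class after cleaning -> untestable, not an error
  small <- random_matrix(25, 3, 3, seed = 19)
  expect_error(run_mtm(small), ">= 4")
})

test_that("the vectorized sweep agrees with the per-pair route exactly", {
  set.seed(23)
  X <- matrix(rnorm(36 * 8), 36, 8)
  X[4, 2] <- 40; X[30, 7] <- -35  # inject outliers to exercise the masks
  m <- expr_matrix(X, labels = rep(0:1, times = c(16, 20)))
  sweep_res <- run_mtm(m)$results
  fields <- c("rho_0", "rho_1", "p_indep_0", "p_indep_1", "C", "p_fisher",
              "p_cov", "p_combined")
  for (r in seq_len(nrow(sweep_res))) {
    single <- mtm_pair_test(m, sweep_res$gene_i[r], sweep_res$gene_j[r])
    for (f in fields)
      expect_equal(sweep_res[[f]][r], single[[f]], tolerance = 1e-10)
    expect_equal(sweep_res$n_used_0[r], single$n_used_0)
    expect_equal(sweep_res$n_used_1[r], single$n_used_1)
  }
})

test_that("the sweep enumerates C(p,2) pairs and ignores gene ordering", {
  m <- random_matrix(10, 10, 4, seed = 29)
  res <- run_mtm(m)
  expect_equal(res$n_pairs, 6)
  expect_equal(nrow(res$results), 6)
  expect_equal(pair_count(13211), 87258655)

  perm <- expr_matrix(m$values[, c(3, 1, 4, 2)], labels = m$labels)
  res_p <- run_mtm(perm)
  key <- function(df) paste(pmin(df$gene_i, df$gene_j), pmax(df$gene_i, df$gene_j))
  a <- res$results[order(key(res$results)), ]
  b <- res_p$results[order(key(res_p$results)), ]
  expect_equal(a$p_combined, b$p_combined, tolerance = 1e-12)
  expect_equal(a$q_bh, b$q_bh, tolerance = 1e-12)
})

test_that("constant features are untestable and excluded from the BH denominator", {
  set.seed(31)
  X <- cbind(matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("g", 1:4))),
             const = rep(1, 20))
  m <- expr_matrix(X, labels = rep(0:1, each = 10))
  res <- run_mtm(m)
  const_rows <- res$results$gene_i == "const" | res$results$gene_j == "const"
  expect_true(all(!res$results$testable[const_rows]))
  expect_equal(res$m_tested, sum(!const_rows))
  expect_true(all(is.na(res$results$q_bh[const_rows])))
})

test_that("null pairs are conservative: rejection rate at alpha stays below alpha", {
  set.seed(37)
  reps <- 40
  pvals <- numeric(0)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(50 * 6), 50, 6)  # equal covariance in both classes
    m <- expr_matrix(X, labels = rep(0:1, each = 25))
    res <- run_mtm(m)$results
    pvals <- c(pvals, res$p_combined[res$testable])
  }
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha), alpha + 2 * sqrt(alpha / length(pvals)))
})

test_that("the pair graph assigns each gene its minimum incident p-value", {
  sim <- generate_expression(scenario(2, preset = "mtm", total_features = 120,
                                      seed = 41), 40, 40)
  res <- run_mtm(sim$data)
  g <- pair_graph(res, top_n = 10)
  expect_equal(nrow(g$genes), 10)
  tested <- res$results[res$results$testable, ]
  for (gene in g$genes$gene) {
    inc <- tested$p_combined[tested$gene_i == gene | tested$gene_j == gene]
    expect_equal(g$genes$min_p[g$genes$gene == gene], min(inc))
  }
  expect_true(all(g$edges$weight >= 0))
  expect_true(all(g$edges$gene_i %in% g$genes$gene))
  # a single dominant pair yields a 2-node, 1-edge graph
  tiny <- tested[order(tested$p_combined), ][1, ]
  g2 <- pair_graph(res, top_n = 2)
  expect_lte(nrow(g2$genes), 2)
})
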
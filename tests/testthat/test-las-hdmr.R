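test_that("feature risks equal the between-class mean LLR difference", {
  # engineered univariate machines give exactly known resubstitution LLRs:
  # linear machine mu0 = 0, mu1 = 1, pooled var 1 -> L(x) = x - 0.5
  m <- two_point_classes(0, 1, 1, 1)
  mc <- fit_gaussian_llr(m, "g1", kind = "linear", lambda = 0)
  risks <- compute_feature_risks(m, list(g1 = mc))
  # class-1 LLRs: {1 - a - .5, 1 + a - .5}, class-0: {-a - .5, a - .5}
  expect_equal(unname(risks["g1"]), 1)

  # hand oracle on random data: recompute the same mean difference directly
  rm <- random_matrix(7, 9, 3, seed = 41)
  machines <- lapply(setNames(nm = colnames(rm$values)),
                     function(f) fit_gaussian_llr(rm, f, lambda = 0.2))
  risks2 <- compute_feature_risks(rm, machines)
  for (f in names(machines)) {
    L <- llr_score(machines[[f]], rm$values[, f])
    expect_equal(unname(risks2[f]),
                 mean(L[rm$labels == 1]) - mean(L[rm$labels == 0]))
  }

  # identical class sample sets give zero risk
  X <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "g1"))
  same <- expr_matrix(rbind(X, X), labels = rep(0:1, each = 6))
  mc3 <- fit_gaussian_llr(same, "g1", lambda = 0.1)
  expect_equal(unname(compute_feature_risks(same, list(g1 = mc3))["g1"]), 0)
  # relabeling the classes flips the LLR sign AND the class means, so the
  # risk itself is invariant (the score antisymmetry shows up in R(X), not r)
  sw <- rm; sw$labels <- 1L - rm$labels
  machines_sw <- lapply(setNames(nm = colnames(sw$values)),
                        function(f) fit_gaussian_llr(sw, f, lambda = 0.2))
  expect_equal(compute_feature_risks(sw, machines_sw), risks2,
               tolerance = 1e-12)
})

test_that("pair risks subtract both member risks and vanish under factorization", {
  rm <- random_matrix(10, 10, 2, seed = 43)
  machines <- lapply(setNames(nm = c("g1", "g2")),
                     function(f) fit_gaussian_llr(rm, f, lambda = 0))
  r_f <- compute_feature_risks(rm, machines)
  pairm <- fit_gaussian_llr(rm, c("g1", "g2"), lambda = 0)
  r_p <- compute_pair_risks(rm, list("g1|g2" = pairm), r_f)
  L <- llr_score(pairm, rm$values[, c("g1", "g2")])
  expect_equal(unname(r_p["g1|g2"]),
               mean(L[rm$labels == 1]) - mean(L[rm$labels == 0]) -
                 r_f["g1"] - r_f["g2"], ignore_attr = TRUE)
  expect_error(compute_pair_risks(rm, list("g1|g2" = pairm), r_f["g1"]),
               "missing feature risk")

  # diagonal pair machine consistent with the marginals -> zero pair risk
  pairm$sigma0 <- diag(c(machines$g1$sigma0[1, 1], machines$g2$sigma0[1, 1]))
  pairm$sigma1 <- diag(c(machines$g1$sigma1[1, 1], machines$g2$sigma1[1, 1]))
  pairm$mu0 <- c(machines$g1$mu0, machines$g2$mu0)
  pairm$mu1 <- c(machines$g1$mu1, machines$g2$mu1)
  pairm <- hdmr2:::finalize_machine(pairm)
  expect_equal(unname(compute_pair_risks(rm, list("g1|g2" = pairm), r_f)), 0,
               tolerance = 1e-9)
})

test_that("screening is strict and requires both pair members to survive", {
  r_f <- c(g1 = 0.5, g2 = 0.2, g3 = 0.9)
  r_p <- c("g1|g2" = 5, "g1|g3" = 0.4, "g2|g3" = 5)
  sel <- screen_risks(r_f, r_p, T1 = 0.3, T2 = 0.1)
  expect_identical(sel$features, c("g1", "g3"))
  expect_identical(sel$pairs, "g1|g3")  # pairs touching g2 die with it

  # threshold equality removes (strict inequality)
  expect_identical(screen_risks(c(a = 1, b = 2), T1 = 1, T2 = 0)$features, "b")
  # T1 = -Inf, T2 = Inf -> first-order model over everything
  sel2 <- screen_risks(r_f, r_p, T1 = -Inf, T2 = Inf)
  expect_identical(sel2$features, names(r_f))
  expect_length(sel2$pairs, 0)
  expect_error(screen_risks(c(a = 0), T1 = 5), "lower T1/T2")
})

test_that("raising T1 or T2 never adds selections (monotone nesting)", {
  set.seed(47)
  r_f <- setNames(rnorm(10), paste0("g", 1:10))
  keys <- apply(combn(paste0("g", 1:10), 2), 2, paste, collapse = "|")
  r_p <- setNames(rnorm(length(keys)), keys)
  grid <- sort(c(-Inf, quantile(r_f, c(.2, .5, .8))))
  prev <- NULL
  for (T1 in grid) {
    sel <- tryCatch(screen_risks(r_f, r_p, T1, 0.2), error = function(e) NULL)
    if (!is.null(prev) && !is.null(sel)) {
      expect_true(all(sel$features %in% prev$features))
      expect_true(all(sel$pairs %in% prev$pairs))
    }
    prev <- sel
  }
})

test_that("closed-form weights maximize the between-class projection gap", {
  V <- rbind(c(0, 0), c(3, 4))
  expect_equal(solve_weights(V, c(0, 1)), c(0.6, 0.8))
  expect_equal(solve_weights(matrix(c(0, -2), 2, 1), c(0, 1)), -1)
  expect_error(solve_weights(rbind(c(1, 1), c(1, 1)), c(0, 1)),
               "indistinguishable")

  # random-search oracle on the unit sphere
  set.seed(53)
  for (rep in 1:5) {
    d <- 5
    V <- matrix(rnorm(20 * d), 20, d)
    y <- rep(0:1, each = 10)
    b <- solve_weights(V, y)
    expect_equal(sum(b^2), 1, tolerance = 1e-9)
    gap <- function(bb) mean(V[y == 1, ] %*% bb) - mean(V[y == 0, ] %*% bb)
    B <- matrix(rnorm(1e4 * d), 1e4, d)
    B <- B / sqrt(rowSums(B^2))
    diffs <- colMeans(V[y == 1, ]) - colMeans(V[y == 0, ])
    expect_gte(gap(b), max(B %*% diffs))
  }
})

test_that("scores are the b*.V dot product and labels use a strict threshold", {
  sim <- generate_expression(scenario(2, seed = 61), 12, 12)
  model <- train_las_hdmr(sim$data, hdmr_params(T1 = 0, T2 = 0.1, lambda = 0.5))
  x <- sim$data$values[1, ]
  V <- build_V(x, model$single_machines[model$selected_features],
               model$pair_machines[model$selected_pairs])
  manual <- sum(model$b_star * c(V$single_terms[model$selected_features],
                                 V$pair_terms[model$selected_pairs])[model$coordinate_order])
  expect_equal(unname(hdmr_score(model, x)), manual, tolerance = 1e-12)

  s <- hdmr_score(model, x)
  expect_identical(hdmr_classify(model, x, T = s), 0L)        # R = T -> class 0
  expect_identical(hdmr_classify(model, x, T = s - 1e-9), 1L)
  expect_identical(hdmr_classify(model, x, T = -Inf), 1L)
  expect_error(hdmr_score(model, x[-1]), "lacks feature")
})

test_that("with pairs suppressed the model reduces to the univariate LLR rule", {
  # single strong marker: identical test-set ROC to the raw feature LLR
  set.seed(67)
  X0 <- cbind(rnorm(25, 0, 1), rnorm(25))
  X1 <- cbind(rnorm(25, 2, 1), rnorm(25))
  m <- toy_matrix(X0, X1, c("marker", "noise"))
  model <- train_las_hdmr(m, hdmr_params(T1 = 0.2, T2 = Inf, lambda = 0))
  expect_identical(model$selected_features, "marker")
  expect_length(model$selected_pairs, 0)
  te <- toy_matrix(cbind(rnorm(50, 0, 1), rnorm(50)),
                   cbind(rnorm(50, 2, 1), rnorm(50)), c("marker", "noise"))
  mc <- model$single_machines[["marker"]]
  expect_equal(roc_auc(hdmr_score(model, te$values), te$labels)$auc,
               roc_auc(llr_score(mc, te$values[, "marker"]), te$labels)$auc)
})

test_that("column permutation with matching IDs leaves scores unchanged", {
  sim <- generate_expression(scenario(3, seed = 71), 15, 15)
  model <- train_las_hdmr(sim$data, hdmr_params(T1 = 0, T2 = 0.1, lambda = 0.5))
  te <- generate_expression(scenario(3, seed = 72), 20, 20)$data
  perm <- sample(ncol(te$values))
  expect_equal(hdmr_score(model, te$values[, perm]),
               hdmr_score(model, te$values), tolerance = 1e-12)
})

test_that("label swap in training flips the induced ordering (AUC -> 1 - AUC)", {
  sim <- generate_expression(scenario(2, seed = 73), 15, 15)
  sw <- sim$data; sw$labels <- 1L - sw$labels
  p <- hdmr_params(T1 = -Inf, T2 = 0, lambda = 0.5)
  te <- generate_expression(scenario(2, seed = 74), 100, 100)$data
  a1 <- roc_auc(hdmr_score(train_las_hdmr(sim$data, p), te$values), te$labels)$auc
  a2 <- roc_auc(hdmr_score(train_las_hdmr(sw, p), te$values), te$labels)$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-9)
})

test_that("label-permuted training yields chance-level held-out AUC", {
  cfg <- scenario(2, seed = 79)
  aucs <- numeric(20)
  for (r in 1:20) {
    sim <- generate_expression(cfg, 20, 20, seed = 1000 + r)
    perm <- sim$data
    set.seed(2000 + r)
    perm$labels <- sample(perm$labels)
    model <- train_las_hdmr(perm, hdmr_params(T1 = 0, T2 = 0.05, lambda = 0.5))
    te <- generate_expression(cfg, 250, 250, seed = 3000 + r)$data
    aucs[r] <- roc_auc(hdmr_score(model, te$values), te$labels)$auc
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("CV tuning is deterministic and respects the tie-breaking rules", {
  sim <- generate_expression(scenario(2, seed = 83), 20, 20)
  base <- hdmr_params(lambda = 0.5)
  single <- tune_hdmr(sim$data, list(T1 = 0, T2 = 0.05), base, folds = 3, seed = 5)
  expect_equal(single$T1, 0)
  expect_equal(single$T2, 0.05)

  dup <- tune_hdmr(sim$data, list(T1 = c(0, 0), T2 = 0.05), base,
                   folds = 3, seed = 5)
  expect_equal(dup[c("T1", "T2")], single[c("T1", "T2")])

  grids <- list(T1 = c(0, 0.2), T2 = c(0.05, 0.2))
  tuned <- tune_hdmr(sim$data, grids, base, folds = 3, seed = 5)
  tab <- attr(tuned, "cv_table")
  expect_equal(nrow(tab), 4)
  # the winner attains the maximal mean out-of-fold AUC
  expect_equal(max(tab$mean_auc),
               tab$mean_auc[tab$T1 == tuned$T1 & tab$T2 == tuned$T2])
  # an absurd grid point that empties the model scores 0.5, never errors
  wild <- tune_hdmr(sim$data, list(T1 = c(0, 1e6), T2 = 0.05), base,
                    folds = 3, seed = 5)
  wtab <- attr(wild, "cv_table")
  expect_equal(wtab$mean_auc[wtab$T1 == 1e6], 0.5)
})
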
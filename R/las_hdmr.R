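# LAS-HDMR: linear approximation of the second-order HDMR expansion of the
# log-likelihood ratio. Pipeline: fit per-feature and per-pair LLR machines,
# compute between-class risks, screen weak features/pairs, assemble V(x),
# solve the unit-norm weight vector in closed form, threshold R(X) = b*.V(X).

#' Bundle LAS/LABS-HDMR training parameters
#'
#' @param T1 feature risk threshold: features with risk `r_f <= T1` are
#'   removed (strict `>` keeps).
#' @param T2 pair risk magnitude threshold (`>= 0`): pairs with
#'   `|r_pair| <= T2` are removed.
#' @param T3 block risk threshold (`>= 0`), used by LABS-HDMR only.
#' @param T decision threshold on the score `R(X)`; `NULL` means "set to the
#'   midpoint of the training-score class means at fit time".
#' @param kind,lambda machine family and shrinkage passed to
#'   [fit_gaussian_llr()].
#' @param pairs_over `"survivors"` fits pair machines only among features
#'   surviving `T1` (default; quadratic cost in the survivor count);
#'   `"all"` fits all feature pairs.
#' @return A list of class `hdmr_params`.
#' @export
hdmr_params <- function(T1 = -Inf, T2 = 0, T3 = 0, T = NULL,
                        kind = c("quadratic", "linear"), lambda = 0.5,
                        pairs_over = c("survivors", "all")) {
  kind <- match.arg(kind); pairs_over <- match.arg(pairs_over)
  if (T2 < 0 || T3 < 0) stop("T2 and T3 must be >= 0")
  structure(list(T1 = T1, T2 = T2, T3 = T3, T = T, kind = kind,
                 lambda = lambda, pairs_over = pairs_over),
            class = "hdmr_params")
}

# between-class mean difference of an LLR column matrix (resubstitution)
risk_from_llr <- function(L, labels) {
  L <- as.matrix(L)
  colMeans(L[labels == 1L, , drop = FALSE]) -
    colMeans(L[labels == 0L, , drop = FALSE])
}

#' Per-feature risks
#'
#' The risk of a feature is the class-1 training mean of its machine's LLR
#' minus the class-0 training mean (resubstitution values: machines are fit
#' on the full training set and evaluated on it). Positive risk means the
#' feature's LLR separates the classes in the expected direction.
#'
#' @param train labeled [expr_matrix()].
#' @param machines named list of univariate `gaussian_llr` machines.
#' @return named numeric vector of risks `r_f`.
#' @export
compute_feature_risks <- function(train, machines) {
  check_two_classes(train)
  feats <- names(machines)
  L <- vapply(feats, function(f) llr_score(machines[[f]], train$values[, f]),
              numeric(nrow(train$values)))
  risks <- risk_from_llr(matrix(L, ncol = length(feats)), train$labels)
  stats::setNames(risks, feats)
}

#' Per-pair risks
#'
#' The pair risk is the between-class mean difference of the pair machine's
#' LLR minus both member feature risks — equivalently the between-class mean
#' difference of the interaction term `S(X_fi,fj)`. It is 0 whenever the
#' pair machine factorizes into the two marginals.
#'
#' @param train labeled [expr_matrix()].
#' @param pair_machines named list of bivariate machines (canonical keys).
#' @param feature_risks named vector from [compute_feature_risks()]; must
#'   cover both members of every pair.
#' @return named numeric vector of pair risks.
#' @export
compute_pair_risks <- function(train, pair_machines, feature_risks) {
  check_two_classes(train)
  keys <- names(pair_machines)
  out <- stats::setNames(numeric(length(keys)), keys)
  for (key in keys) {
    mc <- pair_machines[[key]]
    u <- mc$u
    if (!all(u %in% names(feature_risks)))
      stop("missing feature risk for member(s) of pair ", key)
    L <- llr_score(mc, train$values[, u, drop = FALSE])
    out[key] <- risk_from_llr(L, train$labels) -
      feature_risks[u[1]] - feature_risks[u[2]]
  }
  out
}

#' Screen features and pairs by risk
#'
#' Features are kept iff `r_f > T1` (strict); pairs are kept iff
#' `|r_pair| > T2` (strict) and both members survived the feature screen.
#'
#' @param feature_risks,pair_risks named risk vectors.
#' @param T1,T2 thresholds.
#' @return list with `features` and `pairs` (character vectors of IDs/keys).
#' @export
screen_risks <- function(feature_risks, pair_risks = numeric(0), T1, T2) {
  keep_f <- names(feature_risks)[feature_risks > T1]
  keep_p <- character(0)
  if (length(pair_risks)) {
    members <- do.call(rbind, split_pair_key(names(pair_risks)))
    both_in <- members[, 1] %in% keep_f & members[, 2] %in% keep_f
    keep_p <- names(pair_risks)[abs(pair_risks) > T2 & both_in]
  }
  if (length(keep_f) + length(keep_p) == 0L)
    stop("screening removed every feature and pair; lower T1/T2")
  list(features = keep_f, pairs = keep_p)
}

#' Solve the unit-norm weight vector
#'
#' Maximizes the between-class gap of the projected training V vectors,
#' `mean(b.V | y=1) - mean(b.V | y=0)` over the unit sphere. The maximizer
#' is the normalized between-class mean difference `d / ||d||_2`
#' (Cauchy-Schwarz).
#'
#' @param V_train numeric matrix, rows = training samples, columns = V
#'   coordinates.
#' @param labels 0/1 vector.
#' @return unit-norm numeric vector `b*` (named as the columns of `V_train`).
#' @export
solve_weights <- function(V_train, labels) {
  V_train <- as.matrix(V_train)
  labels <- as.integer(labels)
  if (!any(labels == 0L) || !any(labels == 1L)) stop("need both classes")
  d <- colMeans(V_train[labels == 1L, , drop = FALSE]) -
    colMeans(V_train[labels == 0L, , drop = FALSE])
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("classes indistinguishable in V space (zero mean difference)")
  d / nd
}

# V matrix for an hdmr_model at a set of samples (samples x features matrix)
model_V <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  missing <- setdiff(unique(unlist(lapply(model$single_machines, `[[`, "u"))),
                     colnames(x))
  if (length(missing))
    stop("sample lacks feature value(s): ", paste(missing, collapse = ", "))
  if (identical(model$variant, "labs")) {
    V <- build_block_V(x, model$blocks, model$single_machines, model$pair_machines,
                       selected_features = model$selected_features)
  } else {
    V <- build_V(x, model$single_machines[model$selected_features],
                 model$pair_machines[model$selected_pairs])
  }
  V[, model$coordinate_order, drop = FALSE]
}

#' Score samples with a fitted HDMR model
#'
#' @param model an `hdmr_model`.
#' @param x named numeric vector (one sample) or samples x features matrix.
#' @return numeric vector `R(X) = b* . V(X)`, one value per sample.
#' @export
hdmr_score <- function(model, x) {
  V <- model_V(model, x)
  drop(V %*% model$b_star)
}

#' Classify samples with a fitted HDMR model
#'
#' Assigns label 1 iff `R(X) > T` strictly.
#'
#' @param model an `hdmr_model`.
#' @param x sample vector or matrix.
#' @param T decision threshold; defaults to the model's fitted threshold.
#' @return integer vector of 0/1 labels.
#' @export
hdmr_classify <- function(model, x, T = model$params$T) {
  as.integer(hdmr_score(model, x) > T)
}

#' @export
predict.hdmr_model <- function(object, newdata, type = c("score", "label"),
                               T = object$params$T, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expr_matrix")) newdata <- newdata$values
  if (type == "score") hdmr_score(object, newdata)
  else hdmr_classify(object, newdata, T = T)
}

#' @export
print.hdmr_model <- function(x, ...) {
  cat(if (identical(x$variant, "labs")) "LABS-HDMR" else "LAS-HDMR",
      " model: ", length(x$selected_features), " features",
      sep = "")
  if (identical(x$variant, "labs")) {
    nb <- length(x$blocks$P_risk) + length(x$blocks$N_risk)
    cat(", ", nb, " blocks", sep = "")
  } else cat(", ", length(x$selected_pairs), " pairs", sep = "")
  cat("; T1 = ", x$params$T1, ", T2 = ", x$params$T2,
      if (identical(x$variant, "labs")) paste0(", T3 = ", x$params$T3),
      ", T = ", signif(x$params$T, 4), "\n", sep = "")
  invisible(x)
}

# fit univariate machines for all candidate features
fit_single_machines <- function(train, features, kind, lambda) {
  ms <- lapply(features, function(f) fit_gaussian_llr(train, f, kind, lambda))
  stats::setNames(ms, features)
}

fit_pair_machines <- function(train, pairs_members, kind, lambda) {
  keys <- apply(pairs_members, 1L, paste, collapse = "|")
  ms <- lapply(seq_len(nrow(pairs_members)), function(r)
    fit_gaussian_llr(train, pairs_members[r, ], kind, lambda))
  stats::setNames(ms, keys)
}

# all unordered pairs (canonical order) among `features`, as a 2-col matrix
pairs_among <- function(features) {
  n <- length(features)
  if (n < 2L) return(matrix(character(0), 0L, 2L))
  idx <- utils::combn(n, 2L)
  cbind(features[idx[1, ]], features[idx[2, ]])
}

#' Train a LAS-HDMR classifier
#'
#' Fits univariate LLR machines for every candidate feature, computes
#' feature risks, fits pair machines (over `T1` survivors by default),
#' computes pair risks, screens both by `T1`/`T2`, assembles the training V
#' matrix, and solves the closed-form unit-norm weights. The decision
#' threshold `T`, when not supplied, is set to the midpoint between the
#' class means of the training scores.
#'
#' @param train labeled [expr_matrix()] with >= 2 samples per class.
#' @param params an [hdmr_params()] bundle.
#' @param candidates optional character vector restricting the candidate
#'   feature set (default: all features).
#' @return An object of class `hdmr_model`.
#' @export
train_las_hdmr <- function(train, params = hdmr_params(), candidates = NULL) {
  check_two_classes(train, min_per_class = 2L)
  feats <- candidates %||% colnames(train$values)
  sm <- fit_single_machines(train, feats, params$kind, params$lambda)
  r_f <- compute_feature_risks(train, sm)
  survivors <- names(r_f)[r_f > params$T1]
  pair_basis <- if (params$pairs_over == "survivors") survivors else feats
  pm <- list(); r_p <- numeric(0)
  members <- pairs_among(pair_basis)
  if (nrow(members)) {
    pm <- fit_pair_machines(train, members, params$kind, params$lambda)
    r_p <- compute_pair_risks(train, pm, r_f)
  }
  sel <- screen_risks(r_f, r_p, params$T1, params$T2)
  coord_order <- c(sel$features, sel$pairs)
  V <- build_V(train$values, sm[sel$features], pm[sel$pairs])
  V <- V[, coord_order, drop = FALSE]
  b <- solve_weights(V, train$labels)
  scores <- drop(V %*% b)
  if (is.null(params$T))
    params$T <- (mean(scores[train$labels == 1L]) +
                   mean(scores[train$labels == 0L])) / 2
  keep_feats <- union(sel$features,
                      unique(unlist(split_pair_key(sel$pairs))))
  model <- list(variant = "las", params = unclass(params),
                selected_features = sel$features,
                selected_pairs = sel$pairs,
                blocks = NULL,
                coordinate_order = coord_order,
                b_star = stats::setNames(b, coord_order),
                single_machines = sm[keep_feats],
                pair_machines = pm[sel$pairs],
                risks = list(r_f = r_f, r_pair = r_p))
  class(model) <- "hdmr_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (y in c(0L, 1L)) {
      idx <- which(labels == y)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Grid-search cross-validation for LAS/LABS-HDMR parameters
#'
#' Stratified k-fold CV; each grid point is scored by its mean out-of-fold
#' AUC of `R(X)`. A grid point whose screening empties the model scores 0.5
#' (it never aborts the search). Ties are broken toward fewer selected
#' coordinates, then toward the lexicographically smaller `(T1, T2, T3)`.
#'
#' @param train labeled [expr_matrix()].
#' @param grids named list of parameter grids; recognized names are `T1`,
#'   `T2`, `T3`, `lambda`, `kind`. Unlisted parameters keep the value in
#'   `base_params`.
#' @param base_params an [hdmr_params()] supplying fixed parameters.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param variant `"las"` or `"labs"`.
#' @return the winning [hdmr_params()], with the CV table in attribute
#'   `"cv_table"`.
#' @export
tune_hdmr <- function(train, grids, base_params = hdmr_params(), folds = 5L,
                      seed = 1L, variant = c("las", "labs")) {
  variant <- match.arg(variant)
  if (!length(grids)) stop("grids must be non-empty")
  grid_df <- unique(expand.grid(grids, stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
  fold <- stratified_folds(train$labels, folds, seed)
  trainer <- if (variant == "labs") train_labs_hdmr else train_las_hdmr
  n_grid <- nrow(grid_df)
  auc <- numeric(n_grid); ncoord <- numeric(n_grid)
  for (g in seq_len(n_grid)) {
    p <- base_params
    for (nm in colnames(grid_df)) p[[nm]] <- grid_df[[nm]][g]
    fold_auc <- rep(NA_real_, folds); fold_nc <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- expr_matrix(train$values[fold != f, , drop = FALSE],
                        labels = train$labels[fold != f])
      te_x <- train$values[fold == f, , drop = FALSE]
      te_y <- train$labels[fold == f]
      if (length(unique(te_y)) < 2L || length(unique(tr$labels)) < 2L) next
      res <- tryCatch({
        model <- trainer(tr, p)
        list(auc = roc_auc(hdmr_score(model, te_x), te_y)$auc,
             nc = length(model$coordinate_order))
      }, error = function(e) list(auc = 0.5, nc = 0))
      fold_auc[f] <- res$auc; fold_nc[f] <- res$nc
    }
    auc[g] <- mean(fold_auc, na.rm = TRUE)
    ncoord[g] <- mean(fold_nc, na.rm = TRUE)
  }
  key_T1 <- if ("T1" %in% colnames(grid_df)) grid_df$T1 else rep(base_params$T1, n_grid)
  key_T2 <- if ("T2" %in% colnames(grid_df)) grid_df$T2 else rep(base_params$T2, n_grid)
  key_T3 <- if ("T3" %in% colnames(grid_df)) grid_df$T3 else rep(base_params$T3, n_grid)
  ord <- order(-auc, ncoord, key_T1, key_T2, key_T3, method = "radix")
  best <- ord[1]
  p <- base_params
  for (nm in colnames(grid_df)) p[[nm]] <- grid_df[[nm]][best]
  attr(p, "cv_table") <- cbind(grid_df, mean_auc = auc, mean_coords = ncoord)
  p
}

#' Default risk-percentile grids for CV tuning
#'
#' `T1` candidates are percentiles of the observed feature-risk
#' distribution, `T2`/`T3` percentiles of the absolute pair-risk
#' distribution, computed from a preliminary fit with the base parameters.
#'
#' @param train labeled [expr_matrix()].
#' @param params machine parameters used for the preliminary risk pass.
#' @param probs percentile probabilities (default 0, .25, .5, .75).
#' @return named list of grids usable with [tune_hdmr()].
#' @export
default_risk_grids <- function(train, params = hdmr_params(),
                               probs = c(0, 0.25, 0.5, 0.75)) {
  p0 <- params; p0$T1 <- -Inf; p0$T2 <- 0
  model <- train_las_hdmr(train, p0)
  list(T1 = unname(stats::quantile(model$risks$r_f, probs)),
       T2 = unname(stats::quantile(abs(model$risks$r_pair), probs)))
}
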
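# LABS-HDMR: block extension of LAS-HDMR. Surviving feature pairs are
# merged into per-feature risk-increasing (P) and risk-decreasing (N)
# blocks; each surviving block contributes a single V coordinate equal to
# the mean interaction term S(X_fi,fj) over its member pairs. Because a
# pair (fi, fj) with |risk| > T2 belongs to both fi's and fj's block, every
# surviving pair is counted in exactly two blocks.

#' Build risk-increasing and risk-decreasing blocks
#'
#' For each feature `fi`, `P[fi]` collects the partners `fj` with pair risk
#' `> T2` and `N[fi]` those with pair risk `< -T2` (strict). Block risks are
#' the arithmetic means of the member-pair risks.
#'
#' @param pair_risks named numeric vector of pair risks (canonical keys).
#' @param T2 pair risk magnitude threshold (`>= 0`).
#' @return A list of class `block_set`: `P_blocks`/`N_blocks` (named lists
#'   of partner-feature vectors; empty blocks absent) and `P_risk`/`N_risk`
#'   (named numeric vectors of block risks).
#' @export
build_blocks <- function(pair_risks, T2) {
  if (T2 < 0) stop("T2 must be >= 0")
  P_blocks <- list(); N_blocks <- list()
  P_members <- list(); N_members <- list()  # pair keys per block
  if (length(pair_risks)) {
    members <- do.call(rbind, split_pair_key(names(pair_risks)))
    for (r in seq_along(pair_risks)) {
      fi <- members[r, 1]; fj <- members[r, 2]; v <- pair_risks[r]
      key <- names(pair_risks)[r]
      if (v > T2) {
        P_blocks[[fi]] <- c(P_blocks[[fi]], fj); P_members[[fi]] <- c(P_members[[fi]], key)
        P_blocks[[fj]] <- c(P_blocks[[fj]], fi); P_members[[fj]] <- c(P_members[[fj]], key)
      } else if (v < -T2) {
        N_blocks[[fi]] <- c(N_blocks[[fi]], fj); N_members[[fi]] <- c(N_members[[fi]], key)
        N_blocks[[fj]] <- c(N_blocks[[fj]], fi); N_members[[fj]] <- c(N_members[[fj]], key)
      }
    }
  }
  block_risk <- function(mem) vapply(mem, function(k) mean(pair_risks[k]), numeric(1))
  structure(list(P_blocks = P_blocks, N_blocks = N_blocks,
                 P_members = P_members, N_members = N_members,
                 P_risk = block_risk(P_members), N_risk = block_risk(N_members)),
            class = "block_set")
}

#' Prune weak blocks
#'
#' Keeps a risk-increasing block iff its mean risk `> T3` (strict) and a
#' risk-decreasing block iff its mean risk `< -T3` (strict).
#'
#' @param blocks a `block_set` from [build_blocks()].
#' @param T3 block risk threshold (`>= 0`).
#' @return the pruned `block_set`.
#' @export
prune_blocks <- function(blocks, T3) {
  if (T3 < 0) stop("T3 must be >= 0")
  keep_P <- names(blocks$P_risk)[blocks$P_risk > T3]
  keep_N <- names(blocks$N_risk)[blocks$N_risk < -T3]
  structure(list(P_blocks = blocks$P_blocks[keep_P],
                 N_blocks = blocks$N_blocks[keep_N],
                 P_members = blocks$P_members[keep_P],
                 N_members = blocks$N_members[keep_N],
                 P_risk = blocks$P_risk[keep_P],
                 N_risk = blocks$N_risk[keep_N]),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("block_set: ", length(x$P_risk), " risk-increasing / ",
      length(x$N_risk), " risk-decreasing blocks\n", sep = "")
  invisible(x)
}

# block coordinate names: "P|fi" / "N|fi"
block_coord_names <- function(blocks) {
  c(if (length(blocks$P_risk)) paste0("P|", names(blocks$P_risk)),
    if (length(blocks$N_risk)) paste0("N|", names(blocks$N_risk)))
}

#' Assemble the block-averaged HDMR feature vector
#'
#' Single-feature coordinates are the LLRs of the `selected_features`
#' machines (as in LAS-HDMR); each surviving block contributes one
#' coordinate equal to the mean of its member pairs' interaction terms
#' `S(X_fi,fj)`.
#'
#' @param x named sample vector or samples x features matrix.
#' @param blocks a (pruned) `block_set`.
#' @param single_machines named list of univariate machines covering all
#'   selected features and all block-pair members.
#' @param pair_machines named list of bivariate machines covering every
#'   member pair of every block.
#' @param selected_features features contributing their own V coordinate.
#' @return numeric matrix, one row per sample; columns = selected features
#'   then block coordinates (`"P|f"`, `"N|f"`).
#' @export
build_block_V <- function(x, blocks, single_machines, pair_machines,
                          selected_features = names(single_machines)) {
  needed_pairs <- unique(c(unlist(blocks$P_members), unlist(blocks$N_members)))
  missing <- setdiff(needed_pairs, names(pair_machines))
  if (length(missing))
    stop("missing pair machine(s) for block member pair(s): ",
         paste(missing, collapse = ", "))
  V_full <- build_V(x, single_machines, pair_machines[needed_pairs])
  n <- nrow(V_full)
  Vs <- V_full[, selected_features, drop = FALSE]
  coords <- block_coord_names(blocks)
  Vb <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  for (f in names(blocks$P_risk))
    Vb[, paste0("P|", f)] <- rowMeans(V_full[, blocks$P_members[[f]], drop = FALSE])
  for (f in names(blocks$N_risk))
    Vb[, paste0("N|", f)] <- rowMeans(V_full[, blocks$N_members[[f]], drop = FALSE])
  cbind(Vs, Vb)
}

#' Train a LABS-HDMR classifier
#'
#' Same pipeline as [train_las_hdmr()] up to pair screening, after which
#' surviving pairs are merged into per-feature risk-increasing/decreasing
#' blocks, weak blocks are pruned with `T3`, and the weight vector is
#' solved over the block-averaged V coordinates. With no surviving block
#' the model reduces to the first-order model over `T1` survivors.
#'
#' @inheritParams train_las_hdmr
#' @return An `hdmr_model` with `variant = "labs"`.
#' @export
train_labs_hdmr <- function(train, params = hdmr_params(), candidates = NULL) {
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
  # blocks over the surviving pairs only, then weak-block pruning
  blocks <- build_blocks(r_p[sel$pairs], params$T2)
  blocks <- prune_blocks(blocks, params$T3)
  coord_order <- c(sel$features, block_coord_names(blocks))
  if (!length(coord_order))
    stop("screening removed every feature and block; lower T1/T2/T3")
  needed_pairs <- unique(c(unlist(blocks$P_members), unlist(blocks$N_members)))
  keep_feats <- union(sel$features, unique(unlist(split_pair_key(needed_pairs))))
  V <- build_block_V(train$values, blocks, sm[keep_feats], pm[needed_pairs],
                     selected_features = sel$features)
  V <- V[, coord_order, drop = FALSE]
  b <- solve_weights(V, train$labels)
  scores <- drop(V %*% b)
  if (is.null(params$T))
    params$T <- (mean(scores[train$labels == 1L]) +
                   mean(scores[train$labels == 0L])) / 2
  model <- list(variant = "labs", params = unclass(params),
                selected_features = sel$features,
                selected_pairs = sel$pairs,
                blocks = blocks,
                coordinate_order = coord_order,
                b_star = stats::setNames(b, coord_order),
                single_machines = sm[keep_feats],
                pair_machines = pm[needed_pairs],
                risks = list(r_f = r_f, r_pair = r_p))
  class(model) <- "hdmr_model"
  model
}
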
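#' Construct a labeled expression matrix
#'
#' The canonical data container of the package: a numeric matrix in
#' samples x features orientation, with unique sample and feature IDs and,
#' optionally, binary class labels (0 = reference class, 1 = case class)
#' attached per sample.
#'
#' @param values numeric matrix, rows = samples, columns = features;
#'   dimnames are used as sample/feature IDs when `sample_ids`/`feature_ids`
#'   are not given.
#' @param labels optional integer vector in \{0, 1\}, one per sample, or a
#'   named vector matched to sample IDs.
#' @param sample_ids,feature_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the samples x features matrix, dimnames set) and `labels` (integer
#'   vector or `NULL`).
#' @export
expr_matrix <- function(values, labels = NULL, sample_ids = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length (", length(sample_ids), ") != sample count (", nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length (", length(feature_ids), ") != feature count (", ncol(values), ")")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", sample_ids[bad[1]], "', feature '",
         feature_ids[bad[2]], "'")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  obj <- structure(list(values = values, labels = NULL), class = "expr_matrix")
  if (!is.null(labels)) obj <- set_labels(obj, labels)
  obj
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " samples x ", ncol(x$values), " features",
      sep = "")
  if (!is.null(x$labels)) {
    n1 <- sum(x$labels == 1L)
    cat("; labels: ", sum(x$labels == 0L), " class-0 / ", n1, " class-1", sep = "")
  } else cat("; unlabeled")
  cat("\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

set_labels <- function(m, labels) {
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(m$values), names(labels))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "))
    unknown <- setdiff(names(labels), rownames(m$values))
    if (length(unknown))
      stop("label(s) for unknown sample(s): ", paste(unknown, collapse = ", "))
    labels <- labels[rownames(m$values)]
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(m$values))
    stop("labels length (", length(labels), ") != sample count (", nrow(m$values), ")")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  m$labels <- labels
  m
}

# error early on ops that need both classes
check_two_classes <- function(m, min_per_class = 1L) {
  if (is.null(m$labels)) stop("expression matrix has no labels attached")
  n0 <- sum(m$labels == 0L); n1 <- sum(m$labels == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("single class: training requires samples from both classes")
  if (n0 < min_per_class || n1 < min_per_class)
    stop("each class needs >= ", min_per_class, " samples (have ", n0, "/", n1, ")")
  invisible(m)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects one header line and one leading ID column. The result is always
#' in the canonical samples x features orientation; use
#' `orientation = "features_in_rows"` for the common genes-in-rows layout.
#' Delimiter is taken from the extension (`.csv` = comma, otherwise tab).
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @return An unlabeled [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows", "features_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expected an ID column plus at least one data column")
  hdr <- colnames(df)[-1]
  if (anyDuplicated(hdr))  # check before [,-1] silently uniquifies names
    stop("duplicate column IDs in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at row '", ids[bad[1]], "', column '",
         colnames(num)[bad[2]], "' (value '", mat[bad[1], bad[2]], "')")
  }
  if (orientation == "features_in_rows") num <- t(num)
  expr_matrix(num)
}

#' Write an expression matrix to delimited text
#'
#' @param m an [expr_matrix()].
#' @param path output path; extension selects the delimiter.
#' @param orientation layout to write (IDs of the rows go in the first column).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path,
                                    orientation = c("samples_in_rows", "features_in_rows")) {
  orientation <- match.arg(orientation)
  v <- m$values
  if (orientation == "features_in_rows") v <- t(v)
  id_col <- if (orientation == "samples_in_rows") "sample_id" else "feature_id"
  df <- data.frame(rownames(v), format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(v))
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach class labels to an expression matrix
#'
#' Labels are aligned to samples by ID, never by file order.
#'
#' @param m an [expr_matrix()].
#' @param labels a two-column data frame (`sample_id`, `label`) or the path
#'   of a two-column TSV/CSV with those columns.
#' @return `m` with `labels` filled in.
#' @export
attach_labels <- function(m, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- utils::read.table(labels, header = TRUE, sep = delim_for(labels),
                                check.names = FALSE, quote = "",
                                colClasses = "character")
  }
  labels <- as.data.frame(labels)
  if (ncol(labels) < 2) stop("labels need two columns: sample_id, label")
  lab <- suppressWarnings(as.numeric(labels[[2]]))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    bad <- labels[[1]][is.na(lab) | !(lab %in% c(0, 1))]
    stop("label outside {0,1} for sample(s): ", paste(bad, collapse = ", "))
  }
  set_labels(m, stats::setNames(as.integer(lab), as.character(labels[[1]])))
}

#' Read a probe-to-gene map
#'
#' Two-column TSV/CSV (`probe_id`, `gene_id`). Probes with an empty or `NA`
#' gene field are kept in the table but flagged unmapped; probes listed with
#' more than one distinct gene are an error.
#'
#' @param path file path.
#' @return data frame with columns `probe_id`, `gene_id`, `mapped` (logical).
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, quote = "", colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("probe map needs two columns: probe_id, gene_id")
  out <- data.frame(probe_id = df[[1]], gene_id = df[[2]], stringsAsFactors = FALSE)
  out$mapped <- !is.na(out$gene_id)
  mapped <- out[out$mapped, ]
  ngene <- tapply(mapped$gene_id, mapped$probe_id, function(g) length(unique(g)))
  multi <- names(ngene)[ngene > 1]
  if (length(multi))
    stop("probe(s) mapped to more than one gene: ", paste(multi, collapse = ", "))
  out
}

#' Write an MTM pair table
#'
#' Rows are sorted ascending by combined p-value, ties broken by the
#' (gene_i, gene_j) pair IDs lexicographically.
#'
#' @param results data frame of pair test results as produced by [run_mtm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(results, path) {
  cols <- c("gene_i", "gene_j", "p_fisher", "p_cov", "p_combined", "q_bh")
  if (is.null(results) || nrow(as.data.frame(results)) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  results <- as.data.frame(results)
  missing <- setdiff(cols, colnames(results))
  if (length(missing)) stop("pair table lacks column(s): ", paste(missing, collapse = ", "))
  ord <- order(results$p_combined, results$gene_i, results$gene_j, method = "radix")
  out <- results[ord, cols]
  num <- c("p_fisher", "p_cov", "p_combined", "q_bh")
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a pair table written by [write_pair_table()]
#' @param path TSV path.
#' @return data frame with the pair table columns.
#' @export
read_pair_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Serialize a fitted HDMR model to a structured text document
#'
#' The document (JSON) contains thresholds, selected feature/pair/block IDs,
#' the unit weight vector, and all fitted Gaussian machine parameters, so a
#' model reloaded in a later session reproduces its scores exactly.
#'
#' @param model an `hdmr_model` from [train_las_hdmr()] or [train_labs_hdmr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hdmr_model <- function(model, path) {
  ser_machine <- function(mc) {
    list(u = mc$u, kind = mc$kind, lambda = mc$lambda,
         mu0 = as.numeric(mc$mu0), mu1 = as.numeric(mc$mu1),
         sigma0 = as.numeric(mc$sigma0), sigma1 = as.numeric(mc$sigma1))
  }
  blocks_ser <- NULL
  if (!is.null(model$blocks)) {
    b <- model$blocks
    blocks_ser <- list(P_blocks = b$P_blocks, N_blocks = b$N_blocks,
                       P_members = b$P_members, N_members = b$N_members,
                       P_risk = as.list(b$P_risk), N_risk = as.list(b$N_risk))
  }
  doc <- list(
    package = "hdmr2", format = 1L, variant = model$variant,
    params = model$params[c("T1", "T2", "T3", "T", "kind", "lambda", "pairs_over")],
    selected_features = model$selected_features,
    selected_pairs = if (length(model$selected_pairs)) model$selected_pairs else list(),
    blocks = blocks_ser,
    coordinate_order = model$coordinate_order,
    b_star = as.numeric(model$b_star),
    single_machines = lapply(model$single_machines, ser_machine),
    pair_machines = lapply(model$pair_machines, ser_machine)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load an HDMR model document
#' @param path path written by [write_hdmr_model()].
#' @return an `hdmr_model` object.
#' @export
read_hdmr_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(doc$package, "hdmr2")) stop("not an hdmr2 model document")
  de_machine <- function(mc) {
    p <- length(mc$u)
    m <- list(u = as.character(mc$u), kind = mc$kind, lambda = mc$lambda,
              mu0 = as.numeric(mc$mu0), mu1 = as.numeric(mc$mu1),
              sigma0 = matrix(as.numeric(mc$sigma0), p, p),
              sigma1 = matrix(as.numeric(mc$sigma1), p, p))
    class(m) <- "gaussian_llr"
    finalize_machine(m)
  }
  pm <- lapply(doc$pair_machines, de_machine)
  sm <- lapply(doc$single_machines, de_machine)
  blocks <- doc$blocks
  if (!is.null(blocks)) {
    blocks$P_blocks <- lapply(blocks$P_blocks, as.character)
    blocks$N_blocks <- lapply(blocks$N_blocks, as.character)
    blocks$P_members <- lapply(blocks$P_members, as.character)
    blocks$N_members <- lapply(blocks$N_members, as.character)
    blocks$P_risk <- unlist_named(blocks$P_risk)
    blocks$N_risk <- unlist_named(blocks$N_risk)
    class(blocks) <- "block_set"
  }
  sel_pairs <- doc$selected_pairs
  if (is.list(sel_pairs) && length(sel_pairs) == 0L) sel_pairs <- character(0)
  # jsonlite writes infinities as strings; coerce numeric params back
  for (nm in c("T1", "T2", "T3", "T", "lambda"))
    doc$params[[nm]] <- as.numeric(doc$params[[nm]])
  model <- list(variant = doc$variant, params = doc$params,
                selected_features = as.character(doc$selected_features),
                selected_pairs = as.character(sel_pairs),
                blocks = blocks,
                coordinate_order = as.character(doc$coordinate_order),
                b_star = as.numeric(doc$b_star),
                single_machines = sm, pair_machines = pm)
  class(model) <- "hdmr_model"
  model
}

unlist_named <- function(x) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(unlist(x)), names(x))
}

# canonical unordered pair key: member IDs in feature-index order, "|" separated
pair_key <- function(i, j, feature_ids) {
  pi <- match(i, feature_ids); pj <- match(j, feature_ids)
  if (anyNA(c(pi, pj))) stop("unknown feature in pair: ", i, ", ", j)
  if (pi == pj) stop("pair members must differ: ", i)
  if (pi < pj) paste0(i, "|", j) else paste0(j, "|", i)
}

split_pair_key <- function(key) {
  if (is.null(key) || length(key) == 0L) return(list())
  strsplit(key, "|", fixed = TRUE)
}
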
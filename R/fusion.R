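BLOCK_ORDER <- c("DL", "CKSNAP", "PCPseDNC", "DCC")

#' Fuse feature blocks into one matrix
#'
#' Column-wise concatenation of feature blocks in the canonical order
#' DL, CKSNAP, PCPseDNC, DCC (ablated subsets keep that order). A registry
#' records which column range belongs to which encoder.
#'
#' @param blocks List of [feature_block()]s with equal row counts and
#'   distinct canonical names.
#' @return A \code{fused_matrix}: list with \code{matrix} (n x D) and
#'   \code{registry} (data.frame: block, start, end; 1-based inclusive
#'   column ranges tiling 1..D).
#' @export
fuse <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  names(blocks) <- vapply(blocks, function(b) b$name, "")
  unknown <- setdiff(names(blocks), BLOCK_ORDER)
  if (length(unknown))
    stop("unknown block name(s): ", paste(unknown, collapse = ", "),
         "; fusable blocks are ", paste(BLOCK_ORDER, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(blocks)))
    stop("duplicate block names", call. = FALSE)
  blocks <- blocks[order(match(names(blocks), BLOCK_ORDER))]
  nr <- vapply(blocks, function(b) nrow(b$matrix), 0L)
  if (length(unique(nr)) != 1L)
    stop("row-count mismatch across blocks: ",
         paste(nr, collapse = ", "), call. = FALSE)
  mat <- do.call(cbind, lapply(blocks, function(b) b$matrix))
  widths <- vapply(blocks, function(b) ncol(b$matrix), 0L)
  ends <- cumsum(widths)
  registry <- data.frame(block = names(blocks),
                         start = ends - widths + 1L, end = ends,
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(matrix = mat, registry = registry), class = "fused_matrix")
}

#' @export
print.fused_matrix <- function(x, ...) {
  cat("fused_matrix:", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  print(x$registry)
  invisible(x)
}

#' Extract one block from a fused matrix
#' @param fused A [fuse()] result.
#' @param block Block name.
#' @return The block's feature matrix.
#' @export
fused_slice <- function(fused, block) {
  r <- fused$registry[fused$registry$block == block, ]
  if (nrow(r) != 1L) stop("block not present: ", block, call. = FALSE)
  fused$matrix[, r$start:r$end, drop = FALSE]
}

#' Shapley additive attributions for a fitted model
#'
#' Per-sample additive feature attributions: a base value plus one value per
#' feature whose sum equals the model output for that sample (local
#' accuracy). For boosted-tree models the attributions are exact TreeSHAP
#' values on the raw margin (log-odds), computed by the tree engine's
#' path-dependent algorithm. For any other model a seeded permutation
#' sampling estimator over a background set is used.
#'
#' @param model A \code{boost_model}, or any object for which
#'   \code{predict_fun} is supplied.
#' @param X Feature matrix (a \code{fused_matrix} or plain matrix) in the
#'   model's feature space.
#' @param background Background matrix for the sampling estimator (defaults
#'   to up to 100 seeded rows of \code{X}).
#' @param predict_fun For non-tree models: \code{function(matrix) -> numeric}.
#' @param n_perm Permutations per sample for the sampling estimator.
#' @param seed Seed for the sampling estimator.
#' @return An \code{attribution_report}: list with \code{base_value},
#'   \code{attributions} (n x D), \code{mean_abs}, \code{feature_names};
#'   ranking/mask slots filled by [rank_and_select()].
#' @export
shapley_attributions <- function(model, X, background = NULL,
                                 predict_fun = NULL, n_perm = 50L,
                                 seed = 1L) {
  if (inherits(X, "fused_matrix")) X <- X$matrix
  stopifnot(is.matrix(X))
  if (inherits(model, "boost_model")) {
    Xc <- check_feature_space(model, X)
    contrib <- stats::predict(model$booster,
                              xgboost::xgb.DMatrix(Xc, nthread = 1L),
                              predcontrib = TRUE)
    d <- ncol(Xc)
    attr_mat <- contrib[, seq_len(d), drop = FALSE]
    base <- contrib[1L, d + 1L]
  } else {
    if (is.null(predict_fun))
      stop("predict_fun required for non-tree models", call. = FALSE)
    if (is.null(background))
      background <- X[with_seed(seed,
        sample.int(nrow(X), min(100L, nrow(X)))), , drop = FALSE]
    if (nrow(background) == 0L) stop("empty background set", call. = FALSE)
    if (ncol(background) != ncol(X))
      stop("feature count mismatch between X and background", call. = FALSE)
    res <- shapley_sampling(predict_fun, X, background, n_perm, seed)
    attr_mat <- res$attributions
    base <- res$base_value
  }
  colnames(attr_mat) <- colnames(X)
  structure(list(base_value = base, attributions = attr_mat,
                 mean_abs = colMeans(abs(attr_mat)),
                 feature_names = colnames(X),
                 ranking = NULL, selected_mask = NULL, top_k = NULL),
            class = "attribution_report")
}

# Permutation-sampling Shapley estimator (Strumbelj & Kononenko): for each
# sample and permutation, features are switched one by one from a random
# background row to the sample's values; the output increment is the
# feature's contribution for that permutation.
shapley_sampling <- function(predict_fun, X, background, n_perm, seed) {
  d <- ncol(X)
  base <- mean(predict_fun(background))
  attr_mat <- matrix(0, nrow(X), d)
  with_seed(seed, {
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      acc <- numeric(d)
      for (p in seq_len(n_perm)) {
        perm <- sample.int(d)
        b <- background[sample.int(nrow(background), 1L), ]
        cur <- b
        prev <- predict_fun(matrix(cur, 1L, d))
        for (j in perm) {
          cur[j] <- x[j]
          val <- predict_fun(matrix(cur, 1L, d))
          acc[j] <- acc[j] + (val - prev)
          prev <- val
        }
      }
      attr_mat[i, ] <- acc / n_perm
    }
  })
  list(base_value = base, attributions = attr_mat)
}

#' Rank features by mean |attribution| and select the top k
#'
#' Ranking is deterministic: descending mean absolute attribution, ties
#' broken by ascending column index. The mask selects the first
#' \code{top_k} ranked features (all features when \code{top_k >= D}).
#'
#' @param report An [shapley_attributions()] report.
#' @param top_k Number of features to keep (>= 1).
#' @return The report with \code{ranking}, \code{selected_mask} and
#'   \code{top_k} filled in.
#' @export
rank_and_select <- function(report, top_k) {
  stopifnot(inherits(report, "attribution_report"))
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  d <- length(report$mean_abs)
  top_k <- min(as.integer(top_k), d)
  ranking <- order(-report$mean_abs, seq_len(d))
  mask <- logical(d)
  mask[ranking[seq_len(top_k)]] <- TRUE
  report$ranking <- ranking
  report$selected_mask <- mask
  report$top_k <- top_k
  report
}

#' Attribution report as a table
#'
#' One row per feature: name, block (when a fused registry is given),
#' mean absolute attribution, rank and selection flag. Written with
#' \code{write.table(..., sep = "\t")} this mirrors a plot-ready top-K
#' importance summary.
#'
#' @param report A ranked [rank_and_select()] report.
#' @param fused Optional \code{fused_matrix} supplying the block registry.
#' @return A data.frame sorted by rank.
#' @export
attribution_table <- function(report, fused = NULL) {
  stopifnot(inherits(report, "attribution_report"))
  d <- length(report$mean_abs)
  block <- rep(NA_character_, d)
  if (!is.null(fused))
    for (i in seq_len(nrow(fused$registry)))
      block[fused$registry$start[i]:fused$registry$end[i]] <-
        fused$registry$block[i]
  rk <- if (is.null(report$ranking)) order(-report$mean_abs, seq_len(d))
        else report$ranking
  pos <- integer(d); pos[rk] <- seq_len(d)
  df <- data.frame(feature = report$feature_names, block = block,
                   mean_abs = report$mean_abs, rank = pos,
                   selected = if (is.null(report$selected_mask)) NA
                              else report$selected_mask,
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$rank), ]
}

#' Block-level importance summary
#'
#' Sums mean absolute attributions per encoder block.
#'
#' @param report An attribution report.
#' @param fused The \code{fused_matrix} the model was fitted on.
#' @return data.frame with block, total and share of attribution mass.
#' @export
block_importance <- function(report, fused) {
  tab <- attribution_table(report, fused)
  agg <- stats::aggregate(mean_abs ~ block, tab, sum)
  agg$share <- agg$mean_abs / sum(agg$mean_abs)
  agg[order(-agg$mean_abs), ]
}
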
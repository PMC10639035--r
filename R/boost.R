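#' Gradient-boosted tree parameters
#'
#' Parameters of the final tree-ensemble classifier. The reference method
#' uses an ordered-boosting engine (ordered boosting computes residuals on
#' examples unseen by earlier trees, avoiding target leakage); this package
#' backs the contract with xgboost, a conventional gradient-boosted tree
#' engine with seeded determinism, and records the engine and whether
#' ordered boosting was used in the model bundle.
#'
#' @param n_trees Number of boosting rounds (default 300).
#' @param depth Maximum tree depth (default 6).
#' @param learning_rate Shrinkage (default 0.1).
#' @param l2_reg L2 leaf regularization (default 1).
#' @param seed Integer seed.
#' @param extra Named list of engine-specific parameters passed through.
#' @return A \code{boost_params} list.
#' @export
boost_params <- function(n_trees = 300L, depth = 6L, learning_rate = 0.1,
                         l2_reg = 1, seed = 1L, extra = list()) {
  stopifnot(n_trees >= 1L, depth >= 1L, learning_rate > 0)
  structure(list(n_trees = as.integer(n_trees), depth = as.integer(depth),
                 learning_rate = learning_rate, l2_reg = l2_reg,
                 seed = as.integer(seed), extra = extra),
            class = "boost_params")
}

#' Train the boosted-tree classifier
#'
#' @param X Numeric feature matrix (rows = samples), finite values only.
#' @param y Binary 0/1 labels.
#' @param params A [boost_params()].
#' @return A \code{boost_model}: list with the fitted booster, params,
#'   feature names and engine metadata. Deterministic for fixed seed
#'   (single-threaded).
#' @export
train_classifier <- function(X, y, params = boost_params()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("single-class labels: need both classes to train", call. = FALSE)
  bad <- which(colSums(!is.finite(X)) > 0L)
  if (length(bad))
    stop("non-finite values in feature column(s): ",
         paste(utils::head(colnames(X)[bad], 5L), collapse = ", "),
         call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  xgb_par <- c(list(objective = "binary:logistic",
                    max_depth = params$depth, eta = params$learning_rate,
                    lambda = params$l2_reg, nthread = 1L,
                    seed = params$seed, tree_method = "hist"),
               params$extra)
  booster <- xgboost::xgb.train(
    params = xgb_par,
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = params$n_trees, verbose = 0)
  structure(list(booster = booster, params = params,
                 feature_names = colnames(X),
                 engine = "xgboost", ordered_boosting = FALSE),
            class = "boost_model")
}

check_feature_space <- function(model, X) {
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names))
      stop("feature count mismatch: model has ",
           length(model$feature_names), ", input has ", ncol(X),
           call. = FALSE)
    colnames(X) <- model$feature_names
  } else if (!identical(colnames(X), model$feature_names))
    stop("feature columns do not match the training feature space",
         call. = FALSE)
  X
}

#' Predict class probabilities
#'
#' @param model A fitted \code{boost_model}.
#' @param X Feature matrix in the training feature space.
#' @param margin Return raw log-odds margins instead of probabilities.
#' @return Numeric vector, one score per row; class call is
#'   \code{score >= 0.5}.
#' @export
predict_proba <- function(model, X, margin = FALSE) {
  stopifnot(inherits(model, "boost_model"))
  X <- check_feature_space(model, X)
  stats::predict(model$booster,
                 xgboost::xgb.DMatrix(X, nthread = 1L),
                 outputmargin = margin)
}
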
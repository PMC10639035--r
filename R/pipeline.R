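#' Configuration of the full ORI prediction pipeline
#'
#' Feature blocks (any subset of DL, CKSNAP, PCPseDNC, DCC) are computed on
#' the training windows, fused in canonical order, attributed with TreeSHAP
#' on a preliminary boosted-tree fit, pruned to the \code{top_k} features,
#' and a final boosted-tree classifier is trained on the selected columns.
#' Selection (and optional hyperparameter tuning) happen on training data
#' only and are frozen before any test row is scored.
#'
#' @param blocks Feature blocks to use, in any subset of
#'   \code{c("DL", "CKSNAP", "PCPseDNC", "DCC")}.
#' @param arch,train Extractor architecture/training configs (used when
#'   \code{"DL"} is in \code{blocks}).
#' @param cksnap_k Gap set for CKSNAP.
#' @param lambda,w PCPseDNC tiers and weight.
#' @param lag_max,dcc_indices DCC lag bound and index names.
#' @param index_table Physicochemical table (default bundled 38-index set).
#' @param select Run Shapley feature selection (default TRUE).
#' @param top_k Features kept by selection; default \code{min(500, D)}.
#' @param tune Tune classifier hyperparameters by Bayesian search.
#' @param tune_budget Trials when tuning.
#' @param boost Final classifier [boost_params()].
#' @param threshold Decision threshold.
#' @param seed Base seed; extractor, selection and classifier seeds derive
#'   from it, so the full metrics report is a deterministic function of
#'   (data seed, this seed).
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(blocks = c("DL", "CKSNAP", "PCPseDNC", "DCC"),
                            arch = arch_config(), train = train_config(),
                            cksnap_k = 0:5, lambda = 2L, w = 0.1,
                            lag_max = 2L,
                            dcc_indices = c("santalucia_dG",
                                            "santalucia_dH"),
                            index_table = NULL, select = TRUE,
                            top_k = 500L, tune = FALSE, tune_budget = 15L,
                            boost = boost_params(), threshold = 0.5,
                            seed = 1L) {
  blocks <- match.arg(blocks, BLOCK_ORDER, several.ok = TRUE)
  structure(list(blocks = blocks, arch = arch, train = train,
                 cksnap_k = cksnap_k, lambda = lambda, w = w,
                 lag_max = lag_max, dcc_indices = dcc_indices,
                 index_table = index_table, select = isTRUE(select),
                 top_k = as.integer(top_k), tune = isTRUE(tune),
                 tune_budget = as.integer(tune_budget), boost = boost,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_blocks <- function(config, x, extractor = NULL) {
  tab <- config$index_table
  if (is.null(tab)) tab <- default_index_table("full38")
  tab <- standardize_index_table(tab)
  blocks <- list()
  if ("DL" %in% config$blocks)
    blocks <- c(blocks, list(extract_features(extractor, x)))
  if ("CKSNAP" %in% config$blocks)
    blocks <- c(blocks, list(cksnap(x, config$cksnap_k)))
  if ("PCPseDNC" %in% config$blocks)
    blocks <- c(blocks, list(pcpsednc(x, config$lambda, config$w, tab)))
  if ("DCC" %in% config$blocks)
    blocks <- c(blocks, list(dcc(x, config$lag_max, config$dcc_indices,
                                 tab)))
  fuse(blocks)
}

#' Fit the full pipeline on a training set
#'
#' @param train_set A labelled [labeled_sequence_set()].
#' @param config A [pipeline_config()].
#' @return An \code{ori_model}: extractor (if any), selection report,
#'   selected-feature mask, block registry and the fitted classifier.
#' @export
fit_pipeline <- function(train_set, config = pipeline_config()) {
  stopifnot(inherits(train_set, "labeled_sequence_set"),
            inherits(config, "pipeline_config"))
  y <- train_set$records$label
  extractor <- NULL
  if ("DL" %in% config$blocks) {
    arch <- config$arch
    if (arch$window_length != train_set$window_length) {
      arch$window_length <- train_set$window_length
      arch <- do.call(arch_config, list(
        conv_kernels = arch$kernels, conv_filters = arch$filters,
        dropout_rate = arch$dropout, pool_stride = arch$pool_stride,
        gru_units = c(arch$gru_units_a, arch$gru_units_b),
        attention_dim = arch$attention_dim, dense_units = arch$dense_units,
        feature_layer = arch$feature_layer,
        window_length = train_set$window_length,
        use_attention = arch$use_attention, use_gru = arch$use_gru))
    }
    tcfg <- config$train
    tcfg$seed <- config$seed
    extractor <- train_extractor(build_extractor(arch, seed = config$seed),
                                 train_set, tcfg)
  }
  fused <- pipeline_blocks(config, train_set, extractor)
  bp <- config$boost
  bp$seed <- config$seed
  report <- NULL
  mask <- rep(TRUE, ncol(fused$matrix))
  if (config$select) {
    prelim <- train_classifier(fused$matrix, y, bp)
    report <- shapley_attributions(prelim, fused, seed = config$seed)
    report <- rank_and_select(report,
                              min(config$top_k, ncol(fused$matrix)))
    mask <- report$selected_mask
  }
  Xsel <- fused$matrix[, mask, drop = FALSE]
  if (config$tune) {
    tuned <- tune_hyperparameters(default_search_space(),
                                  cv_objective(Xsel, y, seed = config$seed),
                                  budget = config$tune_budget,
                                  seed = config$seed)
    bp <- do.call(boost_params, c(tuned$best$params,
                                  list(seed = config$seed)))
  }
  classifier <- train_classifier(Xsel, y, bp)
  structure(list(config = config, extractor = extractor,
                 registry = fused$registry,
                 feature_names = colnames(fused$matrix),
                 selection = report, mask = mask,
                 classifier = classifier,
                 window_length = train_set$window_length),
            class = "ori_model")
}

#' @export
print.ori_model <- function(x, ...) {
  cat("ori_model: blocks", paste(x$config$blocks, collapse = "+"),
      "|", sum(x$mask), "of", length(x$mask), "features |",
      x$classifier$engine, "\n")
  invisible(x)
}

#' Score sequences with a fitted pipeline
#'
#' @param model A [fit_pipeline()] model.
#' @param x Sequences (set or character vector) of the trained window length.
#' @return Numeric vector of ORI probabilities.
#' @export
predict_pipeline <- function(model, x) {
  stopifnot(inherits(model, "ori_model"))
  seqs <- as_sequence_vector(x)
  if (any(nchar(seqs) != model$window_length))
    stop("sequence length does not match the trained window (",
         model$window_length, " bp)", call. = FALSE)
  fused <- pipeline_blocks(model$config, seqs, model$extractor)
  if (!identical(colnames(fused$matrix), model$feature_names))
    stop("feature space mismatch between model and input", call. = FALSE)
  predict_proba(model$classifier,
                fused$matrix[, model$mask, drop = FALSE])
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold the extractor, encoders, Shapley selection and classifier
#' are fitted on the training folds only; the held-out fold is scored once.
#' Per-fold seeds derive deterministically from \code{config$seed}.
#'
#' @param config A [pipeline_config()].
#' @param dataset A labelled [labeled_sequence_set()].
#' @param folds A [split_folds()] assignment for \code{dataset}.
#' @return A \code{cv_report}: \code{per_fold} data.frame (one metric row
#'   per fold) and \code{mean} (column means).
#' @export
cross_validate <- function(config, dataset, folds) {
  stopifnot(inherits(folds, "fold_assignment"))
  ids <- dataset$records$id
  if (!setequal(names(folds$fold_of), ids))
    stop("fold assignment references unknown record ids", call. = FALSE)
  fold_of <- folds$fold_of[ids]
  rows <- vector("list", folds$n_folds)
  for (k in seq_len(folds$n_folds)) {
    cfg_k <- config
    cfg_k$seed <- config$seed * 1000L + k
    fit <- fit_pipeline(subset_set(dataset, fold_of != k), cfg_k)
    test <- subset_set(dataset, fold_of == k)
    scores <- predict_pipeline(fit, test)
    rows[[k]] <- metrics_as_row(compute_metrics(test$records$label, scores,
                                                config$threshold))
  }
  per_fold <- do.call(rbind, rows)
  per_fold <- cbind(fold = seq_len(folds$n_folds), per_fold)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1, drop = FALSE])),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cross-validation over", nrow(x$per_fold), "folds; mean metrics:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Cross-cell generalization matrix
#'
#' Trains one model per tagged dataset (on its training split) and scores
#' accuracy on every dataset's independent test split: training sets index
#' rows, test sets index columns.
#'
#' @param datasets Named list of labelled [labeled_sequence_set()]s sharing
#'   one window length (>= 2 entries).
#' @param config A [pipeline_config()].
#' @param test_fraction Held-out fraction per dataset (default 0.2).
#' @return Numeric matrix of accuracies, rownames = training tags,
#'   colnames = test tags.
#' @export
cross_cell_matrix <- function(datasets, config = pipeline_config(),
                              test_fraction = 0.2) {
  stopifnot(is.list(datasets), length(datasets) >= 2L,
            !is.null(names(datasets)))
  wl <- vapply(datasets, function(d) d$window_length, 0L)
  if (length(unique(wl)) != 1L)
    stop("window-length mismatch across datasets: ",
         paste(wl, collapse = ", "), call. = FALSE)
  splits <- lapply(seq_along(datasets), function(i)
    train_test_split(datasets[[i]], test_fraction,
                     seed = config$seed + i))
  names(splits) <- names(datasets)
  tags <- names(datasets)
  acc <- matrix(NA_real_, length(tags), length(tags),
                dimnames = list(train = tags, test = tags))
  for (i in seq_along(tags)) {
    fit <- fit_pipeline(splits[[i]]$train, config)
    for (j in seq_along(tags)) {
      test <- splits[[j]]$test
      m <- compute_metrics(test$records$label,
                           predict_pipeline(fit, test), config$threshold)
      acc[i, j] <- m$Ac
    }
  }
  acc
}
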
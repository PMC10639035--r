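#' Architecture of the neural feature descriptor
#'
#' Six parallel 1-D convolution branches (ReLU + dropout, same-padding) read
#' the one-hot sequence; their channel-concatenated output (optionally
#' average-pooled along the sequence to shorten recurrence) feeds two
#' bidirectional GRU stacks of different depth (one 1-layer, one 2-layer) in
#' parallel; the per-position GRU outputs are concatenated and pooled by
#' dot-product attention (softmax over query-key similarities, weighted sum
#' of values); a dense ReLU layer and a 1-unit sigmoid head produce the ORI
#' probability. After training, the network serves as a fixed feature
#' extractor from the configured \code{feature_layer}.
#'
#' @param conv_kernels Kernel sizes of the parallel branches
#'   (default \code{c(2, 4, 6, 8, 10, 12)}).
#' @param conv_filters Filters per branch; recycled to the number of
#'   branches (default 16).
#' @param dropout_rate Dropout after each convolution and after the dense
#'   layer, in \code{[0, 1)}.
#' @param pool_stride Average-pooling stride applied to the convolution
#'   output before the recurrent stacks (1 = none); trailing positions not
#'   filling a full window are dropped.
#' @param gru_units Length-2 integer vector: hidden units of the 1-layer and
#'   the 2-layer bidirectional GRU stack.
#' @param attention_dim Dimension of the attention key/query projection.
#' @param dense_units Units of the dense head layer.
#' @param feature_layer \code{"attention_output"} (default) or
#'   \code{"penultimate_dense"}: which activations are exported as the DL
#'   feature block.
#' @param window_length Input window length in bp (default 300).
#' @param use_attention,use_gru Ablation switches: with
#'   \code{use_attention = FALSE} the attention pool is replaced by uniform
#'   mean pooling; with \code{use_gru = FALSE} the recurrent stacks are
#'   bypassed and attention pools the convolution output directly.
#' @return An \code{arch_config} list.
#' @export
arch_config <- function(conv_kernels = c(2L, 4L, 6L, 8L, 10L, 12L),
                        conv_filters = 16L, dropout_rate = 0.3,
                        pool_stride = 5L, gru_units = c(16L, 24L),
                        attention_dim = 24L, dense_units = 32L,
                        feature_layer = c("attention_output",
                                          "penultimate_dense"),
                        window_length = 300L,
                        use_attention = TRUE, use_gru = TRUE) {
  feature_layer <- match.arg(feature_layer)
  conv_filters <- rep_len(as.integer(conv_filters), length(conv_kernels))
  stopifnot(length(conv_kernels) >= 1L, all(conv_kernels >= 1L),
            all(conv_filters >= 1L), dropout_rate >= 0, dropout_rate < 1,
            pool_stride >= 1L, length(gru_units) == 2L, all(gru_units >= 1L),
            attention_dim >= 1L, dense_units >= 1L, window_length >= 2L)
  if (max(conv_kernels) > window_length)
    stop("convolution kernel (", max(conv_kernels),
         ") larger than window (", window_length, ")", call. = FALSE)
  if (window_length %/% pool_stride < 1L)
    stop("pool_stride leaves no sequence positions", call. = FALSE)
  structure(list(kernels = as.integer(conv_kernels),
                 filters = conv_filters, dropout = dropout_rate,
                 pool_stride = as.integer(pool_stride),
                 gru_units_a = as.integer(gru_units[1L]),
                 gru_units_b = as.integer(gru_units[2L]),
                 attention_dim = as.integer(attention_dim),
                 dense_units = as.integer(dense_units),
                 feature_layer = feature_layer,
                 window_length = as.integer(window_length),
                 use_attention = isTRUE(use_attention),
                 use_gru = isTRUE(use_gru)),
            class = "arch_config")
}

#' Training configuration for the neural descriptor
#'
#' All stochastic operations (weight init happens in [build_extractor()];
#' shuffling, dropout and the validation split here) are driven by
#' \code{seed}, so two runs with equal seeds produce equal histories.
#'
#' @param epochs Maximum epochs (default 12).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param validation_fraction Stratified fraction held out for early
#'   stopping, in \code{(0, 0.5]}.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best weights are restored).
#' @param seed Integer seed.
#' @return A \code{train_config} list.
#' @export
train_config <- function(epochs = 12L, batch_size = 32L,
                         learning_rate = 1e-3, validation_fraction = 0.15,
                         early_stop_patience = 3L, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            validation_fraction > 0, validation_fraction <= 0.5,
            early_stop_patience >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)), class = "train_config")
}

#' One-hot encode a DNA sequence
#'
#' @param seq A validated ACGT string.
#' @return An \code{L x 4} matrix, column order A, C, G, T; row i is the
#'   unit vector of base i.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq) {
  codes <- seq_to_codes(validate_sequence(seq))
  m <- matrix(0, length(codes), 4L,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(codes), codes)] <- 1
  m
}

#' Dot-product attention pooling
#'
#' Computes softmax(K q) weights and returns the weighted sum of the value
#' rows. Weights are a probability vector for any input length.
#'
#' @param query Numeric vector (length d).
#' @param keys Matrix \code{n x d} of keys.
#' @param values Matrix \code{n x p} of values (defaults to \code{keys}).
#' @return List with \code{output} (length p) and \code{weights} (length n,
#'   non-negative, summing to 1).
#' @export
attention_pool <- function(query, keys, values = keys) {
  stopifnot(is.matrix(keys), is.matrix(values),
            nrow(keys) == nrow(values), ncol(keys) == length(query))
  if (nrow(keys) == 0L) stop("empty key set", call. = FALSE)
  scores <- as.vector(keys %*% query)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  list(output = as.vector(t(values) %*% w), weights = w)
}

#' Build an (untrained) neural feature extractor
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @return An \code{extractor_bundle}: arch, weights, \code{feature_dim},
#'   \code{trained} flag and (after training) history.
#' @export
build_extractor <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  weights <- nn_init_cpp(unclass(arch), as.integer(seed))
  fd <- if (arch$feature_layer == "penultimate_dense") arch$dense_units
        else if (arch$use_gru) 2L * (arch$gru_units_a + arch$gru_units_b)
        else sum(arch$filters)
  structure(list(arch = arch, weights = weights, feature_dim = fd,
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "extractor_bundle")
}

#' @export
print.extractor_bundle <- function(x, ...) {
  cat("extractor_bundle:", length(x$arch$kernels), "conv branches,",
      "BiGRU", x$arch$gru_units_a, "/", x$arch$gru_units_b,
      "| feature_dim", x$feature_dim,
      if (x$trained) "(trained)" else "(untrained)", "\n")
  invisible(x)
}

check_window <- function(bundle, seqs) {
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != bundle$arch$window_length))
    stop("sequence length does not match the configured window (",
         bundle$arch$window_length, " bp)", call. = FALSE)
  invisible(L)
}

#' Train the neural feature extractor as a binary classifier
#'
#' Binary cross-entropy objective, Adam optimizer, seeded stratified
#' validation split with early stopping; the best-validation weights are
#' kept.
#'
#' @param bundle A [build_extractor()] bundle.
#' @param set A labelled [labeled_sequence_set()] with both classes.
#' @param cfg A [train_config()].
#' @return The bundle with trained weights, \code{history} (per-epoch train
#'   and validation loss) and \code{best_epoch}.
#' @export
train_extractor <- function(bundle, set, cfg = train_config()) {
  stopifnot(inherits(bundle, "extractor_bundle"),
            inherits(set, "labeled_sequence_set"),
            inherits(cfg, "train_config"))
  r <- set$records
  if (anyNA(r$label) || length(unique(r$label)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  check_window(bundle, r$seq)
  codes <- seqs_to_code_matrix(r$seq)
  res <- nn_train_cpp(unclass(bundle$arch), bundle$weights, codes,
                      as.integer(r$label), unclass(cfg))
  bundle$weights <- res$weights
  bundle$history <- res$history
  bundle$best_epoch <- res$best_epoch
  bundle$trained <- TRUE
  bundle
}

#' Extract deep-learning features
#'
#' Runs the trained network in inference mode (dropout disabled) and returns
#' activations of the configured feature layer as the \code{"DL"} block.
#'
#' @param bundle A trained extractor.
#' @param x Sequences (set or character vector) of the trained window length.
#' @return A [feature_block()] named \code{"DL"}, features \code{"DL:{i}"}.
#' @export
extract_features <- function(bundle, x) {
  stopifnot(inherits(bundle, "extractor_bundle"))
  if (!bundle$trained)
    warning("extracting features from an untrained network")
  seqs <- as_sequence_vector(x)
  check_window(bundle, seqs)
  res <- nn_forward_cpp(unclass(bundle$arch), bundle$weights,
                        seqs_to_code_matrix(seqs),
                        bundle$arch$feature_layer)
  m <- res$features
  rownames(m) <- names(seqs)
  feature_block("DL", m, paste0("DL:", seq_len(ncol(m))))
}

#' Predict ORI probabilities with the neural descriptor alone
#'
#' @inheritParams extract_features
#' @return Numeric vector of probabilities in \code{[0, 1]}.
#' @export
predict_extractor <- function(bundle, x) {
  stopifnot(inherits(bundle, "extractor_bundle"))
  seqs <- as_sequence_vector(x)
  check_window(bundle, seqs)
  nn_forward_cpp(unclass(bundle$arch), bundle$weights,
                 seqs_to_code_matrix(seqs), bundle$arch$feature_layer)$prob
}

#' Save / load an extractor bundle
#'
#' The bundle directory holds \code{arch.json} (architecture + metadata),
#' \code{weights.rds} (numeric weight list) and \code{history.csv}.
#'
#' @param bundle A trained or untrained extractor bundle.
#' @param dir Directory to create/populate.
#' @return \code{dir} (save) or the restored bundle (load).
#' @export
save_extractor <- function(bundle, dir) {
  stopifnot(inherits(bundle, "extractor_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- unclass(bundle$arch)
  meta$feature_dim <- bundle$feature_dim
  meta$trained <- bundle$trained
  meta$seed <- bundle$seed
  meta$best_epoch <- bundle$best_epoch
  jsonlite::write_json(meta, file.path(dir, "arch.json"), auto_unbox = TRUE)
  saveRDS(bundle$weights, file.path(dir, "weights.rds"))
  if (!is.null(bundle$history))
    utils::write.csv(bundle$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "arch.json"),
                              simplifyVector = TRUE)
  arch <- arch_config(conv_kernels = meta$kernels,
                      conv_filters = meta$filters,
                      dropout_rate = meta$dropout,
                      pool_stride = meta$pool_stride,
                      gru_units = c(meta$gru_units_a, meta$gru_units_b),
                      attention_dim = meta$attention_dim,
                      dense_units = meta$dense_units,
                      feature_layer = meta$feature_layer,
                      window_length = meta$window_length,
                      use_attention = meta$use_attention,
                      use_gru = meta$use_gru)
  bundle <- build_extractor(arch, seed = meta$seed)
  bundle$weights <- readRDS(file.path(dir, "weights.rds"))
  bundle$trained <- meta$trained
  bundle$best_epoch <- meta$best_epoch
  hp <- file.path(dir, "history.csv")
  if (file.exists(hp)) bundle$history <- utils::read.csv(hp)
  bundle
}
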
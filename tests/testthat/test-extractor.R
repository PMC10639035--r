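tiny_arch <- function(...) {
  args <- utils::modifyList(
    list(conv_kernels = c(3L, 5L), conv_filters = 3L, dropout_rate = 0,
         pool_stride = 2L, gru_units = c(3L, 4L), attention_dim = 4L,
         dense_units = 5L, window_length = 24L),
    list(...))
  do.call(arch_config, args)
}

tiny_set <- function(n = 16, seed = 1) {
  generate_synthetic_dataset(synthetic_config(
    n_per_class = n, window_length = 24L, motif = "ACGTAC",
    gc_skew_shift = 0.1, flank_offset_range = c(5L, 10L), seed = seed))
}

test_that("one_hot_encode produces unit rows in A,C,G,T order", {
  m <- one_hot_encode("ACGT")
  expect_identical(m, diag(4), ignore_attr = TRUE)
  expect_identical(colnames(m), c("A", "C", "G", "T"))
  expect_equal(unname(rowSums(one_hot_encode("GATTACA"))), rep(1, 7))
})

test_that("attention_pool matches the softmax oracle and sums weights to 1", {
  K <- matrix(with_seed(2, rnorm(12)), 4, 3)
  V <- matrix(with_seed(3, rnorm(8)), 4, 2)
  q <- c(0.3, -1, 2)
  got <- attention_pool(q, K, V)
  ref <- oracle_attention(q, K, V)
  expect_equal(got$output, unname(ref$output), tolerance = 1e-12)
  expect_equal(got$weights, ref$weights, tolerance = 1e-12)
  expect_equal(sum(got$weights), 1)
  # uniform weights when all scores tie
  expect_equal(attention_pool(c(0, 0, 0), K, V)$weights, rep(0.25, 4))
  expect_error(attention_pool(q, K[0, , drop = FALSE],
                              V[0, , drop = FALSE]), "empty")
})

test_that("attention_pool is numerically stable for large scores", {
  K <- matrix(c(1000, -1000), 2, 1)
  r <- attention_pool(1, K, matrix(c(5, 7), 2, 1))
  expect_equal(sum(r$weights), 1)
  expect_equal(r$output, 5, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  arch <- tiny_arch()
  b <- build_extractor(arch, seed = 3)
  set <- tiny_set(n = 3, seed = 5)
  codes <- t(vapply(strsplit(set$records$seq, ""), function(ch)
    match(ch, c("A", "C", "G", "T")), integer(24L)))
  y <- set$records$label
  res <- nn_loss_grad_cpp(unclass(arch), b$weights, codes, y)
  eps <- 1e-5
  worst <- 0
  for (wn in c("conv_W_1", "gru_gruA_l1_f_U", "gru_gruB_l2_b_W",
               "attn_Wk", "attn_q", "dense_W", "out_W", "out_b")) {
    W <- b$weights[[wn]]
    picks <- with_seed(9, sample.int(length(W), min(4L, length(W))))
    for (j in picks) {
      wp <- b$weights; wp[[wn]][j] <- W[j] + eps
      wm <- b$weights; wm[[wn]][j] <- W[j] - eps
      num <- (nn_loss_grad_cpp(unclass(arch), wp, codes, y)$loss -
              nn_loss_grad_cpp(unclass(arch), wm, codes, y)$loss) / (2 * eps)
      ana <- res$grads[[wn]][j]
      worst <- max(worst, abs(num - ana) / max(1e-4, abs(num), abs(ana)))
    }
  }
  expect_lt(worst, 1e-2)
})

test_that("build and training are deterministic in the seed", {
  arch <- tiny_arch()
  b1 <- build_extractor(arch, seed = 11)
  b2 <- build_extractor(arch, seed = 11)
  expect_equal(b1$weights, b2$weights, tolerance = 0)
  expect_false(isTRUE(all.equal(build_extractor(arch, 12)$weights,
                                b1$weights)))
  set <- tiny_set(n = 12, seed = 2)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 21)
  t1 <- train_extractor(b1, set, cfg)
  t2 <- train_extractor(b2, set, cfg)
  expect_equal(t1$weights, t2$weights, tolerance = 0)
  expect_equal(t1$history, t2$history, tolerance = 0)
})

test_that("extract_features has the declared shape and inference is
           deterministic despite dropout at train time", {
  arch <- tiny_arch(dropout_rate = 0.4)
  set <- tiny_set(n = 10, seed = 6)
  b <- train_extractor(build_extractor(arch, 1), set,
                       train_config(epochs = 2, batch_size = 8, seed = 1))
  f1 <- extract_features(b, set)
  expect_s3_class(f1, "feature_block")
  expect_identical(f1$name, "DL")
  expect_identical(dim(f1$matrix), c(20L, b$feature_dim))
  expect_identical(b$feature_dim, 2L * (3L + 4L))
  expect_identical(rownames(f1$matrix), set$records$id)
  expect_equal(extract_features(b, set)$matrix, f1$matrix, tolerance = 0)
  p <- predict_extractor(b, set)
  expect_true(all(p >= 0 & p <= 1))
  expect_warning(extract_features(build_extractor(arch, 1), set),
                 "untrained")
})

test_that("feature_layer and ablation switches change the exported
           dimension but keep the pipeline runnable", {
  set <- tiny_set(n = 8, seed = 3)
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 2)
  pen <- build_extractor(tiny_arch(feature_layer = "penultimate_dense"), 1)
  expect_identical(pen$feature_dim, 5L)
  no_att <- train_extractor(
    build_extractor(tiny_arch(use_attention = FALSE), 1), set, cfg)
  no_gru <- train_extractor(
    build_extractor(tiny_arch(use_gru = FALSE), 1), set, cfg)
  expect_identical(ncol(extract_features(no_att, set)$matrix), 14L)
  expect_identical(no_gru$feature_dim, 6L)  # sum of conv filters
  expect_identical(ncol(extract_features(no_gru, set)$matrix), 6L)
  expect_true(all(is.finite(extract_features(no_att, set)$matrix)))
})

test_that("training reduces loss and learns the tiny planted signal", {
  set <- tiny_set(n = 60, seed = 7)
  sp <- train_test_split(set, 0.25, seed = 1)
  b <- train_extractor(build_extractor(tiny_arch(conv_filters = 6L), 2),
                       sp$train,
                       train_config(epochs = 15, batch_size = 16,
                                    early_stop_patience = 5, seed = 2))
  h <- b$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  auc <- auc_score(sp$test$records$label, predict_extractor(b, sp$test))
  expect_gt(auc, 0.75)
})

test_that("extractor save/load roundtrip preserves weights and outputs", {
  set <- tiny_set(n = 8, seed = 4)
  b <- train_extractor(build_extractor(tiny_arch(), 5), set,
                       train_config(epochs = 1, batch_size = 8, seed = 5))
  d <- tempfile()
  save_extractor(b, d)
  back <- load_extractor(d)
  expect_equal(back$weights, b$weights, tolerance = 0)
  expect_identical(back$trained, TRUE)
  expect_equal(extract_features(back, set)$matrix,
               extract_features(b, set)$matrix, tolerance = 0)
  unlink(d, recursive = TRUE)
})

test_that("architecture and window validation fail loudly", {
  expect_error(arch_config(conv_kernels = 40, window_length = 24),
               "larger than window")
  expect_error(arch_config(dropout_rate = 1))
  b <- build_extractor(tiny_arch(), 1)
  expect_error(suppressWarnings(extract_features(b, "ACGT")), "window")
  one_class <- labeled_sequence_set("a", strrep("ACGT", 6), 1)
  expect_error(train_extractor(b, one_class, train_config()),
               "both classes")
})
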
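fake_block <- function(name, n, p, seed) {
  m <- matrix(with_seed(seed, rnorm(n * p)), n, p)
  rownames(m) <- paste0("r", seq_len(n))
  feature_block(name, m, paste0(name, ":", seq_len(p)))
}

test_that("fuse concatenates blocks in canonical order with a tiling
           registry", {
  blocks <- list(fake_block("DCC", 6, 4, 1), fake_block("DL", 6, 5, 2),
                 fake_block("CKSNAP", 6, 3, 3))
  fused <- fuse(blocks)
  expect_identical(fused$registry$block, c("DL", "CKSNAP", "DCC"))
  expect_identical(fused$registry$start, c(1L, 6L, 9L))
  expect_identical(fused$registry$end, c(5L, 8L, 12L))
  expect_identical(ncol(fused$matrix), 12L)
  expect_equal(fused_slice(fused, "CKSNAP"), blocks[[3]]$matrix,
               ignore_attr = TRUE)
  expect_identical(colnames(fused$matrix)[1:5], paste0("DL:", 1:5))
  expect_error(fuse(list(fake_block("XX", 3, 2, 1))), "unknown block")
  expect_error(fuse(list(fake_block("DL", 3, 2, 1),
                         fake_block("DCC", 4, 2, 2))), "row-count")
  expect_error(fused_slice(fused, "PCPseDNC"), "not present")
})

test_that("tree-model Shapley attributions satisfy local accuracy on the
           margin", {
  n <- 120
  X <- matrix(with_seed(31, rnorm(n * 6)), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(X[, 1] + 0.5 * X[, 3] + with_seed(32, rnorm(n, 0, .3)) > 0)
  model <- train_classifier(X, y, boost_params(n_trees = 40, seed = 5))
  rep <- shapley_attributions(model, X)
  margins <- predict_proba(model, X, margin = TRUE)
  recon <- rep$base_value + rowSums(rep$attributions)
  expect_equal(recon, margins, tolerance = 1e-5)
  expect_identical(colnames(rep$attributions), colnames(X))
})

test_that("a single-split stump attributes everything to its split feature", {
  X <- cbind(a = c(rep(0, 30), rep(1, 30)),
             b = with_seed(41, rnorm(60)))
  y <- c(rep(0L, 30), rep(1L, 30))
  model <- train_classifier(X, y,
                            boost_params(n_trees = 1, depth = 1, seed = 1))
  rep <- shapley_attributions(model, X)
  expect_equal(unname(rep$attributions[, "b"]), rep(0, 60),
               tolerance = 1e-8)
  expect_gt(mean(abs(rep$attributions[, "a"])), 0)
})

test_that("rank_and_select ranks by mean |attribution| with index
           tiebreaks", {
  rep <- structure(list(base_value = 0,
                        attributions = rbind(c(0.2, -0.5, 0.2, 0)),
                        mean_abs = c(0.2, 0.5, 0.2, 0),
                        feature_names = paste0("f", 1:4),
                        ranking = NULL, selected_mask = NULL, top_k = NULL),
                   class = "attribution_report")
  r <- rank_and_select(rep, 2)
  expect_identical(r$ranking, c(2L, 1L, 3L, 4L))
  expect_identical(r$selected_mask, c(TRUE, TRUE, FALSE, FALSE))
  all_in <- rank_and_select(rep, 99)
  expect_true(all(all_in$selected_mask))
  expect_error(rank_and_select(rep, 0), "top_k")
})

test_that("sampling estimator recovers exact Shapley values of a linear
           model", {
  # for f(x) = sum_j w_j x_j and a single-row background b the Shapley value
  # of feature j at x is exactly w_j (x_j - b_j), for every permutation
  d <- 3
  w <- c(1.5, -2, 0.5)
  f <- function(M) as.vector(M %*% w)
  X <- matrix(with_seed(51, rnorm(4 * d)), 4, d,
              dimnames = list(NULL, paste0("f", 1:3)))
  bg <- matrix(c(0.5, -1, 2), 1, d)
  rep <- shapley_attributions(structure(list(), class = "other_model"),
                              X, background = bg, predict_fun = f,
                              n_perm = 10, seed = 7)
  exact <- sweep(X, 2, bg[1, ]) %*% diag(w)
  expect_equal(unname(rep$attributions), unname(exact), tolerance = 1e-9)
  expect_equal(rep$base_value, f(bg), tolerance = 1e-12)
  expect_equal(rep$base_value + rowSums(rep$attributions), f(X),
               tolerance = 1e-9)
})

test_that("sampling estimator demands a predict_fun and a consistent
           background", {
  X <- matrix(rnorm(10), 5, 2)
  m <- structure(list(), class = "other_model")
  expect_error(shapley_attributions(m, X), "predict_fun")
  expect_error(shapley_attributions(m, X, background = X[, 1, drop = FALSE],
                                    predict_fun = rowSums),
               "feature count")
})

test_that("attribution_table and block_importance summarize per block", {
  blocks <- list(fake_block("DL", 40, 2, 11), fake_block("CKSNAP", 40, 2, 12))
  fused <- fuse(blocks)
  y <- as.integer(fused$matrix[, 1] > 0)
  model <- train_classifier(fused$matrix, y,
                            boost_params(n_trees = 20, seed = 2))
  rep <- rank_and_select(shapley_attributions(model, fused), 3)
  tab <- attribution_table(rep, fused)
  expect_identical(tab$rank, 1:4)
  expect_identical(tab$feature[1], "DL:1")
  bi <- block_importance(rep, fused)
  expect_equal(sum(bi$share), 1)
  expect_identical(bi$block[1], "DL")
})
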
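# Independent, deliberately naive reference implementations of the sequence
# encoders, written as literal loop transcriptions of their defining
# formulas. They share no code with the package internals.

.bases <- c("A", "C", "G", "T")
.dinucs <- paste0(rep(.bases, each = 4), .bases)

rand_seq <- function(L, seed) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(seed, paste(sample(.bases, L, replace = TRUE), collapse = ""))
}

oracle_cksnap <- function(seq, k_values) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (k in sort(k_values)) {
    cnt <- stats::setNames(numeric(16), .dinucs)
    for (i in seq_len(L - k - 1)) {
      pair <- paste0(chars[i], chars[i + k + 1])
      cnt[pair] <- cnt[pair] + 1
    }
    out <- c(out, cnt / (L - k - 1))
  }
  unname(out)
}

# P: standardized index matrix (indices x 16, colnames AA..TT)
oracle_pse <- function(seq, lambda, w, P) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  dn <- function(i) paste0(chars[i], chars[i + 1])
  f <- stats::setNames(numeric(16), .dinucs)
  for (i in seq_len(L - 1)) f[dn(i)] <- f[dn(i)] + 1
  f <- f / (L - 1)
  corr <- function(d1, d2) mean((P[, d1] - P[, d2])^2)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    s <- 0
    for (i in seq_len(L - 1 - j)) s <- s + corr(dn(i), dn(i + j))
    theta[j] <- s / (L - 1 - j)
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

oracle_dcc <- function(seq, lag_max, P) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  dn <- function(i) paste0(chars[i], chars[i + 1])
  idx <- rownames(P)
  pbar <- sapply(idx, function(u)
    mean(sapply(seq_len(L - 1), function(j) P[u, dn(j)])))
  out <- numeric(0)
  for (u1 in idx) for (u2 in idx) {
    if (u1 == u2) next
    for (lag in seq_len(lag_max)) {
      s <- 0
      for (i in seq_len(L - lag - 1))
        s <- s + (P[u1, dn(i)] - pbar[u1]) * (P[u2, dn(i + lag)] - pbar[u2])
      out <- c(out, s / (L - lag - 1))
    }
  }
  unname(out)
}

oracle_attention <- function(query, keys, values) {
  scores <- apply(keys, 1, function(k) sum(k * query))
  w <- exp(scores) / sum(exp(scores))
  list(output = colSums(values * w), weights = w)
}

# small learnable benchmark shared across tests
small_bench <- function(n = 150, seed = 1, gc = 0.1, motif_rate = 0.8) {
  generate_synthetic_dataset(synthetic_config(
    n_per_class = n, gc_skew_shift = gc, motif_rate = motif_rate,
    seed = seed))
}

# compact extractor architecture used to keep neural tests fast
small_arch <- function(window = 300L, ...) {
  arch_config(conv_filters = 8L, pool_stride = 6L, gru_units = c(8L, 12L),
              attention_dim = 12L, dense_units = 16L, dropout_rate = 0.2,
              window_length = window, ...)
}

desk_pipeline_config <- function(seed, blocks = c("DL", "CKSNAP",
                                                  "PCPseDNC", "DCC"),
                                 epochs = 4L) {
  pipeline_config(blocks = blocks, arch = small_arch(),
                  train = train_config(epochs = epochs, batch_size = 64L,
                                       early_stop_patience = 2L,
                                       seed = seed),
                  boost = boost_params(n_trees = 200L, seed = seed),
                  seed = seed)
}
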
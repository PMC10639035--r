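std38 <- standardize_index_table(default_index_table("full38"))
std6 <- standardize_index_table(default_index_table("pse6"))

test_that("cksnap matches hand-computed small cases", {
  b <- cksnap("ACGT", k_values = 0)
  v <- b$matrix[1, ]
  expect_equal(unname(v[c("CKSNAP:k0:AC", "CKSNAP:k0:CG", "CKSNAP:k0:GT")]),
               rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  b1 <- cksnap("ACGT", k_values = 1)$matrix[1, ]
  expect_equal(unname(b1[c("CKSNAP:k1:AG", "CKSNAP:k1:CT")]), c(0.5, 0.5))
  expect_equal(unname(cksnap("AAAA", 0)$matrix[1, "CKSNAP:k0:AA"]), 1)
})

test_that("cksnap agrees with the naive transcription on random sequences", {
  for (seed in 1:20) {
    s <- rand_seq(sample(20:120, 1), seed)
    expect_equal(unname(cksnap(s, 0:5)$matrix[1, ]),
                 oracle_cksnap(s, 0:5), tolerance = 1e-12)
  }
})

test_that("cksnap block structure: 16 columns per k summing to 1", {
  set <- small_bench(n = 15, seed = 8)
  M <- cksnap(set, 0:5)$matrix
  expect_identical(dim(M), c(30L, 96L))
  expect_identical(rownames(M), set$records$id)
  for (k in 0:5) {
    cols <- grepl(paste0(":k", k, ":"), colnames(M))
    expect_identical(sum(cols), 16L)
    expect_equal(unname(rowSums(M[, cols])), rep(1, 30), tolerance = 1e-12)
  }
  expect_error(cksnap("ACG", k_values = 2), "too short")
})

test_that("pcpsednc and psednc agree with the naive transcription", {
  for (seed in 21:35) {
    s <- rand_seq(sample(20:120, 1), seed)
    expect_equal(unname(pcpsednc(s, lambda = 2, w = 0.1)$matrix[1, ]),
                 oracle_pse(s, 2, 0.1, index_values(std38)),
                 tolerance = 1e-12)
    expect_equal(unname(psednc(s, lambda = 3, w = 0.4)$matrix[1, ]),
                 oracle_pse(s, 3, 0.4, index_values(std6)),
                 tolerance = 1e-12)
  }
})

test_that("pseudo-composition vectors are probability vectors", {
  set <- small_bench(n = 15, seed = 13)
  for (blk in list(pcpsednc(set), psednc(set, lambda = 4, w = 0.5))) {
    M <- blk$matrix
    expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
})

test_that("pcpsednc converges to plain dinucleotide frequencies as w -> 0", {
  s <- rand_seq(90, 41)
  tiny <- pcpsednc(s, lambda = 2, w = 1e-9)$matrix[1, 1:16]
  f <- cksnap(s, 0)$matrix[1, ]
  expect_equal(unname(tiny), unname(f), tolerance = 1e-6)
})

test_that("pcpsednc validates lambda and w", {
  expect_error(pcpsednc("ACGTAC", lambda = 5), "lambda")
  expect_error(pcpsednc("ACGTACGT", w = 0))
  expect_error(pcpsednc("ACGTACGT", w = 1.5))
})

test_that("dcc agrees with the naive transcription and is zero on
           homopolymers", {
  idx <- c("santalucia_dG", "santalucia_dH")
  P <- index_values(subset_index_table(std38, idx))
  for (seed in 51:65) {
    s <- rand_seq(sample(20:120, 1), seed)
    expect_equal(unname(dcc(s, 2, idx)$matrix[1, ]),
                 oracle_dcc(s, 2, P), tolerance = 1e-12)
  }
  for (h in c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"))
    expect_equal(unname(dcc(h, 2, idx)$matrix[1, ]), rep(0, 4),
                 tolerance = 1e-12)
})

test_that("dcc dimensionality and naming follow n_idx*(n_idx-1)*lag_max", {
  idx3 <- c("santalucia_dG", "santalucia_dH", "santalucia_dS")
  b <- dcc(rand_seq(50, 7), lag_max = 3, indices = idx3)
  expect_identical(ncol(b$matrix), 3L * 2L * 3L)
  expect_identical(b$feature_names[1], "DCC:santalucia_dG|santalucia_dH:lag1")
  expect_error(dcc("ACGTACGT", indices = "santalucia_dG"), "at least 2")
  expect_error(dcc("ACGT", lag_max = 3), "lag_max")
})

test_that("dcc is invariant to adding a constant to a raw index", {
  raw <- default_index_table("full38")
  shifted <- raw
  shifted$values["santalucia_dG", ] <-
    shifted$values["santalucia_dG", ] + 100
  s <- rand_seq(80, 77)
  expect_equal(dcc(s, 2, table = raw)$matrix,
               dcc(s, 2, table = shifted)$matrix, tolerance = 1e-9)
})

test_that("encoders are permutation-equivariant over input rows", {
  set <- small_bench(n = 12, seed = 17)
  seqs <- set$records$seq
  names(seqs) <- set$records$id
  perm <- rev(seq_along(seqs))
  for (enc in list(function(x) cksnap(x, 0:2),
                   function(x) pcpsednc(x),
                   function(x) dcc(x))) {
    M1 <- enc(seqs)$matrix
    M2 <- enc(seqs[perm])$matrix
    expect_equal(M2, M1[perm, ], tolerance = 1e-12)
  }
})
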
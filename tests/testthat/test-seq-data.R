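test_that("validate_sequence upper-cases and enforces the ACGT alphabet", {
  expect_identical(validate_sequence("acgt"), "ACGT")
  expect_error(validate_sequence("ACGN"), "position\\(s\\) 4")
  expect_error(validate_sequence("NCGN"), "1, 4")
  expect_identical(validate_sequence("ACGN", policy = "drop"), NA_character_)
  r <- validate_sequence("ACGN", policy = "randomize", seed = 7)
  expect_match(r, "^ACG[ACGT]$")
  expect_identical(r, validate_sequence("ACGN", policy = "randomize",
                                        seed = 7))
})

test_that("labeled_sequence_set enforces equal windows and 0/1 labels", {
  s <- labeled_sequence_set(c("a", "b"), c("ACGT", "TTTT"), c(1, 0),
                            tag = "demo")
  expect_s3_class(s, "labeled_sequence_set")
  expect_identical(s$window_length, 4L)
  expect_identical(unname(as.integer(s$class_counts)), c(1L, 1L))
  expect_error(labeled_sequence_set("a", "ACGT", 2), "labels must be")
  expect_error(labeled_sequence_set(c("a", "b"), c("ACGT", "ACG")),
               "window length")
  expect_error(labeled_sequence_set(c("a", "a"), c("ACGT", "ACGT")))
})

test_that("FASTA write/read roundtrip is the identity on records", {
  set <- small_bench(n = 20, seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_fasta(set, f)
  back <- read_fasta(f, tag = set$tag)
  expect_identical(back$records, set$records)
  expect_identical(back$window_length, set$window_length)
})

test_that("read_fasta reads header labels, side-table labels, and rejects
           malformed input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">r1|1", "ACGT", ">r2|0", "TTTT", ">r3", "GGGG"), f)
  s <- read_fasta(f)
  expect_identical(s$records$label, c(1L, 0L, NA_integer_))
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("r3\t1", "r2\t1"), tab)
  s2 <- read_fasta(f, labels = tab)
  expect_identical(s2$records$label, c(1L, 1L, 1L))
  bad <- tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">r1", "ACGT"), bad)
  expect_error(read_fasta(bad), "malformed FASTA at line 1")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("generator obeys counts, window length, labels and determinism", {
  cfg <- synthetic_config(n_per_class = 25, seed = 11)
  set <- generate_synthetic_dataset(cfg)
  expect_identical(nrow(set$records), 50L)
  expect_true(all(nchar(set$records$seq) == 300L))
  expect_identical(sum(set$records$label), 25L)
  again <- generate_synthetic_dataset(cfg)
  expect_identical(again$records, set$records)
  other <- generate_synthetic_dataset(synthetic_config(n_per_class = 25,
                                                       seed = 12))
  expect_false(identical(other$records$seq, set$records$seq))
})

test_that("planted motif appears in positives at about motif_rate and the
           GC skew separates the classes", {
  cfg <- synthetic_config(n_per_class = 200, motif_rate = 0.8,
                          gc_skew_shift = 0.1, seed = 5)
  set <- generate_synthetic_dataset(cfg)
  pos <- set$records$seq[set$records$label == 1L]
  neg <- set$records$seq[set$records$label == 0L]
  hit <- mean(grepl(cfg$motif, pos, fixed = TRUE))
  # >= because the motif can also arise by chance
  expect_gte(hit, 0.7)
  # chance occurrence in 300 bp of a specific 8-mer is ~1e-2
  expect_lte(mean(grepl(cfg$motif, neg, fixed = TRUE)), 0.1)
  skew <- function(s) {
    g <- vapply(gregexpr("G", s, fixed = TRUE), function(m)
      sum(m > 0), 0)
    c <- vapply(gregexpr("C", s, fixed = TRUE), function(m)
      sum(m > 0), 0)
    (g - c) / pmax(g + c, 1)
  }
  expect_gt(mean(skew(pos)), mean(skew(neg)) + 0.1)
})

test_that("generator validates its configuration", {
  expect_error(synthetic_config(n_per_class = 0), "positive")
  expect_error(synthetic_config(motif = strrep("ACGT", 100)),
               "longer than window")
  expect_error(synthetic_config(gc_skew_shift = 0.3), "gc_skew_shift")
  expect_error(synthetic_config(motif = "ACGN"), "position")
})

test_that("stratified folds partition all ids with balanced classes", {
  set <- small_bench(n = 53, seed = 2)
  folds <- split_folds(set, n_folds = 10, seed = 4)
  expect_identical(sort(names(folds$fold_of)), sort(set$records$id))
  expect_true(all(folds$fold_of %in% 1:10))
  lab <- set$records$label[match(names(folds$fold_of), set$records$id)]
  per_fold_pos <- table(folds$fold_of[lab == 1L])
  expect_lte(diff(range(per_fold_pos)), 1)
  per_fold_neg <- table(folds$fold_of[lab == 0L])
  expect_lte(diff(range(per_fold_neg)), 1)
  expect_identical(split_folds(set, 10, seed = 4)$fold_of, folds$fold_of)
  expect_error(split_folds(set, n_folds = 54), "minority class")
})

test_that("train_test_split holds out the requested stratified fraction", {
  set <- small_bench(n = 50, seed = 9)
  sp <- train_test_split(set, test_fraction = 0.2, seed = 1)
  expect_identical(nrow(sp$test$records), 20L)
  expect_identical(sum(sp$test$records$label), 10L)
  expect_identical(sort(c(sp$train$records$id, sp$test$records$id)),
                   sort(set$records$id))
})
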
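#' Stratified cross-validation fold assignment
#'
#' Partitions record ids into \code{n_folds} folds, stratified by label so
#' that per-fold class proportions are within one record of the global
#' proportion. Reproducible from \code{seed}.
#'
#' @param set A [labeled_sequence_set()] with both classes present.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A \code{fold_assignment} list with \code{n_folds}, \code{fold_of}
#'   (named integer vector id -> fold in 1..n_folds) and \code{seed}.
#' @export
split_folds <- function(set, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(set, "labeled_sequence_set"), n_folds >= 2L)
  r <- set$records
  if (anyNA(r$label) || length(unique(r$label)) < 2L)
    stop("both classes must be present and labelled", call. = FALSE)
  min_class <- min(table(r$label))
  if (n_folds > min_class)
    stop("n_folds (", n_folds, ") exceeds minority class size (",
         min_class, ")", call. = FALSE)
  fold_of <- integer(nrow(r))
  names(fold_of) <- r$id
  with_seed(seed, {
    for (cls in unique(r$label)) {
      idx <- which(r$label == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(n_folds = as.integer(n_folds), fold_of = fold_of,
                 seed = as.integer(seed)), class = "fold_assignment")
}

# subset a labeled_sequence_set by logical/integer index into records
subset_set <- function(set, idx) {
  r <- set$records[idx, , drop = FALSE]
  labeled_sequence_set(r$id, r$seq, r$label, tag = set$tag)
}

#' Stratified train/test split
#'
#' Emits an independent held-out split, mirroring a benchmark's train/test
#' separation.
#'
#' @param set A [labeled_sequence_set()].
#' @param test_fraction Fraction of each class held out (default 0.2).
#' @param seed Integer seed.
#' @return List with elements \code{train} and \code{test}.
#' @export
train_test_split <- function(set, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  r <- set$records
  test_idx <- with_seed(seed, unlist(lapply(unique(r$label), function(cls) {
    idx <- which(r$label == cls)
    sample(idx, max(1L, round(length(idx) * test_fraction)))
  }), use.names = FALSE))
  list(train = subset_set(set, setdiff(seq_len(nrow(r)), test_idx)),
       test = subset_set(set, sort(test_idx)))
}
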
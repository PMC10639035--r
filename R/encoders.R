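#' Named feature block
#'
#' A block of features computed by one encoder: an \code{n x p} matrix with
#' unique feature names and record-id rownames.
#'
#' @param name Block name: one of \code{"DL"}, \code{"CKSNAP"},
#'   \code{"PCPseDNC"}, \code{"DCC"}, \code{"PseDNC"}.
#' @param matrix Numeric matrix (rows = sequences).
#' @param feature_names Character vector of length \code{ncol(matrix)}.
#' @return A \code{feature_block}.
#' @export
feature_block <- function(name, matrix, feature_names) {
  stopifnot(is.matrix(matrix), length(feature_names) == ncol(matrix),
            !anyDuplicated(feature_names))
  colnames(matrix) <- feature_names
  structure(list(name = name, matrix = matrix,
                 feature_names = feature_names), class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat("feature_block '", x$name, "': ", nrow(x$matrix), " x ",
      ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

# dinucleotide ids (1..16) for codes separated by gap k
dinuc_ids <- function(codes, k = 0L) {
  n <- length(codes)
  (codes[seq_len(n - k - 1L)] - 1L) * 4L + codes[(k + 2L):n]
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP)
#'
#' For each gap \code{k}, the 16 frequencies of nucleotide pairs
#' \code{X (k bases) Y}, in AA..TT order, each count divided by the total
#' number of k-spaced pairs \code{L - k - 1}. Sub-blocks for increasing k
#' are concatenated.
#'
#' @param x A [labeled_sequence_set()] or character vector of ACGT strings.
#' @param k_values Integer vector of gaps (default \code{0:5}).
#' @return A [feature_block()] named \code{"CKSNAP"}; features
#'   \code{"CKSNAP:k{k}:{XY}"}.
#' @examples
#' cksnap("ACGT", k_values = 0)$matrix
#' @export
cksnap <- function(x, k_values = 0:5) {
  seqs <- as_sequence_vector(x)
  k_values <- sort(unique(as.integer(k_values)))
  stopifnot(all(k_values >= 0L))
  L <- nchar(seqs[1L])
  if (L <= max(k_values) + 1L)
    stop("sequence length ", L, " too short for gap k = ", max(k_values),
         call. = FALSE)
  out <- matrix(0, length(seqs), 16L * length(k_values))
  for (s in seq_along(seqs)) {
    codes <- seq_to_codes(seqs[s])
    out[s, ] <- unlist(lapply(k_values, function(k)
      tabulate(dinuc_ids(codes, k), 16L) / (L - k - 1L)))
  }
  rownames(out) <- names(seqs)
  feature_block("CKSNAP", out,
                unlist(lapply(k_values, function(k)
                  paste0("CKSNAP:k", k, ":", DINUCLEOTIDES))))
}

# 16 x 16 matrix of mean squared index differences between dinucleotides,
# the pairwise correlation function of the pseudo-composition encoders
dinuc_sq_diff <- function(P) {
  D2 <- matrix(0, 16L, 16L)
  for (a in seq_len(16L)) for (b in seq_len(16L))
    D2[a, b] <- mean((P[, a] - P[, b])^2)
  D2
}

pse_vector <- function(codes, lambda, w, D2) {
  d <- (codes[-length(codes)] - 1L) * 4L + codes[-1L]
  nf <- length(d)
  f <- tabulate(d, 16L) / nf
  theta <- vapply(seq_len(lambda), function(j)
    mean(D2[cbind(d[seq_len(nf - j)], d[(1L + j):nf])]), 0)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

pse_block <- function(x, lambda, w, table, block_name) {
  seqs <- as_sequence_vector(x)
  L <- nchar(seqs[1L])
  stopifnot(lambda >= 1L, w > 0, w <= 1)
  if (lambda >= L - 1L)
    stop("lambda (", lambda, ") must be < L - 1 = ", L - 1L, call. = FALSE)
  P <- index_values(table)
  if (nrow(P) == 0L) stop("empty index subset", call. = FALSE)
  D2 <- dinuc_sq_diff(P)
  out <- t(vapply(seqs, function(s)
    pse_vector(seq_to_codes(s), lambda, w, D2),
    numeric(16L + lambda), USE.NAMES = FALSE))
  rownames(out) <- names(seqs)
  feature_block(block_name, out,
                c(paste0(block_name, ":f:", DINUCLEOTIDES),
                  paste0(block_name, ":theta:", seq_len(lambda))))
}

#' Parallel-correlation pseudo dinucleotide composition (PCPseDNC)
#'
#' A vector of \code{16 + lambda} components: the 16 normalized dinucleotide
#' frequencies followed by \code{lambda} sequence-order correlation terms
#' weighted by \code{w}. The j-tier correlation is the mean, over positions,
#' of the mean squared difference of the (standardized) physicochemical
#' index values between dinucleotides j positions apart. The full vector is
#' normalized to sum to 1. PCPseDNC uses the 38-index default table; plain
#' [psednc()] uses the 6-index subset.
#'
#' @param x Sequences (set or character vector).
#' @param lambda Number of correlation tiers (default 2); must be < L - 1.
#' @param w Weight of the correlation terms, in (0, 1] (default 0.1).
#' @param table An [index_table()]; standardized internally if raw.
#' @return A [feature_block()]; features \code{"PCPseDNC:f:{XY}"} and
#'   \code{"PCPseDNC:theta:{j}"}.
#' @export
pcpsednc <- function(x, lambda = 2L, w = 0.1,
                     table = default_index_table("full38")) {
  pse_block(x, as.integer(lambda), w, table, "PCPseDNC")
}

#' Pseudo dinucleotide composition (PseDNC, 6 indices)
#'
#' Identical construction to [pcpsednc()] but over the 6-index subset.
#'
#' @inheritParams pcpsednc
#' @return A [feature_block()] named \code{"PseDNC"}.
#' @export
psednc <- function(x, lambda = 2L, w = 0.1,
                   table = default_index_table("pse6")) {
  pse_block(x, as.integer(lambda), w, table, "PseDNC")
}

#' Dinucleotide-based cross covariance (DCC)
#'
#' For each ordered pair of distinct physicochemical indices (u1, u2) and
#' each lag in \code{1..lag_max}, the covariance between the u1 value at a
#' dinucleotide and the u2 value at the dinucleotide \code{lag} positions
#' later, averaged over the \code{L - lag - 1} such position pairs; each
#' index is centred by its sequence-wide mean over all \code{L - 1}
#' dinucleotides.
#'
#' @param x Sequences (set or character vector).
#' @param lag_max Maximum lag (default 2); must satisfy
#'   \code{lag_max <= L - 2}.
#' @param indices Character vector of >= 2 index names; all ordered distinct
#'   pairs are used. Default \code{c("santalucia_dG", "santalucia_dH")}.
#' @param table An [index_table()] containing \code{indices}.
#' @return A [feature_block()] of width
#'   \code{n_idx * (n_idx - 1) * lag_max}; features
#'   \code{"DCC:{u1}|{u2}:lag{lag}"}.
#' @export
dcc <- function(x, lag_max = 2L,
                indices = c("santalucia_dG", "santalucia_dH"),
                table = default_index_table("full38")) {
  seqs <- as_sequence_vector(x)
  lag_max <- as.integer(lag_max)
  L <- nchar(seqs[1L])
  indices <- unique(indices)
  if (length(indices) < 2L)
    stop("need at least 2 distinct indices", call. = FALSE)
  if (lag_max < 1L || lag_max > L - 2L)
    stop("lag_max must satisfy 1 <= lag_max <= L - 2 = ", L - 2L,
         call. = FALSE)
  P <- index_values(subset_index_table(table, indices))
  pairs <- expand.grid(u2 = indices, u1 = indices,
                       stringsAsFactors = FALSE)[, c("u1", "u2")]
  pairs <- pairs[pairs$u1 != pairs$u2, , drop = FALSE]
  # order: for each u1 (table order), each u2, each lag
  pairs <- pairs[order(match(pairs$u1, indices), match(pairs$u2, indices)), ]
  out <- matrix(0, length(seqs), nrow(pairs) * lag_max)
  fnames <- character(ncol(out))
  for (s in seq_along(seqs)) {
    d <- dinuc_ids(seq_to_codes(seqs[s]), 0L)
    V <- P[, d, drop = FALSE]            # n_idx x (L-1) index values
    Vc <- V - rowMeans(V)
    col <- 0L
    for (p in seq_len(nrow(pairs))) {
      v1 <- Vc[pairs$u1[p], ]
      v2 <- Vc[pairs$u2[p], ]
      n <- length(d)
      for (lag in seq_len(lag_max)) {
        col <- col + 1L
        out[s, col] <- sum(v1[seq_len(n - lag)] * v2[(1L + lag):n]) / (n - lag)
        if (s == 1L)
          fnames[col] <- paste0("DCC:", pairs$u1[p], "|", pairs$u2[p],
                                ":lag", lag)
      }
    }
  }
  rownames(out) <- names(seqs)
  feature_block("DCC", out, fnames)
}
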
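#' Configuration for the synthetic ORI benchmark generator
#'
#' The generator emulates the geometry of published ORI benchmarks: positives
#' are fixed-length windows (default 300 bp) carrying a plantable
#' compositional signal, negatives are flank windows cut 300--600 bp away
#' from the positive window edge of the same simulated locus.
#'
#' Two signals are plantable in positives: a consensus motif inserted at a
#' uniform position with probability \code{motif_rate}, and a GC-skew shift
#' (\code{gc_skew_shift} is moved from the C to the G emission probability,
#' so positives are enriched in G relative to C while total GC stays at the
#' background value).
#'
#' @param n_per_class Positive (= negative) count.
#' @param window_length Window size in bp (default 300).
#' @param motif Planted consensus motif (ACGT string).
#' @param motif_rate Probability that a given positive carries the motif.
#' @param gc_skew_shift Probability mass moved from C to G in positives.
#' @param flank_offset_range Length-2 integer vector: the distance (bp) from
#'   the positive window edge to the near edge of the negative window is
#'   drawn uniformly from this range; the side (upstream/downstream) is
#'   chosen uniformly.
#' @param base_comp Background base composition, named A/C/G/T, summing to 1.
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_per_class = 500L, window_length = 300L,
                             motif = "ACGTACGT", motif_rate = 0.8,
                             gc_skew_shift = 0.05,
                             flank_offset_range = c(300L, 600L),
                             base_comp = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                             seed = 1L) {
  stopifnot(window_length >= 2L, motif_rate >= 0, motif_rate <= 1,
            length(flank_offset_range) == 2L,
            flank_offset_range[1L] >= 0L,
            flank_offset_range[2L] >= flank_offset_range[1L],
            abs(sum(base_comp) - 1) < 1e-8, all(base_comp >= 0))
  if (n_per_class <= 0L) stop("n_per_class must be positive", call. = FALSE)
  motif <- validate_sequence(motif)
  if (nchar(motif) > window_length)
    stop("motif longer than window", call. = FALSE)
  g <- base_comp[["G"]] + gc_skew_shift / 1
  if (gc_skew_shift > base_comp[["C"]] || gc_skew_shift < 0)
    stop("gc_skew_shift must lie in [0, base_comp['C']]", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 window_length = as.integer(window_length),
                 motif = motif, motif_rate = motif_rate,
                 gc_skew_shift = gc_skew_shift,
                 flank_offset_range = as.integer(flank_offset_range),
                 base_comp = base_comp, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic ORI benchmark
#'
#' For each of \code{n_per_class} simulated loci a background segment is
#' drawn i.i.d. from \code{base_comp} using 0-based half-open coordinates.
#' The positive window occupies \code{[0, L)} of the segment and is
#' re-emitted from the skewed composition (see [synthetic_config()]), then
#' the motif is planted at a uniform position with probability
#' \code{motif_rate}. The paired negative window is the untouched background
#' slice starting \code{offset} bp beyond the positive window edge, with
#' \code{offset} uniform in \code{flank_offset_range} and the side
#' (upstream/downstream) chosen uniformly per locus.
#'
#' @param cfg A [synthetic_config()].
#' @return A [labeled_sequence_set()] with \code{2 * n_per_class} records
#'   (positives first), tag \code{"synthetic"}.
#' @examples
#' set <- generate_synthetic_dataset(synthetic_config(n_per_class = 10))
#' table(set$records$label)
#' @export
generate_synthetic_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  L <- cfg$window_length
  n <- cfg$n_per_class
  omax <- cfg$flank_offset_range[2L]
  pos_comp <- cfg$base_comp
  pos_comp[["G"]] <- pos_comp[["G"]] + cfg$gc_skew_shift
  pos_comp[["C"]] <- pos_comp[["C"]] - cfg$gc_skew_shift
  motif_chars <- strsplit(cfg$motif, "")[[1]]
  mlen <- length(motif_chars)
  with_seed(cfg$seed, {
    pos_seqs <- character(n)
    neg_seqs <- character(n)
    for (i in seq_len(n)) {
      # segment spans [-(omax+L), L+omax+L) around the positive window
      seg_len <- 2L * (omax + L) + L
      seg <- sample(DNA_BASES, seg_len, replace = TRUE, prob = cfg$base_comp)
      origin <- omax + L  # 0-based segment index of positive window start
      pos <- sample(DNA_BASES, L, replace = TRUE, prob = pos_comp)
      if (stats::runif(1) < cfg$motif_rate) {
        at <- sample.int(L - mlen + 1L, 1L)
        pos[at:(at + mlen - 1L)] <- motif_chars
      }
      offset <- sample(seq.int(cfg$flank_offset_range[1L],
                               cfg$flank_offset_range[2L]), 1L)
      downstream <- stats::runif(1) < 0.5
      neg_start <- if (downstream) origin + L + offset
                   else origin - offset - L
      neg <- seg[(neg_start + 1L):(neg_start + L)]
      pos_seqs[i] <- paste(pos, collapse = "")
      neg_seqs[i] <- paste(neg, collapse = "")
    }
    labeled_sequence_set(
      ids = c(sprintf("locus%04d_pos", seq_len(n)),
              sprintf("locus%04d_neg", seq_len(n))),
      seqs = c(pos_seqs, neg_seqs),
      labels = c(rep(1L, n), rep(0L, n)),
      tag = "synthetic")
  })
}
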
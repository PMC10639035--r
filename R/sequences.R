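#' @useDynLib oripredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")
DINUCLEOTIDES <- paste0(rep(DNA_BASES, each = 4), DNA_BASES)

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Validate a DNA sequence against the ACGT alphabet
#'
#' Sequences are upper-cased, then characters outside \code{A/C/G/T} are
#' handled according to \code{policy}: \code{"strict"} raises an error naming
#' the offending positions, \code{"drop"} flags the record for exclusion
#' (returns \code{NA}), and \code{"randomize"} replaces each ambiguous
#' character with a seeded uniform draw from \code{A/C/G/T}.
#'
#' @param seq A single character string.
#' @param policy One of \code{"strict"}, \code{"drop"}, \code{"randomize"}.
#' @param seed Integer seed used by the \code{"randomize"} policy.
#' @return The validated (upper-case) sequence, or \code{NA_character_} under
#'   the \code{"drop"} policy when ambiguous characters are present.
#' @examples
#' validate_sequence("acgt")
#' validate_sequence("ACGN", policy = "randomize", seed = 7)
#' @export
validate_sequence <- function(seq, policy = c("strict", "drop", "randomize"),
                              seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) == 0L) return(seq)
  switch(policy,
    strict = stop("ambiguous or invalid base(s) at position(s) ",
                  paste(bad, collapse = ", "), call. = FALSE),
    drop = NA_character_,
    randomize = {
      chars[bad] <- with_seed(seed,
        sample(DNA_BASES, length(bad), replace = TRUE))
      paste(chars, collapse = "")
    })
}

#' Construct a labelled set of fixed-length sequence windows
#'
#' @param ids Character vector of unique record ids.
#' @param seqs Character vector of validated ACGT sequences, all of one length.
#' @param labels Optional integer vector of 0/1 labels (or \code{NA}).
#' @param tag Name of the cell line / species / benchmark the set represents.
#' @return An object of class \code{labeled_sequence_set} with elements
#'   \code{records} (data.frame: id, seq, label), \code{window_length},
#'   \code{class_counts} and \code{tag}.
#' @export
labeled_sequence_set <- function(ids, seqs, labels = NULL, tag = "") {
  stopifnot(length(ids) == length(seqs), length(ids) > 0L, !anyDuplicated(ids))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("all sequences must share one window length; observed lengths: ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  if (is.null(labels)) labels <- rep(NA_integer_, length(ids))
  labels <- as.integer(labels)
  if (!all(is.na(labels) | labels %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA", call. = FALSE)
  structure(list(
    records = data.frame(id = as.character(ids), seq = as.character(seqs),
                         label = labels, stringsAsFactors = FALSE),
    window_length = lens[1L],
    class_counts = table(factor(labels, levels = c(0L, 1L))),
    tag = tag), class = "labeled_sequence_set")
}

#' @export
print.labeled_sequence_set <- function(x, ...) {
  cat("labeled_sequence_set", if (nzchar(x$tag)) paste0("'", x$tag, "'"), "\n")
  cat("  records:", nrow(x$records), " window:", x$window_length, "bp\n")
  cat("  class counts: neg =", x$class_counts[["0"]],
      " pos =", x$class_counts[["1"]], "\n")
  invisible(x)
}

#' Read labelled sequence windows from a FASTA file
#'
#' Labels are taken from a \code{"|0"} / \code{"|1"} suffix on each header,
#' or, when \code{labels} points at a two-column TSV (id, label), from that
#' table (which overrides header suffixes).
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to an id/label TSV (no header).
#' @param policy Ambiguous-base policy passed to [validate_sequence()];
#'   \code{"drop"} silently excludes offending records.
#' @param seed Seed for the \code{"randomize"} policy.
#' @param tag Dataset tag stored on the returned set.
#' @return A [labeled_sequence_set()].
#' @export
read_fasta <- function(path, labels = NULL, policy = "strict", seed = 1L,
                       tag = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
    stop("malformed FASTA at line ", nonempty[1L],
         ": expected '>' header", call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no records in ", path, call. = FALSE)
  headers <- names(x)
  ids <- sub("\\|[01]$", "", headers)
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  lab <- rep(NA_integer_, length(x))
  has_suffix <- grepl("\\|[01]$", headers)
  lab[has_suffix] <- as.integer(sub("^.*\\|", "", headers[has_suffix]))
  if (!is.null(labels)) {
    tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    m <- match(ids, tab$id)
    lab[!is.na(m)] <- tab$label[m[!is.na(m)]]
  }
  seqs <- as.character(x)
  seqs <- vapply(seq_along(seqs), function(i)
    validate_sequence(seqs[i], policy = policy, seed = seed + i), "")
  keep <- !is.na(seqs)
  labeled_sequence_set(ids[keep], seqs[keep], lab[keep], tag = tag)
}

#' Write a labelled sequence set to FASTA
#'
#' Headers carry labels as \code{id|label}; unlabeled records get a bare id.
#' Output is deterministic (one sequence line per record).
#'
#' @param set A [labeled_sequence_set()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "labeled_sequence_set"))
  r <- set$records
  hdr <- ifelse(is.na(r$label), paste0(">", r$id),
                paste0(">", r$id, "|", r$label))
  writeLines(as.vector(rbind(hdr, r$seq)), path)
  invisible(path)
}

# integer base codes 1..4 (A,C,G,T) for one sequence
seq_to_codes <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  if (anyNA(codes)) stop("sequence contains non-ACGT characters", call. = FALSE)
  codes
}

# n x L integer matrix of base codes for equal-length sequences
seqs_to_code_matrix <- function(seqs) {
  t(vapply(seqs, seq_to_codes, integer(nchar(seqs[1L])), USE.NAMES = FALSE))
}

as_sequence_vector <- function(x) {
  if (inherits(x, "labeled_sequence_set")) {
    stats::setNames(x$records$seq, x$records$id)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else stop("expected a labeled_sequence_set or character vector",
              call. = FALSE)
}
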
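#' Dinucleotide physicochemical index tables
#'
#' An index table maps each of the 16 dinucleotides (AA, AC, ..., TT in
#' lexicographic order) to a numeric value under each named property
#' ("index"). The pseudo-composition and cross-covariance encoders consume
#' tables after per-index z-standardization across the 16 dinucleotides, so
#' only relative differences between dinucleotides matter.
#'
#' The bundled default table (\code{inst/extdata/dinucleotide_properties.tsv})
#' holds 38 indices: the SantaLucia (1998) unified nearest-neighbour
#' thermodynamic parameters (free energy, enthalpy, entropy of each duplex
#' step) plus 35 exactly-defined compositional descriptors (GC content,
#' purine/keto content, GC/AT skew, per-base counts, positional base
#' indicators, dinucleotide indicators, homodimer and transition-step flags).
#' Any user table in the same TSV layout can be substituted.
#'
#' @param values Numeric matrix, indices in rows (rownames = index names),
#'   16 dinucleotide columns named AA..TT.
#' @param standardized Logical; whether rows are already z-scored.
#' @param provenance Character vector (one per index) of source notes.
#' @return An \code{index_table} object.
#' @export
index_table <- function(values, standardized = FALSE, provenance = NULL) {
  stopifnot(is.matrix(values), ncol(values) == 16L,
            !is.null(rownames(values)), all(is.finite(values)))
  if (is.null(colnames(values))) colnames(values) <- DINUCLEOTIDES
  stopifnot(identical(colnames(values), DINUCLEOTIDES))
  if (is.null(provenance)) provenance <- rep("", nrow(values))
  structure(list(values = values, standardized = standardized,
                 provenance = provenance), class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat("index_table:", nrow(x$values), "indices,",
      if (x$standardized) "standardized" else "raw", "\n")
  cat(" ", paste(utils::head(rownames(x$values), 8L), collapse = ", "),
      if (nrow(x$values) > 8L) "...", "\n")
  invisible(x)
}

#' Read an index table from TSV
#'
#' Layout: columns \code{index}, \code{AA} .. \code{TT}, optional
#' \code{source}.
#'
#' @param path TSV file path.
#' @return An [index_table()] (raw, not standardized).
#' @export
read_index_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("index", DINUCLEOTIDES) %in% colnames(df)))
  m <- as.matrix(df[, DINUCLEOTIDES])
  rownames(m) <- df$index
  index_table(m, standardized = FALSE,
              provenance = if ("source" %in% colnames(df)) df$source
                           else NULL)
}

#' Bundled default index table
#'
#' @param subset \code{"full38"} for all 38 indices (the PCPseDNC default
#'   count), \code{"pse6"} for the 6-index subset used by plain PseDNC
#'   (thermodynamic dG/dH/dS plus GC content and GC/AT skew), or a character
#'   vector of index names.
#' @return A raw [index_table()].
#' @export
default_index_table <- function(subset = c("full38", "pse6")) {
  tab <- read_index_table(system.file("extdata",
                                      "dinucleotide_properties.tsv",
                                      package = "oripredict"))
  if (is.character(subset) && length(subset) == 1L &&
      subset %in% c("full38", "pse6")) {
    subset <- match.arg(subset)
    if (subset == "pse6")
      tab <- subset_index_table(tab, c("santalucia_dG", "santalucia_dH",
                                       "santalucia_dS", "gc_content",
                                       "gc_skew", "at_skew"))
    tab
  } else subset_index_table(tab, subset)
}

#' Restrict an index table to named indices
#' @param table An [index_table()].
#' @param indices Character vector of index names to keep (order preserved).
#' @return An [index_table()].
#' @export
subset_index_table <- function(table, indices) {
  stopifnot(inherits(table, "index_table"))
  missing <- setdiff(indices, rownames(table$values))
  if (length(missing))
    stop("unknown indices: ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- match(indices, rownames(table$values))
  index_table(table$values[keep, , drop = FALSE], table$standardized,
              table$provenance[keep])
}

#' Z-standardize an index table
#'
#' Each index row is centred and scaled to population standard deviation 1
#' across the 16 dinucleotides. Idempotent; errors on a constant index.
#'
#' @param table An [index_table()].
#' @return A standardized [index_table()].
#' @export
standardize_index_table <- function(table) {
  stopifnot(inherits(table, "index_table"))
  v <- table$values
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))
  if (any(sdev < 1e-12))
    stop("constant index (zero SD): ",
         paste(rownames(v)[sdev < 1e-12], collapse = ", "), call. = FALSE)
  index_table((v - mu) / sdev, standardized = TRUE,
              provenance = table$provenance)
}

# standardized values matrix, standardizing on demand
index_values <- function(table) {
  if (!table$standardized) table <- standardize_index_table(table)
  table$values
}
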
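# The msa container: an M x N integer-coded matrix of aligned residues with
# sequence labels, 1-based attribute (column) identifiers and an optional
# reference-sequence renumbering map.

#' Construct an aligned-sequence matrix object
#'
#' The central data structure: `M` sequences by `N` aligned sites, encoded
#' over [default_alphabet()]. Columns carry unique, strictly increasing,
#' 1-based integer *attribute* identifiers which survive column filtering
#' unchanged, so cluster reports always refer to positions in the original
#' alignment.
#'
#' @param mat Integer matrix of symbol codes (M rows, N columns) or a
#'   character matrix of symbols to be encoded.
#' @param seq_labels Character vector of M sequence identifiers.
#' @param attribute_ids Integer vector of N unique, strictly increasing,
#'   positive column identifiers. Defaults to `1:N`.
#' @param reference_map Optional named integer vector mapping attribute ids
#'   (names) to reference-sequence residue numbers; `NA` marks unmapped
#'   columns. Usually built with [build_reference_map()].
#' @param alphabet A `symbol_alphabet`.
#' @return An object of class `msa`.
#' @seealso [read_msa()], [msa_from_strings()]
#' @export
new_msa <- function(mat, seq_labels = NULL, attribute_ids = NULL,
                    reference_map = NULL, alphabet = default_alphabet()) {
  if (is.character(mat)) {
    dm <- dim(mat)
    mat <- matrix(encode_symbols(as.vector(mat), alphabet), dm[1], dm[2])
  }
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("'mat' must be an integer or character matrix")
  }
  storage.mode(mat) <- "integer"
  m <- nrow(mat); n <- ncol(mat)
  if (m < 2L) stop("an alignment needs at least 2 sequences (M >= 2)")
  if (n < 2L) stop("an alignment needs at least 2 columns (N >= 2)")
  if (is.null(seq_labels)) seq_labels <- sprintf("seq%d", seq_len(m))
  if (length(seq_labels) != m) stop("seq_labels must have one entry per row")
  if (is.null(attribute_ids)) attribute_ids <- seq_len(n)
  attribute_ids <- as.integer(attribute_ids)
  if (length(attribute_ids) != n ||
      anyDuplicated(attribute_ids) ||
      any(attribute_ids < 1L) ||
      is.unsorted(attribute_ids, strictly = TRUE)) {
    stop("attribute_ids must be unique, positive and strictly increasing")
  }
  if (any(mat < 1L) || any(mat > length(alphabet$symbols))) {
    stop("matrix cells must be codes from the declared alphabet")
  }
  if (!is.null(reference_map)) {
    mapped <- reference_map[!is.na(reference_map)]
    if (anyDuplicated(mapped)) {
      stop("reference_map must be injective over mapped positions")
    }
  }
  structure(list(
    matrix = mat,
    seq_labels = as.character(seq_labels),
    attribute_ids = attribute_ids,
    reference_map = reference_map,
    alphabet = alphabet
  ), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (attributes %d..%d)\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$attribute_ids), max(x$attribute_ids)))
  gf <- mean(!is_residue_code(x$matrix, x$alphabet))
  cat(sprintf("  gap/unknown fraction: %.3f; reference map: %s\n",
              gf, if (is.null(x$reference_map)) "none" else "present"))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$matrix)

# column of codes for one attribute id
msa_column <- function(aln, a) {
  j <- match(a, aln$attribute_ids)
  if (is.na(j)) stop("attribute ", a, " is not present in the alignment")
  aln$matrix[, j]
}

#' Build an alignment from aligned strings
#'
#' Convenience constructor used in examples and tests: one string per
#' sequence, all the same width.
#'
#' @param x Character vector of aligned sequences.
#' @param seq_labels Optional sequence labels.
#' @inheritParams new_msa
#' @return An `msa`.
#' @examples
#' msa_from_strings(c("ACDE", "AC-E", "ACDE"))
#' @export
msa_from_strings <- function(x, seq_labels = NULL,
                             alphabet = default_alphabet()) {
  if (length(unique(nchar(x))) != 1L) {
    stop("all sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  new_msa(mat, seq_labels = seq_labels, alphabet = alphabet)
}

#' Per-column gap/unknown fraction
#'
#' @param aln An `msa`.
#' @return Named numeric vector (names = attribute ids) of the fraction of
#'   gap-or-unknown symbols per column.
#' @export
gap_fraction <- function(aln) {
  frac <- colMeans(!is_residue_code(aln$matrix, aln$alphabet))
  stats::setNames(frac, aln$attribute_ids)
}
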
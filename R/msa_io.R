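# Reading and writing aligned sequence data (FASTA and a CSV matrix
# dialect), reference renumbering, and gap-based column filtering.

#' Read an aligned protein MSA
#'
#' Reads a pre-aligned FASTA file (via Biostrings, headers kept verbatim) or
#' a CSV matrix dialect in which each row is one sequence, each remaining
#' cell one residue, and an optional first column holds sequence labels
#' (auto-detected by cell width). Symbols are upper-cased; characters
#' outside the alphabet are mapped to unknown (`X`) with a warning giving
#' the count. Ragged alignments are an error naming the first offending
#' record, never silently padded.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by file extension), `"fasta"` or `"csv"`.
#' @param alphabet A `symbol_alphabet`.
#' @return An [new_msa()] object with `M >= 2`, `N >= 2` and
#'   `attribute_ids = 1:N`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "AC-E"), f)
#' read_msa(f)
#' @export
read_msa <- function(path, format = c("auto", "fasta", "csv"),
                     alphabet = default_alphabet()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(csv|txt)$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (format == "fasta") .read_msa_fasta(path, alphabet) else .read_msa_csv(path, alphabet)
}

.normalize_cells <- function(cells, alphabet) {
  cells <- toupper(cells)
  bad <- !(cells %in% alphabet$symbols)
  if (any(bad)) {
    warning(sum(bad), " unrecognized symbol(s) mapped to unknown ('X')")
    cells[bad] <- "X"
  }
  cells
}

.read_msa_fasta <- function(path, alphabet) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty file: ", path)
  if (length(set) < 2L) {
    stop("need at least 2 sequences; mutual information is undefined on one")
  }
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L) {
    off <- which(w != w[1])[1]
    stop(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      names(set)[off], w[off], w[1]))
  }
  cells <- .normalize_cells(
    unlist(strsplit(as.character(set), "", fixed = TRUE), use.names = FALSE),
    alphabet)
  mat <- matrix(encode_symbols(cells, alphabet), nrow = length(set),
                ncol = w[1], byrow = TRUE)
  new_msa(mat, seq_labels = names(set), alphabet = alphabet)
}

.read_msa_csv <- function(path, alphabet) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  rows <- lapply(rows, trimws)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1])[1]
    stop(sprintf("ragged alignment: CSV row %d has %d cells, expected %d",
                 off, lens[off], lens[1]))
  }
  first <- vapply(rows, `[[`, "", 1L)
  has_labels <- any(nchar(first) != 1L) ||
    !all(toupper(first) %in% alphabet$symbols)
  if (has_labels) {
    labels <- first
    rows <- lapply(rows, `[`, -1L)
  } else {
    labels <- sprintf("seq%d", seq_along(rows))
  }
  if (length(rows) < 2L) {
    stop("need at least 2 sequences; mutual information is undefined on one")
  }
  if (length(rows[[1]]) < 2L) stop("need at least 2 columns")
  cells <- .normalize_cells(unlist(rows, use.names = FALSE), alphabet)
  mat <- matrix(encode_symbols(cells, alphabet), nrow = length(rows),
                byrow = TRUE)
  new_msa(mat, seq_labels = labels, alphabet = alphabet)
}

#' Write an alignment
#'
#' FASTA output is normalised to 60-character lines with verbatim headers,
#' so `write_msa(read_msa(f))` is byte-identical for already-normalised
#' input. CSV output writes one labelled row per sequence.
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @param format `"fasta"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path, format = c("fasta", "csv")) {
  format <- match.arg(format)
  chars <- matrix(decode_symbols(as.vector(aln$matrix), aln$alphabet),
                  nrow = nrow(aln$matrix))
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(chars))) {
      s <- paste(chars[i, ], collapse = "")
      writeLines(c(paste0(">", aln$seq_labels[i]),
                   substring(s, seq(1, nchar(s), 60),
                             pmin(seq(1, nchar(s), 60) + 59, nchar(s)))),
                 con)
    }
  } else {
    rows <- vapply(seq_len(nrow(chars)), function(i) {
      paste(c(aln$seq_labels[i], chars[i, ]), collapse = ",")
    }, "")
    writeLines(rows, path)
  }
  invisible(path)
}

#' Renumber columns by a reference sequence
#'
#' Attaches a reference map so that cluster members can be reported as
#' residue numbers of a chosen template sequence (e.g. numbering sites by
#' the human orthologue). A column maps to the count of non-gap reference
#' symbols up to and including it when the reference row holds a residue
#' there; columns where the reference row is gapped (or unknown) are
#' unmapped (`NA`).
#'
#' @param aln An `msa`.
#' @param reference_label A label present in `aln$seq_labels`.
#' @return The `msa` with `reference_map` set (names = attribute ids).
#' @examples
#' aln <- msa_from_strings(c("A-CD", "AACD"), c("ref", "s2"))
#' build_reference_map(aln, "ref")$reference_map
#' @export
build_reference_map <- function(aln, reference_label) {
  i <- match(reference_label, aln$seq_labels)
  if (is.na(i)) stop("no sequence labelled '", reference_label, "'")
  row <- aln$matrix[i, ]
  nongap <- !(row %in% aln$alphabet$gap_codes)
  residue <- is_residue_code(row, aln$alphabet)
  resno <- cumsum(nongap)
  map <- ifelse(residue, resno, NA_integer_)
  aln$reference_map <- stats::setNames(as.integer(map), aln$attribute_ids)
  aln
}

#' Drop columns dominated by gaps
#'
#' Retains columns whose combined gap-plus-unknown fraction is at most
#' `gap_cutoff` (the "35% cutoff" style of pre-filter). Retained columns
#' keep their original attribute ids; nothing is renumbered.
#'
#' @param aln An `msa`.
#' @param gap_cutoff Maximum tolerated gap+unknown fraction, in `[0, 1]`.
#' @return A list with `alignment` (the filtered `msa`) and `excluded`
#'   (data.frame of `attribute_id`, `gap_fraction` for dropped columns).
#' @export
filter_columns <- function(aln, gap_cutoff) {
  if (!is.numeric(gap_cutoff) || gap_cutoff < 0 || gap_cutoff > 1) {
    stop("gap_cutoff must be a fraction in [0, 1]")
  }
  gf <- gap_fraction(aln)
  keep <- gf <= gap_cutoff
  excluded <- data.frame(attribute_id = aln$attribute_ids[!keep],
                         gap_fraction = unname(gf[!keep]))
  if (sum(keep) < 2L) {
    stop("fewer than 2 columns survive gap_cutoff = ", gap_cutoff,
         "; use a larger cutoff")
  }
  out <- aln
  out$matrix <- aln$matrix[, keep, drop = FALSE]
  out$attribute_ids <- aln$attribute_ids[keep]
  if (!is.null(aln$reference_map)) {
    out$reference_map <- aln$reference_map[as.character(out$attribute_ids)]
  }
  list(alignment = out, excluded = excluded)
}
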
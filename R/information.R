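# Column entropy, gap-nullified contingency tables, and symmetric
# normalized mutual information (NMI) between column pairs.
#
# All entropies are Shannon entropies in bits. Probabilities are plain
# empirical frequencies (no pseudocounts, no small-sample correction).
# Gaps and unknown symbols never contribute: a contingency table is
# "nullified" by zeroing every cell whose row or column symbol is a gap or
# unknown, and entropies/MI are computed from the nullified table, i.e.
# from the sequences that carry a residue at BOTH positions.

# Core pair statistics on encoded columns. Rows where either symbol is a
# gap/unknown are dropped; counts-based entropy avoids accumulating the
# same rounding twice for the two marginals.
.pair_core <- function(x, y, n_res) {
  ok <- (x <= n_res) & (y <= n_res)
  n <- sum(ok)
  if (n == 0L) {
    return(list(n_effective = 0L, mi = NA_real_, h_a = NA_real_,
                h_b = NA_real_, k_a = 0L, k_b = 0L))
  }
  tab <- tabulate((x[ok] - 1L) * n_res + y[ok], nbins = n_res * n_res)
  jm <- matrix(tab, nrow = n_res, ncol = n_res, byrow = TRUE)
  ra <- rowSums(jm)
  cb <- colSums(jm)
  h_counts <- function(cnt) {
    cnt <- cnt[cnt > 0L]
    log2(n) - sum(cnt * log2(cnt)) / n
  }
  nz <- which(jm > 0L, arr.ind = TRUE, useNames = FALSE)
  cc <- jm[nz]
  mi <- sum(cc * log2((cc * n) / (ra[nz[, 1L]] * cb[nz[, 2L]]))) / n
  list(n_effective = n, mi = max(mi, 0), h_a = h_counts(ra),
       h_b = h_counts(cb), k_a = sum(ra > 0L), k_b = sum(cb > 0L))
}

# Status / value decision shared by pair_nmi() and nmi_matrix().
# A perfectly invariant pair (one residue symbol on each axis of the
# nullified table) is scored 1 and flagged; a denominator below
# epsilon_inv bits cannot normalise the MI and the pair is excluded.
.pair_decide <- function(core, epsilon_inv) {
  if (core$n_effective == 0L) {
    return(list(nmi = NA_real_, status = "undefined_low_entropy"))
  }
  if (core$k_a == 1L && core$k_b == 1L) {
    return(list(nmi = 1, status = "perfectly_invariant_pair"))
  }
  den <- min(core$h_a, core$h_b)
  if (den < epsilon_inv || core$mi > den * (1 + 1e-9)) {
    return(list(nmi = NA_real_, status = "undefined_low_entropy"))
  }
  list(nmi = min(core$mi / den, 1), status = "ok")
}

#' Shannon entropy of one alignment column
#'
#' Entropy in bits of the empirical residue distribution of a column,
#' computed over non-gap, non-unknown symbols only. A perfectly invariant
#' column has entropy 0; a column with no residue content at all has no
#' finite entropy basis and returns `NA`.
#'
#' @param aln An `msa`.
#' @param a An attribute id present in the alignment.
#' @return Entropy in bits (`NA` for an all-gap column).
#' @examples
#' aln <- msa_from_strings(c("AA", "AC", "CA", "CC"))
#' column_entropy(aln, 1)  # 1 bit
#' @export
column_entropy <- function(aln, a) {
  x <- msa_column(aln, a)
  n_res <- aln$alphabet$n_residues
  cnt <- tabulate(x[x <= n_res], nbins = n_res)
  n <- sum(cnt)
  if (n == 0L) return(NA_real_)
  cnt <- cnt[cnt > 0L]
  log2(n) - sum(cnt * log2(cnt)) / n
}

#' Gap-nullified contingency table for a column pair
#'
#' Tabulates co-occurring symbols of two columns across all sequences, then
#' nullifies the table: every cell whose row or column symbol is a gap or
#' unknown is zeroed and the effective count is recomputed, so downstream
#' entropies and MI see only sequences with residues at both positions.
#'
#' @param aln An `msa`.
#' @param a,b Two distinct attribute ids.
#' @return An object of class `contingency_table`: list with `counts`
#'   (nullified residue-by-residue table, symbol dimnames), `raw_counts`
#'   (pre-nullification table over all symbols), `nullified = TRUE` and
#'   `n_effective`.
#' @export
contingency <- function(aln, a, b) {
  if (a == b) stop("a and b must be distinct attributes")
  ab <- aln$alphabet
  x <- msa_column(aln, a)
  y <- msa_column(aln, b)
  k <- length(ab$symbols)
  raw <- matrix(tabulate((x - 1L) * k + y, nbins = k * k),
                nrow = k, ncol = k, byrow = TRUE,
                dimnames = list(ab$symbols, ab$symbols))
  res <- seq_len(ab$n_residues)
  counts <- raw
  counts[-res, ] <- 0L
  counts[, -res] <- 0L
  structure(list(
    a = a, b = b,
    counts = counts[res, res],
    raw_counts = raw,
    nullified = TRUE,
    n_effective = sum(counts)
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("nullified contingency table for attributes %d x %d (n_effective = %d)\n",
              x$a, x$b, x$n_effective))
  keep_r <- rowSums(x$counts) > 0
  keep_c <- colSums(x$counts) > 0
  print(x$counts[keep_r, keep_c, drop = FALSE])
  invisible(x)
}

#' Normalized mutual information between two columns
#'
#' The pairwise interdependency score: mutual information of the nullified
#' contingency table, normalised into `[0, 1]` by the smaller of the two
#' column entropies computed on the same table. The score is symmetric and
#' invariant to reordering the sequences. A pair of perfectly invariant
#' columns is flagged `perfectly_invariant_pair` and scored 1 (maximally
#' conserved sites are treated as highly important); a pair whose smaller
#' entropy is below `epsilon_inv` bits cannot be normalised and is flagged
#' `undefined_low_entropy` with `nmi = NA` -- such pairs are excluded from
#' clustering.
#'
#' @param aln An `msa`.
#' @param a,b Two distinct attribute ids.
#' @param epsilon_inv Minimum entropy (bits) accepted as a normalisation
#'   denominator; also the near-invariance threshold of
#'   [classify_column()]. Default 0.05.
#' @return An object of class `pair_score`: list with `a`, `b`, `nmi`,
#'   `status` (`"ok"`, `"perfectly_invariant_pair"` or
#'   `"undefined_low_entropy"`), `mi`, `h_a`, `h_b`, `n_effective`.
#' @examples
#' aln <- msa_from_strings(c("AG", "CT", "AG", "CT"))
#' pair_nmi(aln, 1, 2)$nmi  # 1: columns related by a symbol bijection
#' @export
pair_nmi <- function(aln, a, b, epsilon_inv = 0.05) {
  if (a == b) stop("a and b must be distinct attributes")
  # canonical argument order guarantees bit-for-bit symmetry
  lo <- min(a, b); hi <- max(a, b)
  core <- .pair_core(msa_column(aln, lo), msa_column(aln, hi),
                     aln$alphabet$n_residues)
  dec <- .pair_decide(core, epsilon_inv)
  swap <- a > b
  structure(list(
    a = a, b = b,
    nmi = dec$nmi, status = dec$status,
    mi = core$mi,
    h_a = if (swap) core$h_b else core$h_a,
    h_b = if (swap) core$h_a else core$h_b,
    n_effective = core$n_effective
  ), class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("pair (%d, %d): nmi = %s [%s], n_effective = %d\n",
              x$a, x$b, format(x$nmi, digits = 4), x$status, x$n_effective))
  invisible(x)
}

#' Classify a column as variable or (im)perfectly invariant
#'
#' A column with exactly one residue symbol is *perfectly invariant*
#' (entropy 0). A column with more than one symbol but entropy below
#' `epsilon_inv` bits is *imperfectly invariant*: its entropy is too small
#' to normalise mutual information, so it is excluded from scoring but
#' reported. Everything else is *variable*. A column with no residue
#' content at all is also flagged imperfectly invariant (unusable), with
#' `NA` entropy.
#'
#' @inheritParams column_entropy
#' @param epsilon_inv Near-invariance entropy threshold in bits.
#' @return A list with `attribute_id`, `entropy_bits`, `n_symbols` and
#'   `klass`.
#' @export
classify_column <- function(aln, a, epsilon_inv = 0.05) {
  x <- msa_column(aln, a)
  n_res <- aln$alphabet$n_residues
  cnt <- tabulate(x[x <= n_res], nbins = n_res)
  k <- sum(cnt > 0L)
  h <- column_entropy(aln, a)
  klass <- if (k == 1L) {
    "perfectly_invariant"
  } else if (k == 0L || h < epsilon_inv) {
    "imperfectly_invariant"
  } else {
    "variable"
  }
  list(attribute_id = a, entropy_bits = h, n_symbols = k, klass = klass)
}

#' Classify every column of an alignment
#'
#' @inheritParams classify_column
#' @return A data.frame with one row per attribute: `attribute_id`,
#'   `entropy_bits`, `n_symbols`, `klass`.
#' @export
classify_columns <- function(aln, epsilon_inv = 0.05) {
  rows <- lapply(aln$attribute_ids, classify_column, aln = aln,
                 epsilon_inv = epsilon_inv)
  data.frame(
    attribute_id = vapply(rows, `[[`, 0L, "attribute_id"),
    entropy_bits = vapply(rows, `[[`, 0, "entropy_bits"),
    n_symbols = vapply(rows, `[[`, 0L, "n_symbols"),
    klass = vapply(rows, `[[`, "", "klass")
  )
}

#' All pairwise NMI scores
#'
#' Computes the symmetric NMI matrix over a set of attributes. Pairs that
#' are not `status = "ok"` carry `NA` in the score matrix and are listed in
#' `flagged`; they take no part in clustering.
#'
#' @param aln An `msa`.
#' @param attrs Attribute ids to score (default: all columns of `aln`).
#' @param epsilon_inv See [pair_nmi()].
#' @return An object of class `nmi_scores`: list with `nmi` (symmetric
#'   matrix, dimnames = attribute ids, `NA` diagonal and `NA` for non-ok
#'   pairs), `status` (character matrix), `attrs`, `epsilon_inv`, and
#'   `flagged` (data.frame of excluded pairs).
#' @export
nmi_matrix <- function(aln, attrs = NULL, epsilon_inv = 0.05) {
  if (is.null(attrs)) attrs <- aln$attribute_ids
  attrs <- sort(as.integer(attrs))
  if (!all(attrs %in% aln$attribute_ids)) {
    stop("attrs contains attributes not present in the alignment")
  }
  p <- length(attrs)
  cols <- aln$matrix[, match(attrs, aln$attribute_ids), drop = FALSE]
  n_res <- aln$alphabet$n_residues
  nm <- matrix(NA_real_, p, p, dimnames = list(attrs, attrs))
  st <- matrix("self", p, p, dimnames = list(attrs, attrs))
  for (i in seq_len(p - 1L)) {
    xi <- cols[, i]
    for (j in seq((i + 1L), p)) {
      dec <- .pair_decide(.pair_core(xi, cols[, j], n_res), epsilon_inv)
      nm[i, j] <- nm[j, i] <- if (dec$status == "ok") dec$nmi else NA_real_
      st[i, j] <- st[j, i] <- dec$status
    }
  }
  ut <- which(upper.tri(st) & st != "ok" & st != "self", arr.ind = TRUE)
  flagged <- data.frame(a = attrs[ut[, 1L]], b = attrs[ut[, 2L]],
                        status = st[ut])
  structure(list(nmi = nm, status = st, attrs = attrs,
                 epsilon_inv = epsilon_inv, flagged = flagged),
            class = "nmi_scores")
}

#' @export
print.nmi_scores <- function(x, ...) {
  cat(sprintf("nmi_scores: %d attributes, %d scored pairs, %d flagged\n",
              length(x$attrs),
              sum(!is.na(x$nmi[upper.tri(x$nmi)])),
              nrow(x$flagged)))
  invisible(x)
}

# Accept an nmi_scores object or a plain numeric matrix with attribute-id
# dimnames; returns the usable-score matrix (NA = unusable pair).
.score_matrix <- function(scores) {
  if (inherits(scores, "nmi_scores")) return(scores$nmi)
  m <- as.matrix(scores)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- seq_len(nrow(m))
  }
  m
}
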
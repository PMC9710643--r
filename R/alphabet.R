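# Symbol alphabet: 20 canonical residues plus gap and unknown classes.
# Codes 1..20 are residues; downstream nullification treats gap and unknown
# identically (both are removed from contingency tables).

AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_SYMBOLS <- c("-", ".")
UNKNOWN_SYMBOLS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Default symbol alphabet
#'
#' The integer encoding used throughout the package: the 20 canonical amino
#' acids map to codes 1--20, gap symbols (`-`, `.`) and unknown/ambiguous
#' symbols (`X`, `B`, `Z`, `J`, `U`, `O`, `*`) to codes above 20. The three
#' symbol classes are pairwise disjoint and the encoding is a bijection, so
#' decoding recovers the input exactly.
#'
#' @return An object of class `symbol_alphabet` with elements `symbols`
#'   (character vector, position = code), `codes` (named integer vector),
#'   `n_residues`, `gap_codes` and `unknown_codes`.
#' @examples
#' ab <- default_alphabet()
#' decode_symbols(encode_symbols(c("A", "-", "X"), ab), ab)
#' @export
default_alphabet <- function() {
  syms <- c(AA_RESIDUES, GAP_SYMBOLS, UNKNOWN_SYMBOLS)
  codes <- seq_along(syms)
  structure(list(
    symbols = syms,
    codes = stats::setNames(codes, syms),
    n_residues = length(AA_RESIDUES),
    gap_codes = codes[match(GAP_SYMBOLS, syms)],
    unknown_codes = codes[match(UNKNOWN_SYMBOLS, syms)]
  ), class = "symbol_alphabet")
}

#' Encode and decode alignment symbols
#'
#' `encode_symbols()` maps characters to integer codes and is strict: a
#' symbol outside the alphabet is an error (file readers normalise
#' unrecognised characters to unknown before encoding, with a warning).
#' `decode_symbols()` inverts the encoding exactly.
#'
#' @param x Character vector of single-character symbols.
#' @param codes Integer vector of symbol codes.
#' @param alphabet A `symbol_alphabet`.
#' @return An integer vector (`encode_symbols`) or character vector
#'   (`decode_symbols`).
#' @export
encode_symbols <- function(x, alphabet = default_alphabet()) {
  out <- unname(alphabet$codes[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("symbols outside the alphabet: ", paste(bad, collapse = " "))
  }
  out
}

#' @rdname encode_symbols
#' @export
decode_symbols <- function(codes, alphabet = default_alphabet()) {
  if (any(codes < 1L | codes > length(alphabet$symbols))) {
    stop("codes outside the alphabet range")
  }
  alphabet$symbols[codes]
}

# TRUE for codes that are amino-acid residues (not gap, not unknown)
is_residue_code <- function(codes, alphabet = default_alphabet()) {
  codes <= alphabet$n_residues
}
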
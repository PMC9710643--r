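# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles over character data (table() +
# probability loops), sharing no code with the package internals.

ORACLE_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# NMI of two character columns: drop rows where either symbol is not a
# residue, tabulate, probabilities, explicit double loop for MI,
# min-entropy normalisation with the same flagging rules.
oracle_nmi <- function(ca, cb, eps = 0.05) {
  ok <- ca %in% ORACLE_RESIDUES & cb %in% ORACLE_RESIDUES
  a <- ca[ok]; b <- cb[ok]
  n <- length(a)
  if (n == 0) {
    return(list(nmi = NA_real_, status = "undefined_low_entropy"))
  }
  if (length(unique(a)) == 1 && length(unique(b)) == 1) {
    return(list(nmi = 1, status = "perfectly_invariant_pair"))
  }
  pj <- table(a, b) / n
  pa <- rowSums(pj); pb <- colSums(pj)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- 0
  for (i in rownames(pj)) {
    for (j in colnames(pj)) {
      p <- pj[i, j]
      if (p > 0) mi <- mi + p * log2(p / (pa[[i]] * pb[[j]]))
    }
  }
  mi <- max(mi, 0)
  den <- min(H(pa), H(pb))
  if (den < eps || mi > den * (1 + 1e-9)) {
    return(list(nmi = NA_real_, status = "undefined_low_entropy"))
  }
  list(nmi = min(mi / den, 1), status = "ok")
}

oracle_entropy <- function(ca) {
  a <- ca[ca %in% ORACLE_RESIDUES]
  if (length(a) == 0) return(NA_real_)
  p <- table(a) / length(a)
  -sum(p * log2(p))
}

# SR/mode/SRM by explicit pair enumeration over a score lookup function
# score(i, j) returning NMI or NA.
oracle_sr <- function(members, i, score) {
  tot <- 0
  for (j in setdiff(members, i)) {
    v <- score(i, j)
    if (!is.na(v)) tot <- tot + v
  }
  tot
}

oracle_mode <- function(members, score) {
  sr <- vapply(members, function(i) oracle_sr(members, i, score), 0)
  min(members[sr == max(sr)])
}

oracle_srm <- function(members, score) {
  oracle_sr(members, oracle_mode(members, score), score) /
    (length(members) - 1)
}

# score-lookup closure over an nmi_scores object
score_fun <- function(scores) {
  m <- scores$nmi
  function(i, j) m[as.character(i), as.character(j)]
}
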
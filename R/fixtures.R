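# Deterministic synthetic-alignment generator with planted groups of
# mutually interdependent columns -- the validation test bed.

#' Generate a synthetic alignment with planted interdependent columns
#'
#' Each planted group is driven by one latent categorical variable drawn
#' uniformly over `n_latent` states per sequence; every column of the
#' group renders the latent state through its own injective mapping into
#' the 20 residues (so at zero noise all within-group pairwise NMIs are
#' exactly 1 and cross-group NMI is 0 up to finite-sample bias), then each
#' cell is independently resampled uniformly with the group's
#' `noise` probability. Non-group columns are i.i.d. uniform residues.
#' Gaps are injected i.i.d. at `gap_rate` over the first `n_cols` columns,
#' after the dependence structure, so gap placement carries no signal.
#' Perfectly invariant columns (one residue) and near-invariant columns
#' (one rare second symbol in a single sequence) are appended after the
#' main block. Fully reproducible from `seed`; the caller's RNG state is
#' untouched.
#'
#' @param n_seqs Number of sequences M (>= 2).
#' @param n_cols Number of main columns N.
#' @param groups List of planted groups; each element is either an integer
#'   vector of column ids (noise 0) or `list(columns =, noise =)` with
#'   `noise` in `[0, 1)`. Group columns must be disjoint and within
#'   `1..n_cols`.
#' @param gap_rate I.i.d. per-cell gap probability in `[0, 1)`.
#' @param n_invariant Number of perfectly invariant columns appended.
#' @param n_near_invariant Number of near-invariant columns appended.
#' @param seed Integer seed.
#' @param n_latent Latent-state cardinality (< 20 so injective maps
#'   exist; default 8).
#' @return A list with `alignment` (an `msa` of `n_cols + n_invariant +
#'   n_near_invariant` columns) and `truth` (the normalised spec: `groups`
#'   with `columns`/`noise`, `invariant_cols`, `near_invariant_cols`,
#'   `seed`).
#' @examples
#' sim <- generate_planted_msa(100, 6,
#'                             groups = list(list(columns = c(1, 2), noise = 0)),
#'                             seed = 42)
#' pair_nmi(sim$alignment, 1, 2)$nmi  # exactly 1
#' @export
generate_planted_msa <- function(n_seqs, n_cols, groups = list(),
                                 gap_rate = 0, n_invariant = 0,
                                 n_near_invariant = 0, seed = 1,
                                 n_latent = 8) {
  if (n_seqs < 2L) stop("n_seqs must be at least 2")
  if (n_latent >= 20L || n_latent < 2L) {
    stop("n_latent must be in 2..19 so injective residue maps exist")
  }
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  groups <- lapply(groups, function(g) {
    if (!is.list(g)) g <- list(columns = g, noise = 0)
    g$columns <- as.integer(g$columns)
    if (is.null(g$noise)) g$noise <- 0
    if (g$noise < 0 || g$noise >= 1) stop("group noise must be in [0, 1)")
    if (any(g$columns < 1L) || any(g$columns > n_cols)) {
      stop("group columns must lie within 1..n_cols")
    }
    g
  })
  all_cols <- unlist(lapply(groups, `[[`, "columns"))
  if (anyDuplicated(all_cols)) stop("planted groups must be disjoint")

  ab <- default_alphabet()
  gap_code <- ab$gap_codes[1]
  m <- as.integer(n_seqs)

  aln <- with_seed(seed, {
    mat <- matrix(sample.int(20L, m * n_cols, replace = TRUE), m, n_cols)
    for (g in groups) {
      latent <- sample.int(n_latent, m, replace = TRUE)
      for (col in g$columns) {
        map <- sample.int(20L, n_latent)
        v <- map[latent]
        if (g$noise > 0) {
          flip <- stats::runif(m) < g$noise
          v[flip] <- sample.int(20L, sum(flip), replace = TRUE)
        }
        mat[, col] <- v
      }
    }
    if (gap_rate > 0) {
      mat[stats::runif(m * n_cols) < gap_rate] <- gap_code
    }
    extras <- NULL
    if (n_invariant > 0) {
      extras <- cbind(extras, vapply(seq_len(n_invariant), function(i) {
        rep(sample.int(20L, 1L), m)
      }, integer(m)))
    }
    if (n_near_invariant > 0) {
      extras <- cbind(extras, vapply(seq_len(n_near_invariant), function(i) {
        base <- sample.int(20L, 1L)
        v <- rep(base, m)
        rare <- sample(setdiff(seq_len(20L), base), 1L)
        v[sample.int(m, 1L)] <- rare
        v
      }, integer(m)))
    }
    new_msa(cbind(mat, extras),
            seq_labels = sprintf("seq%04d", seq_len(m)),
            alphabet = ab)
  })

  n_extra <- n_invariant + n_near_invariant
  list(
    alignment = aln,
    truth = list(
      groups = groups,
      invariant_cols = if (n_invariant > 0) {
        seq.int(n_cols + 1L, n_cols + n_invariant)
      } else integer(),
      near_invariant_cols = if (n_near_invariant > 0) {
        seq.int(n_cols + n_invariant + 1L, n_cols + n_extra)
      } else integer(),
      seed = seed
    )
  )
}
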
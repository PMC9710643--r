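# The two-phase clustering engine.
#
# Phase I extracts the strongest mutually-exclusive column pairs (order-2
# clusters) from the pairwise NMI scores, optionally restricted to
# interleaved "spread" subsets of the columns. Phase II agglomerates the
# pairs and the remaining single columns into higher-order clusters,
# best-first, where the affinity between two entities is the NMI between
# their modes (k-modes: a cluster is represented by its strongest member).
#
# Cluster arithmetic: SR(i) = sum of NMI(i, i') over the other members;
# mode = argmax SR (ties -> lowest attribute id); SRM = SR(mode) / (order-1),
# the per-pair strength of the mode, comparable across cluster orders.

.members_key <- function(members) paste(members, collapse = ";")

.score_submatrix <- function(scores, members) {
  m <- .score_matrix(scores)
  ids <- as.character(members)
  if (!all(ids %in% rownames(m))) {
    stop("scores do not cover attributes: ",
         paste(setdiff(ids, rownames(m)), collapse = ", "))
  }
  m[ids, ids, drop = FALSE]
}

#' Statistical redundancy of cluster members
#'
#' `cluster_sr()` returns, for each member `i` of a cluster, the sum of its
#' NMI with every other member (the statistical redundancy, SR).
#' Pairs with no usable score contribute 0 and are counted in the
#' `n_undefined` attribute. `cluster_mode()` returns the member with the
#' highest SR (ties broken by lowest attribute id) and `cluster_srm()` the
#' mode's SR divided by its number of member pairs (`order - 1`), the SRM.
#'
#' @param members Integer vector of at least 2 attribute ids.
#' @param scores An `nmi_scores` object (see [nmi_matrix()]) or a plain
#'   symmetric numeric matrix with attribute-id dimnames.
#' @return `cluster_sr()`: named numeric vector of SR values;
#'   `cluster_mode()`: a single attribute id; `cluster_srm()`: a number in
#'   `[0, 1]`.
#' @examples
#' m <- matrix(c(NA, .9, .5, .9, NA, .4, .5, .4, NA), 3,
#'             dimnames = list(1:3, 1:3))
#' cluster_sr(1:3, m)    # 1.4 1.3 0.9
#' cluster_mode(1:3, m)  # 1
#' cluster_srm(1:3, m)   # 0.7
#' @export
cluster_sr <- function(members, scores) {
  members <- sort(as.integer(members))
  if (length(members) < 2L) stop("a cluster needs at least 2 members")
  sub <- .score_submatrix(scores, members)
  diag(sub) <- NA_real_
  n_undef <- sum(is.na(sub[upper.tri(sub)]))
  sub[is.na(sub)] <- 0
  sr <- rowSums(sub)
  names(sr) <- members
  attr(sr, "n_undefined") <- n_undef
  sr
}

#' @rdname cluster_sr
#' @export
cluster_mode <- function(members, scores) {
  sr <- cluster_sr(members, scores)
  # members are sorted ascending, which.max takes the first maximum,
  # so ties resolve to the lowest attribute id
  as.integer(names(sr)[which.max(sr)])
}

#' @rdname cluster_sr
#' @export
cluster_srm <- function(members, scores) {
  sr <- cluster_sr(members, scores)
  unname(sr[which.max(sr)]) / (length(sr) - 1L)
}

# Build a cluster record (order >= 2) with recomputed SR/mode/SRM.
new_cluster <- function(members, scores, step, children = character()) {
  members <- sort(as.integer(members))
  sr <- cluster_sr(members, scores)
  i <- which.max(sr)
  structure(list(
    members = members,
    sr = stats::setNames(as.numeric(sr), names(sr)),
    mode = as.integer(names(sr)[i]),
    srm = unname(sr[i]) / (length(members) - 1L),
    order = length(members),
    step = as.integer(step),
    children = children,
    n_undefined = attr(sr, "n_undefined")
  ), class = "srm_cluster")
}

#' @export
print.srm_cluster <- function(x, ...) {
  cat(sprintf("cluster (%s): order %d, mode %d, srm %.4f, step %d\n",
              paste(x$members, collapse = ", "), x$order, x$mode,
              x$srm, x$step))
  invisible(x)
}

#' Interleaved column subsets for phase-I sampling
#'
#' A spread `s` partitions the scored attributes into `s` interleaved
#' subsets (every `s`-th attribute starting at offsets `1..s`); phase I
#' searches for pairs within subsets only, cutting the quadratic pair
#' search. Spread 1 is the exhaustive search.
#'
#' @param attrs Integer vector of attribute ids (in increasing order).
#' @param spread Positive integer.
#' @return A list of `spread` integer vectors partitioning `attrs`.
#' @export
spread_subsets <- function(attrs, spread) {
  spread <- as.integer(spread)
  if (spread < 1L) stop("spread must be a positive integer")
  lapply(seq_len(spread), function(r) {
    attrs[seq.int(r, length(attrs), by = spread)]
  })
}

#' Phase I: extract the strongest mutually-exclusive column pairs
#'
#' Within each spread subset, all usable pairwise NMI scores at least
#' `min_nmi` become candidates; candidates from every requested spread
#' compete in one greedy extraction that repeatedly takes the highest-NMI
#' unused pair (ties: lowest attribute ids) and marks both columns used.
#' Each extracted pair is an order-2 cluster whose SRM equals its NMI;
#' columns that pair with nobody remain singletons for phase II.
#'
#' @param scores An `nmi_scores` object.
#' @param spreads Integer vector of spreads to aggregate (e.g. `1` or
#'   `2:7`).
#' @param min_nmi Minimum NMI for a pair to be extracted.
#' @param max_pairs Optional cap on the number of pairs extracted (the
#'   greedy extraction stops after the `max_pairs` strongest pairs,
#'   leaving everything else singleton). Used by [null_check()] to match
#'   the selection intensity of a real scan on a null alignment.
#' @return A list with `pairs` (list of `srm_cluster`, steps `1..P` in
#'   extraction order) and `singletons` (integer vector).
#' @export
phase1_pairs <- function(scores, spreads = 1, min_nmi = 0.1,
                         max_pairs = Inf) {
  if (min_nmi < 0 || min_nmi > 1) stop("min_nmi must be in [0, 1]")
  attrs <- scores$attrs
  m <- .score_matrix(scores)
  cand <- list()
  for (s in unique(as.integer(spreads))) {
    for (sub in spread_subsets(attrs, s)) {
      if (length(sub) < 2L) next
      sm <- m[as.character(sub), as.character(sub), drop = FALSE]
      w <- which(upper.tri(sm) & !is.na(sm) & sm >= min_nmi, arr.ind = TRUE)
      if (nrow(w) > 0L) {
        cand[[length(cand) + 1L]] <- data.frame(
          a = sub[w[, 1L]], b = sub[w[, 2L]], nmi = sm[w])
      }
    }
  }
  singletons <- attrs
  if (length(cand) == 0L) {
    warning("no column pair reaches min_nmi = ", min_nmi)
    return(list(pairs = list(), singletons = singletons))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[c("a", "b")]), , drop = FALSE]
  cand <- cand[order(-cand$nmi, cand$a, cand$b), , drop = FALSE]
  used <- logical(max(attrs))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    if (length(pairs) >= max_pairs) break
    a <- cand$a[r]; b <- cand$b[r]
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    pairs[[length(pairs) + 1L]] <- new_cluster(
      c(a, b), scores, step = length(pairs) + 1L,
      children = paste0("a", c(a, b)))
  }
  paired <- unlist(lapply(pairs, `[[`, "members"))
  list(pairs = pairs, singletons = setdiff(attrs, paired))
}

#' Phase II: agglomerate pairs and singletons into higher-order clusters
#'
#' Best-first k-modes merging. Active entities are the phase-I pairs plus
#' the remaining single columns (a singleton's mode is itself). At each
#' step the affinity of every candidate merge -- cluster+cluster,
#' cluster+singleton or singleton+singleton -- is the NMI between the two
#' entities' current modes; the highest affinity at or above
#' `min_merge_nmi` merges (ties: lowest mode ids), the merged cluster's
#' SR/mode/SRM are recomputed over all its members, and modes are
#' re-evaluated before the next step. Merging stops when no candidate
#' reaches the threshold or would exceed `max_order`. Every intermediate
#' cluster is retained in the hierarchy with its merge-step index.
#'
#' @param pairs List of order-2 `srm_cluster`s from [phase1_pairs()].
#' @param singletons Integer vector of unpaired attribute ids.
#' @param scores An `nmi_scores` object covering all involved attributes.
#' @param min_merge_nmi Minimum mode-mode NMI for a merge.
#' @param max_order Maximum cluster order (member count).
#' @return An `srm_hierarchy`: list with `clusters` (all clusters ever
#'   created, named `c<step>`), `leaves` (attribute ids appearing in any
#'   cluster), `edges` (data.frame `child`, `parent` of node ids, leaves
#'   named `a<id>`), and `final` (ids of the clusters still active at
#'   termination).
#' @export
phase2_agglomerate <- function(pairs, singletons, scores,
                               min_merge_nmi = 0.1, max_order = 10) {
  clusters <- list()
  for (p in pairs) clusters[[paste0("c", p$step)]] <- p
  step <- length(pairs)
  # active entity bookkeeping (parallel vectors)
  ids <- c(names(clusters), paste0("a", singletons))
  modes <- c(vapply(clusters, `[[`, 0L, "mode"), as.integer(singletons))
  orders <- c(rep(2L, length(clusters)), rep(1L, length(singletons)))
  memb <- c(lapply(clusters, `[[`, "members"),
            lapply(singletons, identity))
  m <- .score_matrix(scores)
  while (length(ids) >= 2L) {
    aff <- m[as.character(modes), as.character(modes), drop = FALSE]
    aff[lower.tri(aff, diag = TRUE)] <- NA_real_
    aff[outer(orders, orders, `+`) > max_order] <- NA_real_
    aff[aff < min_merge_nmi] <- NA_real_
    if (all(is.na(aff))) break
    best <- max(aff, na.rm = TRUE)
    w <- which(aff == best, arr.ind = TRUE, useNames = FALSE)
    if (nrow(w) > 1L) {
      lo <- pmin(modes[w[, 1L]], modes[w[, 2L]])
      hi <- pmax(modes[w[, 1L]], modes[w[, 2L]])
      w <- w[order(lo, hi)[1L], , drop = FALSE]
    }
    i <- w[1L, 1L]; j <- w[1L, 2L]
    step <- step + 1L
    cl <- new_cluster(c(memb[[i]], memb[[j]]), scores, step,
                      children = ids[c(i, j)])
    cid <- paste0("c", step)
    clusters[[cid]] <- cl
    keep <- -c(i, j)
    ids <- c(ids[keep], cid)
    modes <- c(modes[keep], cl$mode)
    orders <- c(orders[keep], cl$order)
    memb <- c(memb[keep], list(cl$members))
  }
  leaves <- sort(unique(unlist(lapply(clusters, `[[`, "members"))))
  edges <- do.call(rbind, lapply(names(clusters), function(id) {
    ch <- clusters[[id]]$children
    if (length(ch) == 0L) return(NULL)
    data.frame(child = ch, parent = id)
  }))
  if (is.null(edges)) edges <- data.frame(child = character(),
                                          parent = character())
  structure(list(clusters = clusters, leaves = leaves, edges = edges,
                 final = ids[startsWith(ids, "c")]),
            class = "srm_hierarchy")
}

#' @export
print.srm_hierarchy <- function(x, ...) {
  ords <- vapply(x$clusters, `[[`, 0L, "order")
  cat(sprintf("srm_hierarchy: %d clusters over %d columns\n",
              length(x$clusters), length(x$leaves)))
  if (length(ords)) print(table(order = ords))
  invisible(x)
}

#' Ranked cluster listing
#'
#' Groups all clusters of a hierarchy by order and sorts each group by SRM
#' descending (ties: earliest merge step, then lowest mode id).
#'
#' @param h An `srm_hierarchy`.
#' @return A data.frame with columns `order`, `rank`, `srm`, `mode`,
#'   `members` (semicolon-separated attribute ids), `step`.
#' @export
rank_clusters <- function(h) {
  cl <- h$clusters
  if (length(cl) == 0L) {
    return(data.frame(order = integer(), rank = integer(), srm = numeric(),
                      mode = integer(), members = character(),
                      step = integer()))
  }
  df <- data.frame(
    order = vapply(cl, `[[`, 0L, "order"),
    srm = vapply(cl, `[[`, 0, "srm"),
    mode = vapply(cl, `[[`, 0L, "mode"),
    members = vapply(cl, function(x) .members_key(x$members), ""),
    step = vapply(cl, `[[`, 0L, "step"),
    row.names = NULL
  )
  df <- df[order(df$order, -df$srm, df$step, df$mode), , drop = FALSE]
  df$rank <- stats::ave(df$srm, df$order,
                        FUN = function(v) seq_along(v))
  rownames(df) <- NULL
  df[, c("order", "rank", "srm", "mode", "members", "step")]
}

#' Discover and rank interdependent column groups in an alignment
#'
#' The full pipeline: filter gap-heavy columns, classify and set aside
#' invariant columns, compute all pairwise NMI among variable columns, run
#' the two-phase clustering, and rank the resulting clusters by SRM within
#' each order.
#'
#' @param aln An `msa`.
#' @param spreads Phase-I spread value(s); see [spread_subsets()].
#' @param gap_cutoff Maximum gap+unknown fraction per column (default 1:
#'   keep everything).
#' @param min_nmi Phase-I pair-extraction threshold.
#' @param min_merge_nmi Phase-II merge threshold.
#' @param max_order Maximum cluster order.
#' @param epsilon_inv Near-invariance entropy threshold in bits.
#' @param max_pairs Optional phase-I pair cap; see [phase1_pairs()].
#' @return An object of class `srm_scan`: list with `hierarchy`, `ranked`
#'   (see [rank_clusters()]), `scores`, `columns` (classification report),
#'   `excluded` (gap-filtered columns), `alignment` (the filtered `msa`)
#'   and `params`.
#' @examples
#' sim <- generate_planted_msa(n_seqs = 200, n_cols = 8,
#'                             groups = list(list(columns = 1:3, noise = 0)),
#'                             seed = 1)
#' scan <- srm_scan(sim$alignment)
#' head(scan$ranked)
#' @export
srm_scan <- function(aln, spreads = 1, gap_cutoff = 1, min_nmi = 0.1,
                     min_merge_nmi = 0.1, max_order = 10,
                     epsilon_inv = 0.05, max_pairs = Inf) {
  fc <- filter_columns(aln, gap_cutoff)
  aln2 <- fc$alignment
  cols <- classify_columns(aln2, epsilon_inv)
  usable <- cols$attribute_id[cols$klass == "variable"]
  if (length(usable) < 2L) {
    stop("fewer than 2 variable columns; nothing to cluster")
  }
  scores <- nmi_matrix(aln2, attrs = usable, epsilon_inv = epsilon_inv)
  p1 <- suppressWarnings(phase1_pairs(scores, spreads, min_nmi, max_pairs))
  h <- phase2_agglomerate(p1$pairs, p1$singletons, scores,
                          min_merge_nmi, max_order)
  structure(list(
    hierarchy = h,
    ranked = rank_clusters(h),
    scores = scores,
    columns = cols,
    excluded = fc$excluded,
    alignment = aln2,
    n_phase1_pairs = length(p1$pairs),
    params = list(spreads = spreads, gap_cutoff = gap_cutoff,
                  min_nmi = min_nmi, min_merge_nmi = min_merge_nmi,
                  max_order = max_order, epsilon_inv = epsilon_inv)
  ), class = "srm_scan")
}

#' @export
print.srm_scan <- function(x, ...) {
  cat("srm_scan of", nrow(x$alignment$matrix), "sequences x",
      ncol(x$alignment$matrix), "columns\n")
  r <- x$ranked
  if (nrow(r) == 0L) {
    cat("  no clusters found\n")
    return(invisible(x))
  }
  for (o in sort(unique(r$order))) {
    sub <- r[r$order == o, ]
    cat(sprintf("  order %d: %d clusters, mean srm %.3f; top: (%s) srm %.3f\n",
                o, nrow(sub), mean(sub$srm),
                gsub(";", ", ", sub$members[1]), sub$srm[1]))
  }
  invisible(x)
}

#' Write the ranked cluster listing as CSV
#'
#' Adds a `reference_members` column (reference-renumbered positions,
#' `NA` for unmapped) when the alignment carries a reference map.
#'
#' @param scan An `srm_scan` (or a ranked data.frame plus `aln`).
#' @param path Output path.
#' @param aln Alignment used for reference renumbering; defaults to the
#'   scan's own.
#' @return `path`, invisibly.
#' @export
write_ranked_csv <- function(scan, path, aln = NULL) {
  if (inherits(scan, "srm_scan")) {
    ranked <- scan$ranked
    if (is.null(aln)) aln <- scan$alignment
  } else {
    ranked <- scan
  }
  rm <- if (!is.null(aln)) aln$reference_map else NULL
  ranked$reference_members <- vapply(ranked$members, function(ms) {
    ids <- strsplit(ms, ";", fixed = TRUE)[[1]]
    if (is.null(rm)) return(NA_character_)
    paste(rm[ids], collapse = ";")
  }, "")
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
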
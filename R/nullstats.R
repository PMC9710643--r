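# Null-model alignments and SRM distribution statistics: how far do the
# discovered clusters deviate from what identical-composition but
# dependence-free sequences would give?

# Run `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Randomized null-model alignment
#'
#' `column_shuffle` independently permutes each column's entries across
#' sequences: every column keeps its exact symbol composition and gap
#' fraction, but all inter-column dependence is destroyed -- the default
#' null model. `iid_uniform` replaces the matrix by residues drawn
#' uniformly from the 20-letter alphabet (same dimensions, no gaps), a
#' harsher composition-free null kept for sensitivity analysis.
#'
#' @param aln An `msa`.
#' @param mode `"column_shuffle"` or `"iid_uniform"`.
#' @param seed Integer seed; the same seed reproduces the same output and
#'   the caller's RNG state is left untouched.
#' @return An `msa` with the same dimensions, labels and attribute ids.
#' @export
randomize_msa <- function(aln, mode = c("column_shuffle", "iid_uniform"),
                          seed = NULL) {
  mode <- match.arg(mode)
  mat <- aln$matrix
  m <- nrow(mat)
  with_seed(seed, {
    if (mode == "column_shuffle") {
      for (j in seq_len(ncol(mat))) {
        mat[, j] <- mat[sample.int(m), j]
      }
    } else {
      mat[] <- sample.int(aln$alphabet$n_residues, length(mat),
                          replace = TRUE)
    }
  })
  out <- aln
  out$matrix <- mat
  out
}

#' SRM distribution at one cluster order
#'
#' Collects the SRM values of all clusters at a given order and summarises
#' them: mean, 95% Student-t confidence interval of the mean, and a
#' normalized histogram over `[0, 1]` (heights are probability densities,
#' so they integrate to 1).
#'
#' @param x An `srm_scan`, an `srm_hierarchy`, or a ranked data.frame from
#'   [rank_clusters()].
#' @param order Cluster order (2 = pairwise, 3 = third order, ...).
#' @param bins Number of histogram bins over `[0, 1]`.
#' @return An object of class `srm_distribution`: list with `order`,
#'   `values`, `n`, `mean`, `ci95`, `breaks`, `heights`.
#' @export
srm_distribution <- function(x, order, bins = 20) {
  ranked <- if (inherits(x, "srm_scan")) {
    x$ranked
  } else if (inherits(x, "srm_hierarchy")) {
    rank_clusters(x)
  } else {
    x
  }
  v <- ranked$srm[ranked$order == order]
  n <- length(v)
  if (n < 2L) {
    stop("need at least 2 clusters at order ", order,
         " for a confidence interval (found ", n, ")")
  }
  mu <- mean(v)
  s <- stats::sd(v)
  half <- if (s == 0) 0 else stats::qt(0.975, n - 1L) * s / sqrt(n)
  h <- graphics::hist(v, breaks = seq(0, 1, length.out = bins + 1L),
                      plot = FALSE)
  structure(list(order = order, values = v, n = n, mean = mu,
                 ci95 = c(low = mu - half, high = mu + half),
                 breaks = h$breaks, heights = h$density),
            class = "srm_distribution")
}

#' @export
print.srm_distribution <- function(x, ...) {
  cat(sprintf("order-%d SRM distribution: n = %d, mean = %.3f (95%% CI %.3f-%.3f)\n",
              x$order, x$n, x$mean, x$ci95["low"], x$ci95["high"]))
  invisible(x)
}

#' @export
plot.srm_distribution <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, max(x$heights) * 1.05),
                 xlab = "SRM", ylab = "normalized probability",
                 main = sprintf("order-%d clusters (n = %d)", x$order, x$n),
                 ...)
  graphics::rect(head(x$breaks, -1), 0, x$breaks[-1], x$heights,
                 col = "grey80")
  graphics::abline(v = x$mean, lwd = 2)
  invisible(x)
}

#' Compare a real SRM distribution with its null
#'
#' Welch's two-sample, two-sided, unequal-variance t-test of mean SRM
#' between the clusters discovered in the real alignment and those from a
#' null-model alignment. Identical degenerate samples (both zero-variance,
#' equal means) give `t = 0`, `p = 1` by convention.
#'
#' @param real,null `srm_distribution` objects (or numeric SRM vectors) at
#'   the same order.
#' @return An object of class `null_comparison`: list with `t_statistic`,
#'   `p_value`, `df`, `real`, `null`.
#' @export
compare_to_null <- function(real, null) {
  rv <- if (inherits(real, "srm_distribution")) real$values else real
  nv <- if (inherits(null, "srm_distribution")) null$values else null
  if (length(rv) < 2L || length(nv) < 2L) {
    stop("both samples need at least 2 values")
  }
  if (stats::sd(rv) == 0 && stats::sd(nv) == 0) {
    eq <- mean(rv) == mean(nv)
    res <- list(t_statistic = if (eq) 0 else sign(mean(rv) - mean(nv)) * Inf,
                p_value = if (eq) 1 else 0, df = NA_real_)
  } else {
    tt <- stats::t.test(rv, nv, var.equal = FALSE)
    res <- list(t_statistic = unname(tt$statistic),
                p_value = tt$p.value,
                df = unname(tt$parameter))
  }
  structure(c(res, list(real = real, null = null)),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("real vs null mean SRM: t = %.2f, two-sided p = %.3g\n",
              x$t_statistic, x$p_value))
  invisible(x)
}

#' Null-model check of a scanned alignment
#'
#' The deviation-from-chance experiment: scan the real alignment, then
#' scan a randomized version and test real vs null mean SRM per order.
#' The null scan is *selection-matched*: phase I runs with no NMI
#' threshold but extracts at most as many pairs as the real scan did (so
#' the null also reflects the greedy take-the-strongest selection), and
#' phase II merges freely up to `max(orders)`, leaving the unpaired
#' columns available as singletons so third- and higher-order null
#' clusters exist.
#'
#' @param aln An `msa`.
#' @param orders Integer vector of cluster orders to compare.
#' @param null_mode See [randomize_msa()].
#' @param seed Seed for the null randomization.
#' @param bins Histogram bins.
#' @param ... Passed to [srm_scan()] for the real alignment.
#' @return A data.frame with one row per order: `order`, `real_mean`,
#'   `real_lo`, `real_hi`, `null_mean`, `null_lo`, `null_hi`, `t`, `p`;
#'   the underlying comparisons are attached as the `"comparisons"`
#'   attribute.
#' @export
null_check <- function(aln, orders = c(2, 3),
                       null_mode = "column_shuffle", seed = 1,
                       bins = 20, ...) {
  real <- srm_scan(aln, ...)
  nul_aln <- randomize_msa(aln, mode = null_mode, seed = seed)
  nul <- srm_scan(nul_aln, min_nmi = 0, min_merge_nmi = 0,
                  max_order = max(orders),
                  max_pairs = max(2L, real$n_phase1_pairs))
  cmp <- lapply(orders, function(o) {
    n_real <- sum(real$ranked$order == o)
    n_null <- sum(nul$ranked$order == o)
    if (n_real < 2L || n_null < 2L) {
      warning("order ", o, ": fewer than 2 clusters on the ",
              if (n_real < 2L) "real" else "null",
              " side; no comparison possible")
      return(NULL)
    }
    compare_to_null(srm_distribution(real, o, bins),
                    srm_distribution(nul, o, bins))
  })
  pick <- function(f) {
    vapply(cmp, function(x) if (is.null(x)) NA_real_ else f(x), 0)
  }
  out <- data.frame(
    order = orders,
    real_mean = pick(function(x) x$real$mean),
    real_lo = pick(function(x) x$real$ci95[["low"]]),
    real_hi = pick(function(x) x$real$ci95[["high"]]),
    null_mean = pick(function(x) x$null$mean),
    null_lo = pick(function(x) x$null$ci95[["low"]]),
    null_hi = pick(function(x) x$null$ci95[["high"]]),
    t = pick(function(x) x$t_statistic),
    p = pick(function(x) x$p_value)
  )
  attr(out, "comparisons") <- cmp
  out
}
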
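# Small in-code fixtures shared across test files.

# alignment whose columns are given as strings ("AACC" = one column over
# 4 sequences)
aln_from_cols <- function(...) {
  cols <- lapply(list(...), function(s) strsplit(toupper(s), "")[[1]])
  new_msa(do.call(cbind, cols))
}

# random character alignment over an arbitrary symbol set
rand_chars <- function(m, n, symbols, seed) {
  set.seed(seed)
  matrix(sample(symbols, m * n, replace = TRUE), m, n)
}

# polytree / member-union structural checks on a hierarchy
expect_valid_hierarchy <- function(h) {
  for (id in names(h$clusters)) {
    cl <- h$clusters[[id]]
    expect_gte(cl$srm, 0)
    expect_lte(cl$srm, 1)
    if (length(cl$children) > 0) {
      got <- sort(unlist(lapply(cl$children, function(ch) {
        if (startsWith(ch, "a")) {
          as.integer(sub("^a", "", ch))
        } else {
          h$clusters[[ch]]$members
        }
      })))
      expect_identical(got, cl$members)
    }
  }
  if (nrow(h$edges) > 0) {
    # each node merges into at most one parent, and the underlying
    # undirected graph is a forest (|E| = |V| - #components)
    expect_false(any(duplicated(h$edges$child)))
    g <- igraph::graph_from_data_frame(h$edges, directed = TRUE)
    expect_true(igraph::is_dag(g))
    expect_true(all(igraph::degree(g, mode = "out") <= 1))
    ug <- igraph::as_undirected(g)
    expect_identical(igraph::ecount(ug),
                     igraph::vcount(ug) - igraph::count_components(ug))
  }
  invisible(h)
}
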
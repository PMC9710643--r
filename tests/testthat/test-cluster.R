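# score matrix helper for hand-built examples
score_mat <- function(ids, vals) {
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (v in vals) {
    m[as.character(v[1]), as.character(v[2])] <- v[3]
    m[as.character(v[2]), as.character(v[1])] <- v[3]
  }
  m
}

test_that("SR, mode and SRM follow the hand-computed arithmetic", {
  m <- score_mat(1:3, list(c(1, 2, .9), c(1, 3, .5), c(2, 3, .4)))
  sr <- cluster_sr(1:3, m)
  expect_equal(as.numeric(sr), c(1.4, 1.3, 0.9), tolerance = 1e-12)
  expect_identical(cluster_mode(1:3, m), 1L)
  expect_equal(cluster_srm(1:3, m), 0.7, tolerance = 1e-12)
  # pair cluster: both SR equal the NMI, mode is the lower id
  pm <- score_mat(c(4, 9), list(c(4, 9, .8)))
  expect_equal(as.numeric(cluster_sr(c(4, 9), pm)), c(.8, .8))
  expect_identical(cluster_mode(c(4, 9), pm), 4L)
  expect_equal(cluster_srm(c(4, 9), pm), .8)
})

test_that("a five-member cluster sums four pairs per attribute", {
  set.seed(8)
  ids <- c(2, 5, 7, 8, 11)
  vals <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    vals[[length(vals) + 1]] <- c(ids[i], ids[j], round(runif(1), 3))
  }
  m <- score_mat(ids, vals)
  sc <- function(i, j) m[as.character(i), as.character(j)]
  sr <- cluster_sr(ids, m)
  for (i in ids) {
    expect_identical(sum(!is.na(m[as.character(i), as.character(setdiff(ids, i))])), 4L)
    expect_equal(sr[[as.character(i)]], oracle_sr(ids, i, sc),
                 tolerance = 1e-12)
  }
  expect_equal(cluster_srm(ids, m),
               oracle_sr(ids, oracle_mode(ids, sc), sc) / 4,
               tolerance = 1e-12)
})

test_that("undefined pair scores contribute zero to SR", {
  m <- score_mat(1:3, list(c(1, 2, .9), c(1, 3, .5)))  # (2,3) unusable
  sr <- cluster_sr(1:3, m)
  expect_equal(as.numeric(sr), c(1.4, 0.9, 0.5))
  expect_identical(attr(sr, "n_undefined"), 1L)
})

test_that("mode ties break to the lowest attribute id", {
  m <- score_mat(c(3, 7, 9), list(c(3, 7, .5), c(3, 9, .5), c(7, 9, .5)))
  expect_identical(cluster_mode(c(9, 3, 7), m), 3L)
})

test_that("spread subsets interleave and partition the attributes", {
  expect_identical(spread_subsets(1:6, 2), list(c(1L, 3L, 5L), c(2L, 4L, 6L)))
  expect_identical(spread_subsets(1:6, 1), list(1:6))
  attrs <- sort(sample.int(100, 37))
  subs <- spread_subsets(attrs, 5)
  expect_identical(sort(unlist(subs)), attrs)
  expect_identical(anyDuplicated(unlist(subs)), 0L)
})

test_that("phase I extracts mutually-exclusive strongest pairs", {
  # one identical pair among independent noise
  sim <- generate_planted_msa(500, 4,
                              groups = list(list(columns = 1:2, noise = 0)),
                              seed = 3)
  sc <- nmi_matrix(sim$alignment)
  p1 <- phase1_pairs(sc, min_nmi = 0.5)
  expect_length(p1$pairs, 1)
  expect_identical(p1$pairs[[1]]$members, c(1L, 2L))
  expect_equal(p1$pairs[[1]]$srm, 1, tolerance = 1e-12)
  expect_identical(p1$singletons, 3:4)
  # three disjoint perfectly-covarying pairs all recovered
  sim3 <- generate_planted_msa(400, 9,
                               groups = list(list(columns = c(1, 2)),
                                             list(columns = c(4, 5)),
                                             list(columns = c(7, 8))),
                               seed = 4)
  p3 <- phase1_pairs(nmi_matrix(sim3$alignment), min_nmi = 0.5)
  got <- vapply(p3$pairs, function(p) paste(p$members, collapse = ","), "")
  expect_setequal(got, c("1,2", "4,5", "7,8"))
  # threshold nobody reaches on a structure-free alignment
  bg <- generate_planted_msa(500, 4, seed = 6)
  expect_warning(p0 <- phase1_pairs(nmi_matrix(bg$alignment),
                                    min_nmi = 0.9),
                 "no column pair")
  expect_length(p0$pairs, 0)
})

test_that("spread aggregation recovers pairs invisible at a single spread", {
  sim <- generate_planted_msa(400, 6,
                              groups = list(list(columns = c(1, 2))),
                              seed = 5)
  sc <- nmi_matrix(sim$alignment)
  # spread 2 puts columns 1 and 2 in different subsets
  p_s2 <- suppressWarnings(phase1_pairs(sc, spreads = 2, min_nmi = 0.5))
  expect_length(p_s2$pairs, 0)
  p_s1 <- phase1_pairs(sc, spreads = 1, min_nmi = 0.5)
  expect_identical(p_s1$pairs[[1]]$members, c(1L, 2L))
  p_agg <- phase1_pairs(sc, spreads = c(1, 2), min_nmi = 0.5)
  expect_identical(p_agg$pairs[[1]]$members, c(1L, 2L))
})

test_that("phase II absorbs the latent group before any background column", {
  hits <- 0L
  for (s in 1:50) {
    sim <- generate_planted_msa(300, 8,
                                groups = list(list(columns = 1:3,
                                                   noise = 0.1)),
                                seed = s)
    scan <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 0.3)
    r3 <- scan$ranked[scan$ranked$order == 3, ]
    if (nrow(r3) >= 1 && r3$members[1] == "1;2;3") hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})

test_that("disjoint planted groups give a forest with two components", {
  sim <- generate_planted_msa(300, 8,
                              groups = list(list(columns = 1:3),
                                            list(columns = 5:7)),
                              seed = 9)
  scan <- srm_scan(sim$alignment, min_nmi = 0.5, min_merge_nmi = 0.5)
  h <- scan$hierarchy
  expect_valid_hierarchy(h)
  g <- igraph::graph_from_data_frame(h$edges, directed = TRUE)
  expect_equal(igraph::count_components(g, mode = "weak"), 2)
})

test_that("min_merge_nmi = 1 freezes the hierarchy at phase-1 pairs", {
  sim <- generate_planted_msa(300, 8,
                              groups = list(list(columns = 1:3,
                                                 noise = 0.1)),
                              seed = 10)
  scan <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 1)
  expect_true(all(scan$ranked$order == 2))
})

test_that("phase II on empty input yields an empty hierarchy", {
  h <- phase2_agglomerate(list(), integer(),
                          score_mat(1:2, list(c(1, 2, .5))))
  expect_length(h$clusters, 0)
  expect_identical(nrow(rank_clusters(h)), 0L)
})

test_that("ranking sorts by SRM within order with step tie-breaks", {
  m <- score_mat(1:6, list(c(1, 2, .7), c(3, 4, .9), c(5, 6, .7)))
  p1 <- phase1_pairs(structure(list(nmi = m, attrs = 1:6),
                               class = "nmi_scores"),
                     min_nmi = 0.5)
  h <- phase2_agglomerate(p1$pairs, integer(), m, min_merge_nmi = 1)
  r <- rank_clusters(h)
  expect_equal(r$srm, c(.9, .7, .7))
  # the two 0.7 pairs tie; earlier step (extraction of lower ids) first
  expect_identical(r$members, c("3;4", "1;2", "5;6"))
  expect_identical(r$rank, c(1, 2, 3))
})

test_that("identical inputs produce identical hierarchies", {
  sim <- generate_planted_msa(200, 10,
                              groups = list(list(columns = c(1, 2),
                                                 noise = 0.1),
                                            list(columns = 4:6,
                                                 noise = 0.1)),
                              seed = 12)
  s1 <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 0.3)
  s2 <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 0.3)
  expect_identical(s1$ranked, s2$ranked)
  expect_identical(s1$hierarchy$edges, s2$hierarchy$edges)
})

test_that("cluster arithmetic matches the oracle on pipeline output", {
  sim <- generate_planted_msa(250, 10,
                              groups = list(list(columns = 1:4,
                                                 noise = 0.15)),
                              seed = 13)
  scan <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 0.3)
  sc <- score_fun(scan$scores)
  for (cl in scan$hierarchy$clusters) {
    expect_identical(cl$mode, oracle_mode(cl$members, sc))
    expect_equal(cl$srm, oracle_srm(cl$members, sc), tolerance = 1e-12)
    for (i in cl$members) {
      expect_equal(cl$sr[[as.character(i)]],
                   oracle_sr(cl$members, i, sc), tolerance = 1e-12)
    }
  }
})
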
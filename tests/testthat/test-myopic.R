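test_that("the two-step distance reports value and provenance correctly", {
  d0 <- myopic_distance(toys$benzene, toys$benzene, T = 10)
  expect_equal(d0$value, 0); expect_equal(d0$provenance, "exact")

  d1 <- myopic_distance(toys$benzene, toys$cyclohexane, T = 10)
  expect_equal(d1$value, 3); expect_equal(d1$provenance, "exact")
  expect_true(verify_solution(toys$benzene, toys$cyclohexane, d1$solution))

  # same pair, tight threshold: the bound certifies >= T, no exact step
  d2 <- myopic_distance(toys$benzene, toys$cyclohexane, T = 2)
  expect_equal(d2$value, 3); expect_equal(d2$provenance, "bound")
  expect_null(d2$solution)

  d3 <- myopic_distance(toys$benzene, toys$methane_carbon, T = 5)
  expect_equal(d3$value, 9); expect_equal(d3$provenance, "bound")

  # exact value meeting T exactly is reported as clamped at T
  d4 <- myopic_distance(toys$benzene, toys$cyclohexane, T = 3)
  expect_equal(d4$value, 3)
  expect_true(d4$provenance %in% c("bound", "clamped"))

  expect_error(myopic_distance(toys$ethane, toys$ethane, T = 0))
})

test_that("clamping applies when the exact distance reaches the threshold", {
  # an 8-ring vs two 4-rings: locally identical (bound 0) but four edge
  # modifications apart, so T = 4 forces the exact step and exact = T
  a <- ring_union(8, 1)
  b <- ring_union(c(4, 4), c(1, 1))
  expect_equal(atomtype_matching_bound(a, b)$value, 0)
  expect_equal(solve_exact(a, b)$objective, 4)
  d <- myopic_distance(a, b, T = 4)
  expect_equal(d$value, 4)
  expect_equal(d$provenance, "clamped")
})

test_that("provenance dichotomy and bound consistency hold on random pairs", {
  graphs <- lapply(1:30, function(s) random_molecular_graph(4 + (s %% 10),
                                                            seed = 30000 + s))
  set.seed(5)
  for (r in 1:120) {
    idx <- sample.int(length(graphs), 2L)
    g1 <- graphs[[idx[1]]]; g2 <- graphs[[idx[2]]]
    d <- myopic_distance(g1, g2, T = 10)
    if (d$provenance == "exact") expect_lt(d$value, 10)
    if (d$provenance == "clamped") expect_equal(d$value, 10)
    if (d$provenance == "bound") {
      expect_gte(d$value, 10)
      expect_equal(d$value, atomtype_matching_bound(g1, g2)$value)
    }
    expect_quarter(d$value)
  }
})

test_that("exact provenance at a low threshold persists at higher ones", {
  graphs <- lapply(1:20, function(s) random_molecular_graph(4 + (s %% 6),
                                                            seed = 31000 + s))
  set.seed(6)
  for (r in 1:40) {
    idx <- sample.int(length(graphs), 2L)
    d10 <- myopic_distance(graphs[[idx[1]]], graphs[[idx[2]]], T = 10)
    if (d10$provenance == "exact") {
      d25 <- myopic_distance(graphs[[idx[1]]], graphs[[idx[2]]], T = 25)
      expect_equal(d25$value, d10$value)
      expect_equal(d25$provenance, "exact")
    }
  }
})

test_that("degree prefilter never changes the exact/clamped regime", {
  graphs <- lapply(1:12, function(s) random_molecular_graph(4 + s, seed = 32000 + s))
  for (i in 1:11) {
    d  <- myopic_distance(graphs[[i]], graphs[[i + 1]], T = 10)
    dp <- myopic_distance(graphs[[i]], graphs[[i + 1]], T = 10,
                          use_degree_prefilter = TRUE)
    if (d$provenance != "bound") {
      expect_equal(dp$value, d$value)
      expect_equal(dp$provenance, d$provenance)
    } else {
      expect_gte(dp$value, 10)
    }
  }
})

test_that("shortest-path closure repairs a broken triangle and fixes a metric", {
  rec <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                    value = c(1, 5, 1), provenance = "exact")
  tab <- structure(list(ids = c("a", "b", "c"), records = rec, threshold = 10),
                   class = "mces_table")
  cl <- metric_closure(tab)
  expect_equal(cl$records$value[cl$records$id1 == "a" & cl$records$id2 == "c"], 2)
  expect_equal(cl$records$provenance[2], "closure")

  # a double-thresholded table is already a metric: closure is the identity
  graphs <- lapply(1:8, function(s) random_molecular_graph(4 + s, seed = 33000 + s))
  tab2 <- pairwise_distances(graphs, T = 10)
  cl2 <- metric_closure(tab2)
  expect_equal(cl2$records$value, tab2$records$value)

  # single structure: nothing to close
  tab3 <- pairwise_distances(graphs[1], T = 10)
  expect_equal(nrow(metric_closure(tab3)$records), 0L)

  tab$records <- tab$records[-2, ]
  expect_error(metric_closure(tab), "missing pairs")
})
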
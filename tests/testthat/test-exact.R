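test_that("model construction instantiates the right variables", {
  m <- build_model(toys$ethane, toys$methane_carbon)
  expect_equal(nrow(m$y), 2L)          # each ethane carbon vs the lone carbon
  expect_equal(nrow(m$cvar), 0L)       # no edge in the second graph
  expect_equal(nrow(m$nvar), 1L)       # the C-C edge
  expect_null(m$threshold4)

  m2 <- build_model(toys$ethane, toys$ethane)
  expect_equal(nrow(m2$y), 4L)
  expect_equal(nrow(m2$cvar), 2L)      # both orientations of the edge pair
  expect_equal(nrow(m2$nvar), 2L)

  water <- mol_from_edges(c("O"), list())
  m3 <- build_model(toys$ethane, water)
  expect_equal(nrow(m3$y), 0L)
  expect_equal(nrow(m3$cvar), 0L)

  m4 <- build_model(toys$benzene, toys$cyclohexane, threshold = 10)
  expect_equal(m4$threshold4, 40L)
  expect_true("8" %in% m4$con$family)

  lp <- tempfile(fileext = ".lp")
  write_lp(m4, lp)
  expect_true(any(grepl("^Minimize$", readLines(lp))))
})

test_that("exact solver reproduces oracle values on the toy fixtures", {
  for (g in toys) {
    s <- solve_exact(g, g)
    expect_equal(s$status, "optimal")
    expect_equal(s$objective, 0)
  }
  expect_equal(solve_exact(toys$benzene, toys$cyclohexane, threshold = 10)$objective, 3)
  expect_equal(solve_exact(toys$carbon_triangle, toys$propane)$objective, 1)
  expect_equal(solve_exact(toys$ethanol, toys$ethane, threshold = 10)$objective, 1)
})

test_that("solutions verify and carry consistent mappings", {
  s <- solve_exact(toys$benzene, toys$cyclohexane)
  expect_true(verify_solution(toys$benzene, toys$cyclohexane, s))
  expect_equal(nrow(s$edge_mapping), 6L)
  expect_equal(nrow(s$unmatched_edges), 0L)

  s2 <- solve_exact(toys$ethanol, toys$ethane)
  expect_true(verify_solution(toys$ethanol, toys$ethane, s2))
  expect_equal(sum(s2$unmatched_edges$graph == 1), 1L)  # the C-O edge
})

test_that("verification flags constructed violations by constraint family", {
  s <- solve_exact(toys$carbon_triangle, toys$propane)
  # one edge of g1 mapped to two edges of g2
  bad <- s
  bad$edge_mapping <- rbind(cbind(e1 = c(1L, 1L), e2 = c(1L, 2L)))
  bad$unmatched_edges <- data.frame(graph = c(1L, 1L), edge = c(2L, 3L))
  expect_match(verify_solution(toys$carbon_triangle, toys$propane, bad),
               "Eq. \\(6\\)")
  # non-injective node map
  bad2 <- s
  bad2$node_mapping <- c(1L, 1L, 2L)
  expect_match(verify_solution(toys$carbon_triangle, toys$propane, bad2),
               "Eq. \\(3\\)")
  # objective inconsistent with the mappings
  bad3 <- s
  bad3$objective <- s$objective + 1
  expect_match(verify_solution(toys$carbon_triangle, toys$propane, bad3),
               "Eq. \\(1\\)")
})

test_that("threshold constraint gives optimal / infeasible semantics", {
  s <- solve_exact(toys$benzene, toys$methane_carbon, threshold = 5)
  expect_equal(s$status, "infeasible")
  expect_gte(s$best_lower_bound, 5)

  # optimal under a threshold implies objective <= T, and removing the
  # threshold does not change the objective
  for (p in oracle_pairs(25, seed_base = 20000)) {
    st <- solve_exact(p$g1, p$g2, threshold = 10)
    su <- solve_exact(p$g1, p$g2)
    if (st$status == "optimal") {
      expect_lte(st$objective, 10)
      expect_equal(st$objective, su$objective)
    } else {
      expect_gt(su$objective, 10)
    }
  }
})

test_that("objective is symmetric in the argument order", {
  for (p in oracle_pairs(30, seed_base = 21000)) {
    expect_equal(solve_exact(p$g1, p$g2)$objective,
                 solve_exact(p$g2, p$g1)$objective)
  }
})

test_that("unweighted instances reduce to |E1| + |E2| - 2|Ec|", {
  strip <- function(g) mol_from_edges(g$atoms, lapply(
    seq_len(n_bonds(g)), function(r) c(g$edges[r, 1], g$edges[r, 2], 1)))
  for (p in oracle_pairs(25, seed_base = 22000)) {
    g1 <- strip(p$g1); g2 <- strip(p$g2)
    s <- solve_exact(g1, g2)
    expect_equal(s$objective,
                 n_bonds(g1) + n_bonds(g2) - 2L * nrow(s$edge_mapping))
    expect_equal(s$objective, brute_force_mces(g1, g2)$distance)
  }
})

test_that("the external MILP backend agrees with branch-and-bound", {
  for (p in oracle_pairs(4, seed_base = 23000)) {
    expect_equal(solve_exact(p$g1, p$g2, solver = "scipy")$objective,
                 solve_exact(p$g1, p$g2)$objective)
  }
  s <- solve_exact(toys$benzene, toys$methane_carbon, threshold = 5,
                   solver = "scipy")
  expect_equal(s$status, "infeasible")
})
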
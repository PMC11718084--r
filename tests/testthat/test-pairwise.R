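fixture3 <- function() list(toys$benzene, toys$cyclohexane, toys$methane_carbon)

test_that("pairwise tables hold all unordered pairs with oracle values", {
  tab <- pairwise_distances(fixture3(), T = 10)
  expect_s3_class(tab, "mces_table")
  expect_equal(nrow(tab$records), 3L)       # C(3, 2)
  val <- function(a, b) tab$records$value[
    (tab$records$id1 == a & tab$records$id2 == b) |
    (tab$records$id1 == b & tab$records$id2 == a)]
  # each value confirmed by the brute-force oracle
  expect_equal(brute_force_mces(toys$benzene, toys$cyclohexane)$distance, 3)
  expect_equal(brute_force_mces(toys$benzene, toys$methane_carbon)$distance, 9)
  expect_equal(brute_force_mces(toys$cyclohexane, toys$methane_carbon)$distance, 6)
  expect_equal(val("benzene", "cyclohexane"), 3)
  expect_equal(val("benzene", "methane_carbon"), 9)
  expect_equal(val("cyclohexane", "methane_carbon"), 6)

  expect_equal(nrow(pairwise_distances(list(), T = 10)$records), 0L)
  expect_error(pairwise_distances(list(toys$benzene, toys$benzene)), "unique")
})

test_that("nearest-neighbor minima and censoring come out right", {
  tab <- pairwise_distances(fixture3(), T = 10)
  nn <- nearest_neighbor_distances(tab)
  expect_equal(nn$min_distance[nn$id == "benzene"], 3)
  expect_equal(nn$min_distance[nn$id == "cyclohexane"], 3)
  expect_equal(nn$min_distance[nn$id == "methane_carbon"], 6)
  expect_false(any(nn$censored))

  one <- structure(list(ids = c("a", "b"),
                        records = data.frame(id1 = "a", id2 = "b", value = 4,
                                             provenance = "exact"),
                        threshold = 10), class = "mces_table")
  nn1 <- nearest_neighbor_distances(one)
  expect_equal(nn1$min_distance, c(4, 4))

  expect_warning(res <- nearest_neighbor_distances(tab, query_ids = "nope"),
                 "none of the query ids")
  expect_equal(nrow(res), 0L)

  tab$records <- tab$records[-1, ]
  expect_error(nearest_neighbor_distances(tab), "incomplete")
})

test_that("coverage profiles report k-th nearest background distances", {
  cov <- coverage_profile(list(toys$cyclohexane),
                          list(toys$benzene, toys$methane_carbon), T = 10)
  expect_equal(cov$distance, 3)
  cov2 <- coverage_profile(list(toys$cyclohexane),
                           list(toys$benzene, toys$methane_carbon),
                           T = 10, k = 2)
  expect_equal(cov2$distance, 6)
  # a dataset structure present in the background is at distance zero
  cov0 <- coverage_profile(list(toys$benzene),
                           list(toys$benzene, toys$ethane), T = 10)
  expect_equal(cov0$distance, 0)
  expect_error(coverage_profile(list(toys$benzene), list()), "empty")
  expect_error(coverage_profile(list(toys$benzene), list(toys$ethane), k = 5),
               "exceeds")
})

test_that("tables round-trip through CSV losslessly", {
  tab <- pairwise_distances(fixture3(), T = 10)
  f <- tempfile(fileext = ".csv")
  write_table(tab, f)
  back <- read_table(f)
  expect_equal(back$ids, tab$ids)
  expect_equal(back$records, tab$records)
  expect_equal(back$threshold, tab$threshold)

  empty <- pairwise_distances(list(), T = 10)
  write_table(empty, f)
  expect_equal(nrow(read_table(f)$records), 0L)

  writeLines(c("# ids: a,b", "id1,id2,value,provenance", "a,b,1,exact"), f)
  expect_error(read_table(f), "malformed")
  writeLines(c("# mcesdist 0", "# threshold: 10", "# ids: a,b",
               "id1,id2,value,provenance", "a,b,not-a-number,exact"), f)
  expect_error(read_table(f), "line 5")
})

test_that("worker count and resume never change the table", {
  graphs <- lapply(1:12, function(s) random_molecular_graph(4 + (s %% 6),
                                                            seed = 40000 + s))
  t1 <- pairwise_distances(graphs, T = 10, workers = 1L)
  t2 <- pairwise_distances(graphs, T = 10, workers = 2L)
  expect_identical(t1$records, t2$records)

  # resume from a prefix of the records
  partial <- t1
  partial$records <- t1$records[1:20, ]
  t3 <- pairwise_distances(graphs, T = 10, resume_from = partial)
  expect_identical(t3$records, t1$records)

  wrongT <- t1; wrongT$threshold <- 25
  expect_error(pairwise_distances(graphs, T = 10, resume_from = wrongT),
               "T = 25")
})

test_that("distance mass concentrates at or above the threshold at desk scale", {
  # structures sized like real heavy-atom counts (~20-48 atoms): unrelated
  # pairs are almost all censored at T, exactly-computed ones are the
  # exception — the truncated-histogram shape of realistic batch runs
  graphs <- lapply(1:200, function(s)
    random_molecular_graph(20L + (s %% 29L), seed = 45000 + s))
  tab <- pairwise_distances(graphs, T = 10)
  expect_equal(nrow(tab$records), choose(200, 2))
  prov <- table(factor(tab$records$provenance,
                       levels = c("bound", "clamped", "exact")))
  expect_gt(prov[["bound"]], prov[["exact"]])
  expect_true(all(tab$records$value[tab$records$provenance == "bound"] >= 10))
})

test_that("the square-matrix export mirrors the table symmetrically", {
  tab <- pairwise_distances(fixture3(), T = 10)
  D <- as_distance_matrix(tab)
  expect_equal(dim(D), c(3L, 3L))
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))
  expect_equal(D["benzene", "cyclohexane"], 3)
  f <- tempfile(fileext = ".csv")
  as_distance_matrix(tab, f)
  expect_equal(unname(as.matrix(utils::read.csv(f, row.names = 1))), unname(D))
})
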
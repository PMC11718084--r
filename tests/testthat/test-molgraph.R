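test_that("edge-list construction builds exactly the requested graph", {
  propane <- mol_from_edges(c("C", "C", "C"), list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(n_atoms(propane), 3L)
  expect_equal(n_bonds(propane), 2L)
  expect_equal(weighted_degree(propane), c(1, 2, 1))

  lone <- mol_from_edges("C", list())
  expect_equal(n_bonds(lone), 0L)
  expect_equal(weighted_degree(lone, 1), 0)

  triangle <- mol_from_edges(c("C", "C", "C"),
                             list(c(1, 2, 1), c(2, 3, 1), c(1, 3, 1)))
  expect_equal(total_bond_weight(triangle), 3)
})

test_that("construction rejects malformed input", {
  expect_error(mol_from_edges(c("C", "C"), list(c(1, 1, 1))), "self-loop")
  expect_error(mol_from_edges(c("C", "C"), list(c(1, 2, 1), c(2, 1, 1))),
               "parallel")
  expect_error(mol_from_edges(c("C", "C"), list(c(1, 3, 1))), "out of range")
  expect_error(mol_from_edges(c("C", "C"), list(c(1, 2, 1.2))), "weight")
  expect_error(mol_from_edges(c("C", "C"), list(c(1, 2, 3)),
                              allow_triple = FALSE), "weight")
  expect_error(mol_from_edges(character(0), list()), "at least one atom")
  expect_error(weighted_degree(toys$ethane, 5), "unknown node")
})

test_that("weighted degree and total bond weight match hand values", {
  expect_equal(weighted_degree(toys$benzene), rep(3, 6))
  expect_equal(weighted_degree(toys$propane, 2), 2)
  expect_equal(total_bond_weight(toys$benzene), 9)
  expect_equal(total_bond_weight(toys$ethane), 1)
})

test_that("handshake identity holds on generated and parsed graphs", {
  for (s in 1:25) {
    g <- random_molecular_graph(3 + (s %% 12), seed = 300 + s)
    expect_equal(sum(weighted_degree(g)), 2 * total_bond_weight(g))
  }
})

test_that("SMILES parsing produces the expected heavy-atom graphs", {
  g <- mol_from_smiles("CC")
  expect_equal(g$atoms, c("C", "C"))
  expect_equal(total_bond_weight(g), 1)

  benzene <- mol_from_smiles("c1ccccc1")
  expect_equal(n_bonds(benzene), 6L)
  expect_equal(weighted_degree(benzene), rep(3, 6))

  # kekulized input is re-perceived as aromatic
  kek <- mol_from_smiles("C1=CC=CC=C1")
  expect_equal(sort(weighted_degree(kek)), sort(weighted_degree(benzene)))
  expect_equal(total_bond_weight(kek), 9)

  ethanol <- mol_from_smiles("CCO")
  expect_setequal(ethanol$atoms, c("C", "C", "O"))
  expect_equal(total_bond_weight(ethanol), 2)

  # multi-fragment SMILES stay one disconnected graph
  two <- mol_from_smiles("CC.O")
  expect_equal(n_atoms(two), 3L)
  expect_equal(n_bonds(two), 1L)

  # triple bonds: weight 3 by default, rejectable by configuration
  yne <- mol_from_smiles("C#C")
  expect_equal(total_bond_weight(yne), 3)
  expect_error(mol_from_smiles("C#C", allow_triple = FALSE), "weight")

  expect_error(mol_from_smiles("not-a-smiles("), "cannot parse")
  expect_warning(g0 <- mol_from_smiles("[H][H]"), "no heavy atoms")
  expect_equal(n_atoms(g0), 0L)
})

test_that("SMILES parsing is deterministic in atom/degree profile", {
  a <- mol_from_smiles("CC(=O)Oc1ccccc1C(=O)O")
  b <- mol_from_smiles("CC(=O)Oc1ccccc1C(=O)O")
  prof <- function(g) sort(paste(g$atoms, weighted_degree(g)))
  expect_identical(prof(a), prof(b))
})

test_that("SMILES list files and JSON fixtures round-trip", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("# header comment", "CCO ethanol", "", "CC ethane"), smi)
  gs <- read_smiles_file(smi)
  expect_length(gs, 2L)
  expect_equal(gs[[1]]$id, "ethanol")

  js <- tempfile(fileext = ".json")
  mol_to_json(toys$benzene, js)
  back <- mol_from_json(js)
  expect_equal(back$atoms, toys$benzene$atoms)
  expect_equal(back$edges, toys$benzene$edges)
  expect_error(read_smiles_file("/nonexistent/file.smi"), "no such file")
})
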
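# Shared fixtures and generators for the test suite. Everything is built
# in code; graphs passed to the brute-force oracle are kept within its
# edge cap by construction.

toys <- toy_library()

# deterministic list of random graph pairs small enough for the oracle
oracle_pairs <- function(n_pairs, seed_base, n_nodes = 4:7, edge_cap = 7) {
  pairs <- vector("list", n_pairs)
  i <- 0L; s <- 0L
  while (i < n_pairs) {
    s <- s + 1L
    g1 <- random_molecular_graph(n_nodes[1 + (s %% length(n_nodes))],
                                 seed = seed_base + 2L * s)
    g2 <- random_molecular_graph(n_nodes[1 + ((s + 3L) %% length(n_nodes))],
                                 seed = seed_base + 2L * s + 1L)
    if (min(n_bonds(g1), n_bonds(g2)) > edge_cap) next
    i <- i + 1L
    pairs[[i]] <- list(g1 = g1, g2 = g2)
  }
  pairs
}

# disjoint union of rings with per-ring bond weight and a repeating atom
# pattern; one big ring versus several small ones is the classic case of
# locally identical but globally different structures (weak bounds)
ring_union <- function(sizes, weights, pattern = "C") {
  atoms <- character(0); bonds <- list(); off <- 0L
  for (s in seq_along(sizes)) {
    k <- sizes[s]
    atoms <- c(atoms, rep_len(pattern, k))
    bonds <- c(bonds, lapply(seq_len(k), function(i)
      c(off + i, off + (i %% k) + 1L, weights[s])))
    off <- off + k
  }
  mol_from_edges(atoms, bonds)
}

# random triple from a shared ring-family context: one big ring, a
# partition of the same atoms into smaller rings, and a weight-perturbed
# copy of the partition. Rings are the regime where the matching bound is
# blind (every atom looks locally alike) while the true distance grows
# with the number of components — the stress case for thresholding.
ring_soup_triple <- function(seed) {
  set.seed(seed)
  n <- c(16L, 20L, 24L)[sample.int(3L, 1L)]
  pattern <- if (stats::runif(1) < 0.5) "C" else c("C", "C", "N")
  w0 <- c(1, 1.5, 2)[sample.int(3L, 1L)]
  sizes <- integer(0); left <- n
  while (left >= 4L) {
    k <- (4:min(8L, left))[sample.int(min(8L, left) - 3L, 1L)]
    if ((left - k) %in% c(1L, 2L, 3L)) k <- left
    sizes <- c(sizes, min(k, left)); left <- left - min(k, left)
  }
  w_y <- rep(w0, length(sizes))
  w_y[sample.int(length(sizes), 1L)] <-
    c(1, 1.5, 2)[c(1, 1.5, 2) != w0][sample.int(2L, 1L)]
  list(x = ring_union(n, w0, pattern),
       y = ring_union(sizes, w_y, pattern),
       z = ring_union(sizes, rep(w0, length(sizes)), pattern))
}

expect_quarter <- function(x) expect_equal(x, round(x * 4) / 4)
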
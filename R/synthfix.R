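# Synthetic molecular graphs, controlled perturbations, canonical toy
# fixtures, and the exhaustive brute-force MCES oracle that anchors all
# correctness tests. The oracle is deliberately pure R and shares no code
# with the branch-and-bound solver in src/.

# Run expr under a private RNG stream; never touches caller's .Random.seed.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Canonical toy-molecule fixtures
#'
#' Small frozen structures (explicit edge lists, no SMILES parsing) used
#' throughout the package's examples and tests: `methane_carbon`, `ethane`,
#' `propane`, `carbon_triangle`, `benzene`, `cyclohexane`, `ethanol`.
#'
#' @param name optional fixture name; if `NULL` the full named list.
#' @return a `molgraph` or a named list of them.
#' @examples
#' toy_library("benzene")
#' @export
toy_library <- function(name = NULL) {
  lib <- list(
    methane_carbon  = mol_from_edges("C", list(), id = "methane_carbon"),
    ethane          = mol_from_edges(c("C", "C"), list(c(1, 2, 1)), id = "ethane"),
    propane         = mol_from_edges(c("C", "C", "C"),
                                     list(c(1, 2, 1), c(2, 3, 1)), id = "propane"),
    carbon_triangle = mol_from_edges(c("C", "C", "C"),
                                     list(c(1, 2, 1), c(2, 3, 1), c(1, 3, 1)),
                                     id = "carbon_triangle"),
    benzene         = mol_from_edges(rep("C", 6),
                                     lapply(1:6, function(i) c(i, i %% 6 + 1, 1.5)),
                                     id = "benzene"),
    cyclohexane     = mol_from_edges(rep("C", 6),
                                     lapply(1:6, function(i) c(i, i %% 6 + 1, 1)),
                                     id = "cyclohexane"),
    ethanol         = mol_from_edges(c("C", "C", "O"),
                                     list(c(1, 2, 1), c(2, 3, 1)), id = "ethanol")
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stop("unknown toy fixture: ", name, call. = FALSE)
  lib[[name]]
}

.DEFAULT_ELEMENTS <- c(C = 0.72, N = 0.10, O = 0.12, S = 0.03, P = 0.01,
                       Cl = 0.02)

#' Generate a random molecular-like graph
#'
#' Stands in for sampled biomolecular structures in tests: node-labeled,
#' edge-weighted simple graphs with capped degree, a carbon-dominated
#' element distribution, and aromatic (1.5) weights only on cycle edges so
#' that fixtures stay chemically plausible. Deterministic for fixed
#' arguments; the caller's RNG state is left untouched.
#'
#' @param n_nodes number of heavy atoms (>= 1).
#' @param seed integer seed; all randomness flows through it.
#' @param element_weights named sampling weights for element symbols.
#' @param max_degree cap on the (unweighted) node degree.
#' @param connected if `TRUE` (default) the graph is connected.
#' @param extra_edge_frac expected number of cycle-closing edges as a
#'   fraction of `n_nodes`.
#' @param free_aromatic if `TRUE`, aromatic weights may appear on any edge
#'   (adversarial mode for property tests).
#' @return a `molgraph` with id `"synth<seed>_<n>"`.
#' @export
random_molecular_graph <- function(n_nodes, seed,
                                   element_weights = .DEFAULT_ELEMENTS,
                                   max_degree = 4, connected = TRUE,
                                   extra_edge_frac = 0.15,
                                   free_aromatic = FALSE) {
  stopifnot(n_nodes >= 1, max_degree >= 1)
  .with_seed(seed, {
    atoms <- sample(names(element_weights), n_nodes, replace = TRUE,
                    prob = element_weights)
    deg <- integer(n_nodes)
    eu <- ev <- integer(0)
    has_edge <- function(a, b) any(eu == pmin(a, b) & ev == pmax(a, b))
    add_edge <- function(a, b) {
      eu <<- c(eu, pmin(a, b)); ev <<- c(ev, pmax(a, b))
      deg[c(a, b)] <<- deg[c(a, b)] + 1L
    }
    if (n_nodes > 1L) {
      for (i in 2:n_nodes) {
        cand <- which(deg[seq_len(i - 1L)] < max_degree)
        if (!length(cand)) {
          if (connected)
            stop("degree constraints make a connected graph infeasible",
                 call. = FALSE)
          next
        }
        if (!connected && stats::runif(1) < 0.1) next  # leave a fragment
        add_edge(cand[sample.int(length(cand), 1L)], i)
      }
      n_extra <- stats::rpois(1, extra_edge_frac * n_nodes)
      tries <- 0L
      while (n_extra > 0L && tries < 50L * n_nodes) {
        tries <- tries + 1L
        ab <- sample.int(n_nodes, 2L)
        if (deg[ab[1]] < max_degree && deg[ab[2]] < max_degree &&
            !has_edge(ab[1], ab[2])) {
          add_edge(ab[1], ab[2])
          n_extra <- n_extra - 1L
        }
      }
    }
    m <- length(eu)
    if (m == 0L)
      return(mol_from_edges(atoms, list(),
                            id = sprintf("synth%d_%d", seed, n_nodes)))
    on_cycle <- if (free_aromatic) rep(TRUE, m) else {
      ig <- igraph::make_graph(rbind(eu, ev), n = n_nodes, directed = FALSE)
      br <- igraph::bridges(ig)
      !(seq_len(m) %in% as.integer(br))
    }
    w <- numeric(m)
    w[!on_cycle] <- sample(c(1, 2), sum(!on_cycle), replace = TRUE,
                           prob = c(0.85, 0.15))
    w[on_cycle] <- sample(c(1, 1.5, 2), sum(on_cycle), replace = TRUE,
                          prob = c(0.5, 0.35, 0.15))
    mol_from_edges(atoms, Map(c, eu, ev, w),
                   id = sprintf("synth%d_%d", seed, n_nodes))
  })
}

#' Randomly perturb a molecular graph
#'
#' Applies `k_ops` random edits (edge deletion, bond-weight change, edge
#' insertion) and records their total weight cost `C`: the exact weighted
#' MCES distance between original and perturbed graph is at most `C`, an
#' upper-bound fixture for oracle tests.
#'
#' @param g a `molgraph`.
#' @param seed integer seed.
#' @param k_ops number of edits (>= 0).
#' @param max_degree degree cap respected by insertions.
#' @return `list(graph, record)` where `record` has one row per edit
#'   (`op`, `cost`), an attribute `total_cost`, and `short = TRUE` when no
#'   legal edit remained before `k_ops` were applied.
#' @export
perturb <- function(g, seed, k_ops, max_degree = 4) {
  .check_molgraph(g)
  stopifnot(k_ops >= 0)
  .with_seed(seed, {
    atoms <- g$atoms
    ed <- g$edges   # u, v, w4
    n <- length(atoms)
    ops <- character(0); costs4 <- integer(0)
    short <- FALSE
    for (step in seq_len(k_ops)) {
      choices <- c(
        if (nrow(ed) > 0L) c("delete", "reweight"),
        if (n >= 2L && nrow(ed) < n * (n - 1) / 2) "insert")
      done <- FALSE
      for (op in sample(choices)) {
        if (op == "delete") {
          r <- sample.int(nrow(ed), 1L)
          costs4 <- c(costs4, ed[r, 3]); ops <- c(ops, "delete")
          ed <- ed[-r, , drop = FALSE]
          done <- TRUE; break
        } else if (op == "reweight") {
          r <- sample.int(nrow(ed), 1L)
          alt <- setdiff(.ALLOWED_W4, ed[r, 3])
          w_new <- sample(alt, 1L)
          costs4 <- c(costs4, abs(w_new - ed[r, 3])); ops <- c(ops, "reweight")
          ed[r, 3] <- w_new
          done <- TRUE; break
        } else {
          deg <- integer(n)
          for (r in seq_len(nrow(ed))) {
            deg[ed[r, 1]] <- deg[ed[r, 1]] + 1L
            deg[ed[r, 2]] <- deg[ed[r, 2]] + 1L
          }
          free <- which(deg < max_degree)
          pairs <- NULL
          if (length(free) >= 2L) {
            cmb <- utils::combn(free, 2L)
            keep <- !apply(cmb, 2L, function(p)
              any(ed[, 1] == p[1] & ed[, 2] == p[2]))
            if (any(keep)) pairs <- cmb[, keep, drop = FALSE]
          }
          if (is.null(pairs)) next
          p <- pairs[, sample.int(ncol(pairs), 1L)]
          w_new <- sample(.ALLOWED_W4, 1L, prob = c(0.7, 0.1, 0.2))
          ed <- rbind(ed, c(p[1], p[2], w_new))
          costs4 <- c(costs4, w_new); ops <- c(ops, "insert")
          done <- TRUE; break
        }
      }
      if (!done) { short <- TRUE; break }
    }
    o <- order(ed[, 1], ed[, 2])
    g2 <- mol_from_edges(atoms,
                         lapply(o, function(r) c(ed[r, 1], ed[r, 2], .q(ed[r, 3]))),
                         id = paste0(if (is.null(g$id)) "g" else g$id, "_pert"))
    record <- data.frame(op = ops, cost = .q(costs4))
    attr(record, "total_cost") <- .q(sum(costs4))
    attr(record, "short") <- short
    list(graph = g2, record = record)
  })
}

#' Brute-force weighted MCES distance (test oracle)
#'
#' Exhaustive search over injective, type-consistent node mappings with
#' branch-and-bound on the accumulated cost only. Guaranteed optimal and
#' fully independent of the branch-and-bound / ILP machinery; intended for
#' tiny graphs in tests.
#'
#' @param g1,g2 `molgraph` objects.
#' @param edge_cap refuse instances where both graphs exceed this many
#'   edges (default 7).
#' @return `list(distance, node_mapping)` where `node_mapping[i]` is the
#'   image in `g2` of node `i` of `g1` (`NA` = unmapped) and `distance` is
#'   the exact weighted MCES distance.
#' @export
brute_force_mces <- function(g1, g2, edge_cap = 7) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  if (min(nrow(g1$edges), nrow(g2$edges)) > edge_cap)
    stop("instance too large for the brute-force oracle (edge cap ",
         edge_cap, ")", call. = FALSE)
  n1 <- length(g1$atoms); n2 <- length(g2$atoms)
  W1 <- .adj4(g1); W2 <- .adj4(g2)
  tot2 <- sum(g2$edges[, 3])
  env <- new.env(parent = emptyenv())
  env$best <- sum(g1$edges[, 3]) + tot2   # all-unmapped solution
  env$best_map <- rep(NA_integer_, n1)
  used <- logical(n2)
  map <- rep(NA_integer_, n1)

  # cost contribution of deciding node i given decisions for 1..i-1;
  # rem2 tracks g2 edge weight not yet compared against g1.
  recurse <- function(i, cost, rem2) {
    if (cost >= env$best) return(invisible())
    if (i > n1) {
      total <- cost + rem2
      if (total < env$best) {
        env$best <- total
        env$best_map <- map
      }
      return(invisible())
    }
    for (k in seq_len(n2)) {
      if (used[k] || g2$atoms[k] != g1$atoms[i]) next
      add <- 0L; covered <- 0L
      for (j in seq_len(i - 1L)) {
        w1 <- W1[i, j]
        l <- map[j]
        if (is.na(l)) {
          if (w1 > 0L) add <- add + w1
        } else {
          w2 <- W2[k, l]
          if (w1 > 0L && w2 > 0L) {
            add <- add + abs(w1 - w2); covered <- covered + w2
          } else if (w1 > 0L) add <- add + w1
          else if (w2 > 0L) { add <- add + w2; covered <- covered + w2 }
        }
      }
      map[i] <<- k; used[k] <<- TRUE
      recurse(i + 1L, cost + add, rem2 - covered)
      map[i] <<- NA_integer_; used[k] <<- FALSE
    }
    # leave node i unmapped: its edges to earlier nodes become uncommon
    add <- sum(W1[i, seq_len(i - 1L)])
    map[i] <<- NA_integer_
    recurse(i + 1L, cost + add, rem2)
    invisible()
  }
  recurse(1L, 0L, tot2)
  list(distance = .q(env$best), node_mapping = env$best_map)
}
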
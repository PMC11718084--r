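# Provably-correct lower bounds on the weighted MCES distance. Both are
# node-matching relaxations: every edge of either graph is incident to two
# nodes, so summing per-node discrepancies counts each edge twice — hence
# the final division by two. All arithmetic is integer quarter-units.

# shared integer atom-type codes for a pair of graphs (safe for empty graphs)
.split_codes <- function(g1, g2) {
  n1 <- length(g1$atoms)
  codes <- as.integer(factor(c(g1$atoms, g2$atoms)))
  list(a1 = codes[seq_len(n1)],
       a2 = if (length(codes) > n1) codes[(n1 + 1L):length(codes)]
            else integer(0))
}

.new_bound <- function(value4, kind) {
  structure(list(value = .q(value4), kind = kind), class = "mces_bound")
}

#' @export
print.mces_bound <- function(x, ...) {
  cat(sprintf("<mces lower bound (%s): %g>\n", x$kind, x$value))
  invisible(x)
}

#' Weighted-degree lower bound
#'
#' Sorts both node sets by weighted degree (descending), pairs them
#' positionally, sums absolute degree differences plus the degrees of
#' unpaired leftover nodes, and halves. Linear-time after sorting; never
#' exceeds the exact weighted MCES distance.
#'
#' @param g1,g2 `molgraph` objects.
#' @return an `mces_bound` with `kind = "degree"`.
#' @examples
#' toys <- toy_library()
#' degree_bound(toys$propane, toys$ethane)$value  # 1
#' @export
degree_bound <- function(g1, g2) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  d1 <- sort(.wdeg4(g1), decreasing = TRUE)
  d2 <- sort(.wdeg4(g2), decreasing = TRUE)
  n <- min(length(d1), length(d2))
  tot <- sum(abs(d1[seq_len(n)] - d2[seq_len(n)]))
  if (length(d1) > n) tot <- tot + sum(d1[-seq_len(n)])
  if (length(d2) > n) tot <- tot + sum(d2[-seq_len(n)])
  # weights are half-integers so tot is even in quarter units
  .new_bound(tot %/% 2L, "degree")
}

# incident edges of node u: matrix (w4, opposite-atom index)
.incident <- function(g, u) {
  e <- g$edges
  sel <- e[, 1] == u | e[, 2] == u
  opp <- ifelse(e[sel, 1] == u, e[sel, 2], e[sel, 1])
  cbind(w4 = e[sel, 3], opp = opp)
}

# Minimum cost of aligning the one-hop neighborhoods of u (in g1) and v
# (in g2), in quarter units: an incident edge of u may pair with one of v
# only if the opposite endpoints share an atom type (cost |b1 - b2|);
# unpaired incident edges cost their full weight. Solved exactly as a
# padded linear assignment problem.
.nbr_cost4 <- function(g1, u, g2, v) {
  iu <- .incident(g1, u); iv <- .incident(g2, v)
  d1 <- nrow(iu); d2 <- nrow(iv)
  if (d1 == 0L && d2 == 0L) return(0L)
  if (d1 == 0L) return(sum(iv[, 1]))
  if (d2 == 0L) return(sum(iu[, 1]))
  n <- d1 + d2
  M <- matrix(0L, n, n)
  for (a in seq_len(d1)) for (b in seq_len(d2)) {
    M[a, b] <- if (g1$atoms[iu[a, 2]] == g2$atoms[iv[b, 2]])
      abs(iu[a, 1] - iv[b, 1]) else iu[a, 1] + iv[b, 1]
  }
  # dummy columns absorb unpaired u-edges, dummy rows unpaired v-edges
  for (a in seq_len(d1)) M[a, (d2 + 1L):n] <- iu[a, 1]
  for (b in seq_len(d2)) M[(d1 + 1L):n, b] <- iv[b, 1]
  sol <- clue::solve_LSAP(M)
  as.integer(sum(M[cbind(seq_len(n), sol)]))
}

#' Local neighborhood alignment cost between two atoms
#'
#' The minimum, over injective pairings of the incident edges of `u` and
#' `v` that respect the opposite endpoint's atom type, of the summed bond
#' weight differences plus the weights of unpaired incident edges. This is
#' the edge weight used in the bipartite graphs of
#' [atomtype_matching_bound()].
#'
#' @param g1,g2 `molgraph` objects.
#' @param u,v node indices with equal atom type.
#' @return non-negative multiple of 0.5.
#' @export
neighborhood_cost <- function(g1, u, g2, v) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  if (g1$atoms[u] != g2$atoms[v])
    stop("neighborhood_cost requires equal atom types (",
         g1$atoms[u], " vs ", g2$atoms[v], ")", call. = FALSE)
  .q(.nbr_cost4(g1, u, g2, v))
}

.matching_bound4 <- function(g1, g2) {
  elems <- union(unique(g1$atoms), unique(g2$atoms))
  wd1 <- .wdeg4(g1); wd2 <- .wdeg4(g2)
  n1 <- length(g1$atoms)
  codes <- .split_codes(g1, g2)
  NC <- .nbr_costs_cpp(codes$a1, codes$a2, .adj4(g1), .adj4(g2))
  tot <- 0L
  for (el in elems) {
    A <- which(g1$atoms == el); B <- which(g2$atoms == el)
    s <- max(length(A), length(B))
    M <- matrix(0L, s, s)
    if (length(A) && length(B))
      M[seq_along(A), seq_along(B)] <- NC[A, B, drop = FALSE]
    # padding nodes: a real node matched to padding contributes its full
    # weighted degree (all incident edges unmatched), mirroring the
    # leftover-node rule of the degree bound; padding-padding costs 0
    if (length(B) < s)
      for (a in seq_along(A)) M[a, (length(B) + 1L):s] <- wd1[A[a]]
    if (length(A) < s)
      for (b in seq_along(B)) M[(length(A) + 1L):s, b] <- wd2[B[b]]
    if (s > 0L) {
      sol <- clue::solve_LSAP(M)
      tot <- tot + as.integer(sum(M[cbind(seq_len(s), sol)]))
    }
  }
  tot %/% 2L
}

#' Atom-type bipartite-matching lower bound
#'
#' The stronger of the two bounds: for each element, a bipartite graph is
#' built between the atoms of that type in the two structures (padded to
#' equal size), edge costs are exact one-hop neighborhood alignment costs
#' ([neighborhood_cost()]; padding costs the real atom's weighted degree),
#' and a minimum-weight perfect matching (Hungarian algorithm) is solved
#' per element. The summed matching weights, halved, never exceed the
#' exact weighted MCES distance and never fall below [degree_bound()].
#'
#' @param g1,g2 `molgraph` objects.
#' @return an `mces_bound` with `kind = "atomtype_matching"`.
#' @examples
#' toys <- toy_library()
#' atomtype_matching_bound(toys$ethanol, toys$ethane)$value  # 1
#' @export
atomtype_matching_bound <- function(g1, g2) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  .new_bound(.matching_bound4(g1, g2), "atomtype_matching")
}
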
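# The two-step myopic MCES distance. Bounds are computed first; only when
# they cannot certify dissimilarity (bound < T) is the exact solver run,
# with T as its threshold constraint. Double thresholding — reporting the
# bound only when it is >= T, and clamping exact values at T — is what
# makes the combined distance a metric: every exactly-computed value is
# <= T and every bound-derived value is >= T, so the two regimes can never
# conspire to break the triangle inequality.

#' Myopic MCES distance between two molecular graphs
#'
#' @param g1,g2 `molgraph` objects.
#' @param T distance threshold (> 0, default 10): exact distances are
#'   clamped at `T`, and pairs whose lower bound reaches `T` are reported
#'   by that bound without exact computation.
#' @param solver backend for [solve_exact()].
#' @param time_limit optional per-instance wall-clock limit (seconds) for
#'   the exact step. When it is hit the result is flagged `approximate`
#'   and reported as `min(best lower bound, T)` with provenance `"bound"`;
#'   such values keep the lower-bound reading but are excluded from the
#'   metric guarantee.
#' @param use_degree_prefilter also try the cheaper degree bound before
#'   the matching bound (default `FALSE`; the matching bound dominates it,
#'   so this is purely a speed knob).
#' @return an `mces_distance`: `value`, `provenance` (`"exact"` — ILP ran,
#'   value < T; `"clamped"` — exact value was >= T or the threshold made
#'   the instance infeasible, value = T; `"bound"` — lower bound >= T,
#'   value is the matching bound), `threshold`, `approximate`, and
#'   `solution` (the `mces_solution` when the exact step ran to
#'   optimality).
#' @examples
#' toys <- toy_library()
#' myopic_distance(toys$benzene, toys$cyclohexane, T = 10)$value   # 3, exact
#' myopic_distance(toys$benzene, toys$cyclohexane, T = 2)$value    # 3, bound
#' @export
myopic_distance <- function(g1, g2, T = 10, solver = c("bb", "scipy"),
                            time_limit = NULL, use_degree_prefilter = FALSE) {
  solver <- match.arg(solver)
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  stopifnot(T > 0)
  T4 <- .to_q(T)

  if (use_degree_prefilter) {
    # the cheap bound can certify dissimilarity without any matching; it is
    # itself a pseudometric below the matching bound, so mixing is safe
    db4 <- .to_q(degree_bound(g1, g2)$value)
    if (db4 >= T4) return(.new_distance(db4, "bound", T, NULL, FALSE))
  }
  bound4 <- .matching_bound4(g1, g2)
  if (bound4 >= T4)
    return(.new_distance(bound4, "bound", T, NULL, FALSE))

  sol <- solve_exact(g1, g2, threshold = T, time_limit = time_limit,
                     solver = solver)
  if (sol$status == "optimal") {
    obj4 <- .to_q(sol$objective)
    if (obj4 < T4) return(.new_distance(obj4, "exact", T, sol, FALSE))
    return(.new_distance(T4, "clamped", T, sol, FALSE))
  }
  if (sol$status == "infeasible")
    return(.new_distance(T4, "clamped", T, NULL, FALSE))
  # time limit: fall back to the certified lower bound, clamped at T
  .new_distance(min(.to_q(sol$best_lower_bound), T4), "bound", T, NULL, TRUE)
}

.new_distance <- function(value4, provenance, T, solution, approximate) {
  structure(list(value = .q(value4), provenance = provenance, threshold = T,
                 solution = solution, approximate = approximate),
            class = "mces_distance")
}

#' @export
print.mces_distance <- function(x, ...) {
  cat(sprintf("<myopic MCES distance: %g (%s%s, T = %g)>\n", x$value,
              x$provenance, if (x$approximate) ", approximate" else "",
              x$threshold))
  invisible(x)
}

#' Enforce the triangle inequality on a distance table by shortest paths
#'
#' All-pairs shortest-path (Floyd-Warshall) closure of a complete pairwise
#' table. For double-thresholded myopic distances this is the identity —
#' they already form a metric — but it is the documented alternative when
#' raw exact distances above the threshold are kept.
#'
#' @param table an `mces_table` (see [pairwise_distances()]), complete over
#'   its structure set.
#' @return the table with values replaced by their shortest-path closure;
#'   no entry increases, and provenance is set to `"closure"` on every
#'   record whose value changed.
#' @export
metric_closure <- function(table) {
  stopifnot(inherits(table, "mces_table"))
  ids <- table$ids
  n <- length(ids)
  miss <- .missing_pairs(table)
  if (nrow(miss))
    stop("table is incomplete; missing pairs: ",
         paste(paste(miss$id1, miss$id2, sep = "--"), collapse = ", "),
         call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  rec <- table$records
  D[cbind(match(rec$id1, ids), match(rec$id2, ids))] <- rec$value
  D[cbind(match(rec$id2, ids), match(rec$id1, ids))] <- rec$value
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, via)
  }
  new_val <- D[cbind(match(rec$id1, ids), match(rec$id2, ids))]
  changed <- new_val < rec$value
  rec$provenance[changed] <- "closure"
  rec$value <- new_val
  table$records <- rec
  table
}
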
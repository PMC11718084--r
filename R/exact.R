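# Exact weighted MCES distance. The optimization is stated as an integer
# linear program over node-mapping indicators y_ik, orientation-resolved
# edge-mapping indicators c (edge of G1 onto edge of G2) and unmapped-edge
# indicators n, with the distance threshold as an extra linear constraint.
# `build_model()` materializes that program (and can export it in LP
# format); `solve_exact()` solves the same optimization either with the
# package's own branch-and-bound (default, compiled) or by handing the
# explicit program to an external MILP backend (scipy/HiGHS via python).

#' Build the integer-program model for a weighted MCES instance
#'
#' Variables: `y[i,k]` for atom-type-compatible node pairs; `c` for each
#' compatible orientation of an edge pair (edge `ij` of `g1` onto edge
#' `kl` of `g2`, endpoint-wise type compatibility; both orientations are
#' instantiated when both are compatible) with cost `|b(ij) - b(kl)|`;
#' `n` for every edge of either graph with cost `b(e)`. Constraint
#' families (reported by [verify_solution()] by the same numbers):
#' (2)/(3) node maps injective in both directions, (4)/(5) an edge map
#' forces consistent node maps, (6)/(7) every edge mapped exactly once or
#' marked unmapped, (8) objective bounded by the threshold (omitted when
#' `threshold` is `NULL`).
#'
#' @param g1,g2 `molgraph` objects.
#' @param threshold optional distance threshold `T` (> 0).
#' @return an object of class `mces_ilp`: variable tables `y`, `cvar`,
#'   `nvar`; objective coefficients `obj4` (quarter units); constraint
#'   triplets `con` with bounds; and `threshold4`.
#' @export
build_model <- function(g1, g2, threshold = NULL) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  a1 <- g1$atoms; a2 <- g2$atoms
  E1 <- g1$edges; E2 <- g2$edges
  m1 <- nrow(E1); m2 <- nrow(E2)

  y <- data.frame(i = integer(0), k = integer(0))
  if (length(a1) && length(a2)) {
    gr <- expand.grid(i = seq_along(a1), k = seq_along(a2))
    gr <- gr[a1[gr$i] == a2[gr$k], , drop = FALSE]
    y <- data.frame(i = gr$i, k = gr$k)
  }

  ce1 <- ce2 <- integer(0); cflip <- logical(0); cw4 <- integer(0)
  if (m1 && m2) {
    for (r in seq_len(m1)) {
      i <- E1[r, 1]; j <- E1[r, 2]
      for (s in seq_len(m2)) {
        k <- E2[s, 1]; l <- E2[s, 2]
        w4 <- abs(E1[r, 3] - E2[s, 3])
        if (a1[i] == a2[k] && a1[j] == a2[l]) {
          ce1 <- c(ce1, r); ce2 <- c(ce2, s)
          cflip <- c(cflip, FALSE); cw4 <- c(cw4, w4)
        }
        if (a1[i] == a2[l] && a1[j] == a2[k]) {
          ce1 <- c(ce1, r); ce2 <- c(ce2, s)
          cflip <- c(cflip, TRUE); cw4 <- c(cw4, w4)
        }
      }
    }
  }
  cvar <- data.frame(e1 = ce1, e2 = ce2, flip = cflip, w4 = cw4)
  nvar <- data.frame(graph = rep(1:2, c(m1, m2)),
                     edge = c(seq_len(m1), seq_len(m2)),
                     b4 = as.integer(c(E1[, 3], E2[, 3])))

  ny <- nrow(y); nc <- nrow(cvar); nn <- nrow(nvar)
  nvars <- ny + nc + nn
  obj4 <- c(rep(0L, ny), cvar$w4, nvar$b4)

  # orientation-resolved endpoints of each c variable: edge (i,j) of G1
  # maps onto (k,l) of G2 with i -> k and j -> l
  c_i <- E1[cvar$e1, 1]; c_j <- E1[cvar$e1, 2]
  c_k <- ifelse(cvar$flip, E2[cvar$e2, 2], E2[cvar$e2, 1])
  c_l <- ifelse(cvar$flip, E2[cvar$e2, 1], E2[cvar$e2, 2])

  ti <- list(); tj <- list(); tx <- list()
  lb <- numeric(0); ub <- numeric(0); fam <- character(0)
  nrow_ <- 0L
  add_row <- function(cols, lo, hi, family, vals = rep(1, length(cols))) {
    if (!length(cols)) return(invisible())
    nrow_ <<- nrow_ + 1L
    ti[[nrow_]] <<- rep(nrow_, length(cols))
    tj[[nrow_]] <<- as.integer(cols)
    tx[[nrow_]] <<- vals
    lb <<- c(lb, lo); ub <<- c(ub, hi); fam <<- c(fam, family)
  }

  for (i in unique(y$i)) add_row(which(y$i == i), -Inf, 1, "2")
  for (k in unique(y$k)) add_row(which(y$k == k), -Inf, 1, "3")

  # (4): for each node i of G1 and edge kl of G2, the c variables pairing
  # an edge at i with kl require i to be mapped to one endpoint of kl
  if (nc) {
    for (i in unique(c(c_i, c_j))) {
      for (s in seq_len(m2)) {
        sel <- which((c_i == i | c_j == i) & cvar$e2 == s)
        if (!length(sel)) next
        k <- E2[s, 1]; l <- E2[s, 2]
        ycols <- c(.yidx(y, i, k), .yidx(y, i, l))
        add_row(c(ny + sel, ycols), -Inf, 0, "4",
                c(rep(1, length(sel)), rep(-1, length(ycols))))
      }
    }
    # (5): symmetric, for each node k of G2 and edge ij of G1
    for (k in unique(c(c_k, c_l))) {
      for (r in seq_len(m1)) {
        sel <- which((c_k == k | c_l == k) & cvar$e1 == r)
        if (!length(sel)) next
        i <- E1[r, 1]; j <- E1[r, 2]
        ycols <- c(.yidx(y, i, k), .yidx(y, j, k))
        add_row(c(ny + sel, ycols), -Inf, 0, "5",
                c(rep(1, length(sel)), rep(-1, length(ycols))))
      }
    }
  }
  # (6)/(7): each edge mapped exactly once or flagged unmapped
  for (r in seq_len(m1))
    add_row(c(ny + which(cvar$e1 == r), ny + nc + r), 1, 1, "6")
  for (s in seq_len(m2))
    add_row(c(ny + which(cvar$e2 == s), ny + nc + m1 + s), 1, 1, "7")

  threshold4 <- NULL
  if (!is.null(threshold)) {
    stopifnot(threshold > 0)
    threshold4 <- .to_q(threshold)
    add_row(which(obj4 != 0), -Inf, threshold4, "8", obj4[obj4 != 0])
  }

  structure(list(
    y = y, cvar = cvar, nvar = nvar, obj4 = obj4, n_vars = nvars,
    con = list(i = unlist(ti), j = unlist(tj), x = unlist(tx),
               lb = lb, ub = ub, family = fam),
    threshold4 = threshold4,
    dims = c(n1 = length(a1), n2 = length(a2), m1 = m1, m2 = m2)),
    class = "mces_ilp")
}

.yidx <- function(y, i, k) which(y$i == i & y$k == k)

#' @export
print.mces_ilp <- function(x, ...) {
  cat(sprintf(
    "<mces integer program: %d y + %d c + %d n variables, %d constraints%s>\n",
    nrow(x$y), nrow(x$cvar), nrow(x$nvar), length(x$con$lb),
    if (is.null(x$threshold4)) "" else
      sprintf(", threshold %g", .q(x$threshold4))))
  invisible(x)
}

#' Export a built model in LP text format
#'
#' Writes the CPLEX-style LP representation of an [build_model()] result,
#' mainly for debugging and for feeding external solvers by hand.
#'
#' @param model an `mces_ilp`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "mces_ilp"))
  vn <- c(sprintf("y_%d_%d", model$y$i, model$y$k),
          sprintf("c_%d_%d%s", model$cvar$e1, model$cvar$e2,
                  ifelse(model$cvar$flip, "f", "")),
          sprintf("n_%d_%d", model$nvar$graph, model$nvar$edge))
  term <- function(v, x) paste(sprintf("%+g %s", x, vn[v]), collapse = " ")
  lines <- c("Minimize",
             paste(" obj:", term(which(model$obj4 != 0),
                                 model$obj4[model$obj4 != 0] / 4)),
             "Subject To")
  con <- model$con
  for (r in seq_along(con$lb)) {
    sel <- con$i == r
    lhs <- term(con$j[sel], con$x[sel])
    rel <- if (is.finite(con$lb[r]) && con$lb[r] == con$ub[r])
      sprintf("= %g", con$ub[r])
    else sprintf("<= %g", con$ub[r])
    lines <- c(lines, sprintf(" e%s_%d: %s %s", con$family[r], r, lhs, rel))
  }
  lines <- c(lines, "Binary", paste("", vn), "End")
  writeLines(lines, path)
  invisible(path)
}

# derive the full solution object from a node mapping (1-based, NA =
# unmapped): mapping an existing edge pair is never worse than leaving
# both unmatched, so the edge map follows from the node map
.solution_from_map <- function(g1, g2, node_map, status, threshold,
                               best_lower_bound4) {
  E1 <- g1$edges; E2 <- g2$edges
  W2 <- .adj4(g2)
  e2key <- if (nrow(E2)) paste(E2[, 1], E2[, 2]) else character(0)
  em1 <- em2 <- integer(0)
  obj4 <- 0L
  if (nrow(E1)) for (r in seq_len(nrow(E1))) {
    k <- node_map[E1[r, 1]]; l <- node_map[E1[r, 2]]
    if (!is.na(k) && !is.na(l) && W2[k, l] > 0L) {
      s <- match(paste(min(k, l), max(k, l)), e2key)
      em1 <- c(em1, r); em2 <- c(em2, s)
      obj4 <- obj4 + abs(E1[r, 3] - E2[s, 3])
    } else obj4 <- obj4 + E1[r, 3]
  }
  un1 <- setdiff(seq_len(nrow(E1)), em1)
  un2 <- setdiff(seq_len(nrow(E2)), em2)
  obj4 <- unname(obj4) + if (length(un2)) sum(E2[un2, 3]) else 0L
  structure(list(
    status = status,
    objective = if (status == "optimal") .q(obj4) else NA_real_,
    best_lower_bound = .q(max(best_lower_bound4,
                              if (status == "optimal") obj4 else 0L)),
    node_mapping = node_map,
    edge_mapping = cbind(e1 = em1, e2 = em2),
    unmatched_edges = data.frame(graph = rep(1:2, c(length(un1), length(un2))),
                                 edge = c(un1, un2)),
    threshold = threshold), class = "mces_solution")
}

#' @export
print.mces_solution <- function(x, ...) {
  cat(sprintf("<mces solution: %s%s, lower bound %g, %d mapped edge pairs>\n",
              x$status,
              if (!is.na(x$objective)) sprintf(", distance %g", x$objective)
              else "",
              x$best_lower_bound, nrow(x$edge_mapping)))
  invisible(x)
}

#' Solve a weighted MCES instance exactly
#'
#' Computes the minimum weighted MCES distance, optionally subject to the
#' threshold constraint (distance <= `threshold`; if no common-subgraph
#' mapping achieves it the instance is `infeasible` and the true distance
#' exceeds the threshold). The default `"bb"` backend is the package's
#' compiled branch-and-bound; `"scipy"` hands the explicit integer program
#' from [build_model()] to python's scipy (HiGHS), if available.
#'
#' @param g1,g2 `molgraph` objects.
#' @param threshold optional distance threshold `T` (> 0).
#' @param time_limit optional wall-clock limit in seconds (default none,
#'   matching the package's reference configuration).
#' @param solver `"bb"` (default) or `"scipy"`.
#' @return an `mces_solution`: `status` (`optimal`, `infeasible`, or
#'   `time_limit`), `objective` (when optimal; always recomputed from the
#'   mapping, so it is exact), `best_lower_bound` (valid lower bound on
#'   the true distance, never below the matching bound), `node_mapping`,
#'   `edge_mapping`, `unmatched_edges`.
#' @examples
#' toys <- toy_library()
#' solve_exact(toys$benzene, toys$cyclohexane)$objective  # 3
#' @export
solve_exact <- function(g1, g2, threshold = NULL, time_limit = NULL,
                        solver = c("bb", "scipy")) {
  solver <- match.arg(solver)
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  mb4 <- .matching_bound4(g1, g2)
  T4 <- if (is.null(threshold)) NULL else .to_q(threshold)

  if (solver == "scipy")
    return(.solve_scipy(g1, g2, T4, time_limit, threshold, mb4))

  swap <- length(g1$atoms) > length(g2$atoms)
  ga <- if (swap) g2 else g1
  gb <- if (swap) g1 else g2
  codes <- .split_codes(ga, gb)
  res <- .mces_bb_cpp(codes$a1, codes$a2, .adj4(ga), .adj4(gb),
                      if (is.null(T4)) -1 else T4,
                      if (is.null(time_limit)) -1 else time_limit)
  status <- c("optimal", "infeasible", "time_limit")[res$status + 1L]
  if (status == "infeasible" && is.null(T4))
    stop("internal error: unconstrained search reported infeasible")
  map_ab <- res$map
  node_map <- if (swap) {
    inv <- rep(NA_integer_, length(gb$atoms))
    ok <- which(!is.na(map_ab))
    inv[map_ab[ok]] <- ok
    inv
  } else map_ab
  lb4 <- switch(status, optimal = mb4,
                infeasible = max(mb4, T4),
                time_limit = mb4)
  sol <- .solution_from_map(g1, g2,
                            if (status == "optimal") node_map
                            else rep(NA_integer_, length(g1$atoms)),
                            status, threshold, lb4)
  if (status == "optimal" && .to_q(sol$objective) != res$obj4)
    stop("internal error: recomputed objective disagrees with search (",
         sol$objective, " vs ", .q(res$obj4), ")")
  sol
}

.solve_scipy <- function(g1, g2, T4, time_limit, threshold, mb4) {
  model <- build_model(g1, g2, threshold = threshold)
  payload <- list(
    n_vars = model$n_vars,
    obj = as.numeric(model$obj4),
    rows = as.numeric(model$con$i - 1L),
    cols = as.numeric(model$con$j - 1L),
    vals = as.numeric(model$con$x),
    lb = as.numeric(model$con$lb),
    ub = as.numeric(model$con$ub),
    time_limit = if (is.null(time_limit)) -1 else time_limit)
  res <- tryCatch(.run_python_tool("solve_milp.py", payload),
                  error = function(e)
                    stop("scipy MILP backend unavailable (requires python ",
                         "with scipy): ", conditionMessage(e), call. = FALSE))
  status <- res$status
  if (status == "optimal") {
    x <- round(unlist(res$x))
    node_map <- rep(NA_integer_, length(g1$atoms))
    on <- which(x[seq_len(nrow(model$y))] == 1)
    node_map[model$y$i[on]] <- model$y$k[on]
    sol <- .solution_from_map(g1, g2, node_map, "optimal", threshold, mb4)
    if (.to_q(sol$objective) != round(res$objective))
      stop("internal error: MILP objective ", res$objective / 4,
           " disagrees with mapping-derived distance ", sol$objective)
    return(sol)
  }
  lb4 <- if (status == "infeasible") max(mb4, T4) else mb4
  .solution_from_map(g1, g2, rep(NA_integer_, length(g1$atoms)),
                     status, threshold, lb4)
}

#' Independently verify an exact solution
#'
#' Recomputes every structural requirement of a solution directly from the
#' graphs: injectivity of the node map in both directions (families 2/3),
#' endpoint consistency of every mapped edge pair (4/5), the mapped-or-
#' unmatched dichotomy for every edge (6/7), and exact agreement of the
#' reported objective with the value recomputed from the mappings (1).
#'
#' @param g1,g2 `molgraph` objects.
#' @param sol an `mces_solution` with `status == "optimal"`.
#' @return `TRUE` if all checks pass, otherwise a character string naming
#'   the first violated constraint family, e.g. `"Eq. (6)"`.
#' @export
verify_solution <- function(g1, g2, sol) {
  .check_molgraph(g1, "g1"); .check_molgraph(g2, "g2")
  stopifnot(inherits(sol, "mces_solution"), sol$status == "optimal")
  nm <- sol$node_mapping
  mapped <- nm[!is.na(nm)]
  if (anyDuplicated(mapped)) return("Eq. (3)")
  if (length(nm) != length(g1$atoms)) return("Eq. (2)")
  if (any(g1$atoms[!is.na(nm)] != g2$atoms[mapped])) return("Eq. (9)")
  em <- sol$edge_mapping
  E1 <- g1$edges; E2 <- g2$edges
  if (nrow(em)) {
    if (anyDuplicated(em[, 1])) return("Eq. (6)")
    if (anyDuplicated(em[, 2])) return("Eq. (7)")
    for (r in seq_len(nrow(em))) {
      i <- E1[em[r, 1], 1]; j <- E1[em[r, 1], 2]
      k <- E2[em[r, 2], 1]; l <- E2[em[r, 2], 2]
      ok <- (!is.na(nm[i]) && !is.na(nm[j])) &&
        ((nm[i] == k && nm[j] == l) || (nm[i] == l && nm[j] == k))
      if (!ok) return("Eq. (4)")
    }
  }
  un <- sol$unmatched_edges
  cover1 <- sort(c(em[, 1], un$edge[un$graph == 1]))
  cover2 <- sort(c(em[, 2], un$edge[un$graph == 2]))
  if (length(cover1) != nrow(E1) || !all(cover1 == seq_len(nrow(E1))))
    return("Eq. (6)")
  if (length(cover2) != nrow(E2) || !all(cover2 == seq_len(nrow(E2))))
    return("Eq. (7)")
  obj4 <- 0L
  if (nrow(em)) for (r in seq_len(nrow(em)))
    obj4 <- obj4 + abs(E1[em[r, 1], 3] - E2[em[r, 2], 3])
  if (nrow(un)) {
    s1 <- un$edge[un$graph == 1]; s2 <- un$edge[un$graph == 2]
    if (length(s1)) obj4 <- obj4 + sum(E1[s1, 3])
    if (length(s2)) obj4 <- obj4 + sum(E2[s2, 3])
  }
  if (.to_q(sol$objective) != obj4) return("Eq. (1)")
  TRUE
}
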
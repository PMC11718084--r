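#' @useDynLib mcesdist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bond weights are held internally in quarter units (integers, value * 4) so
# that every bound and distance in the package is exact integer arithmetic:
# weights are multiples of 0.5 and both bounds divide by 2, so quarters are
# closed under all formulas. Public accessors always return decimals.
.ALLOWED_W4 <- c(4L, 6L, 8L)   # single, aromatic, double
.TRIPLE_W4 <- 12L

.q <- function(x4) x4 / 4          # quarter units -> decimal
.to_q <- function(x) {
  x4 <- round(x * 4)
  if (any(abs(x4 - x * 4) > 1e-9))
    stop("distance/weight values must be multiples of 0.25", call. = FALSE)
  as.integer(x4)
}

#' Construct a molecular graph from an explicit edge list
#'
#' A molecular graph is a simple, undirected graph whose nodes carry an
#' element symbol (heavy atoms only, hydrogens are never represented) and
#' whose edges carry a bond weight: 1 for a single, 1.5 for an aromatic and
#' 2 for a double bond (3 for a triple bond when `allow_triple = TRUE`).
#' All distances in the package are defined on these graphs.
#'
#' @param atoms character vector of element symbols, one per node.
#' @param bonds a list of length-3 vectors `(u, v, weight)`, or a matrix /
#'   data frame with three columns, using 1-based node indices. May be
#'   empty for an edgeless graph.
#' @param id optional structure identifier.
#' @param allow_triple accept bond weight 3 (default `TRUE`). The weighted
#'   MCES machinery is agnostic to the weight alphabet.
#' @return An object of class `molgraph` with elements `atoms` (character),
#'   `edges` (integer matrix with columns `u`, `v`, `w4`; weights in quarter
#'   units) and `id`.
#' @examples
#' propane <- mol_from_edges(c("C", "C", "C"), list(c(1, 2, 1), c(2, 3, 1)))
#' total_bond_weight(propane)
#' @export
mol_from_edges <- function(atoms, bonds = list(), id = NULL,
                           allow_triple = TRUE) {
  atoms <- as.character(atoms)
  if (length(atoms) < 1L) stop("a molecular graph needs at least one atom")
  if (anyNA(atoms) || any(!nzchar(atoms)))
    stop("atom symbols must be non-empty strings")
  if (is.matrix(bonds) || is.data.frame(bonds)) {
    bonds <- lapply(seq_len(nrow(bonds)), function(i) as.numeric(bonds[i, 1:3]))
  }
  m <- length(bonds)
  edges <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("u", "v", "w4")))
  if (m > 0L) {
    b <- do.call(rbind, lapply(bonds, function(e) {
      if (length(e) != 3L) stop("each bond must be (u, v, weight)")
      as.numeric(e)
    }))
    u <- as.integer(pmin(b[, 1], b[, 2]))
    v <- as.integer(pmax(b[, 1], b[, 2]))
    if (any(u < 1L) || any(v > length(atoms)))
      stop("bond endpoint index out of range")
    if (any(u == v)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(u, v)))
      stop("parallel edges are not allowed")
    w4 <- vapply(b[, 3], .to_q, integer(1))
    ok <- .ALLOWED_W4
    if (allow_triple) ok <- c(ok, .TRIPLE_W4)
    if (!all(w4 %in% ok))
      stop("bond weight must be one of 1, 1.5, 2",
           if (allow_triple) " or 3" else "", call. = FALSE)
    o <- order(u, v)
    edges <- cbind(u = u[o], v = v[o], w4 = w4[o])
  }
  structure(list(atoms = atoms, edges = edges, id = id), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d atoms (%s), %d bonds, total bond weight %.2f>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$atoms),
              paste(names(sort(table(x$atoms), decreasing = TRUE)),
                    collapse = ","),
              nrow(x$edges), total_bond_weight(x)))
  invisible(x)
}

.check_molgraph <- function(g, arg = "g") {
  if (!inherits(g, "molgraph"))
    stop(sprintf("`%s` must be a molgraph", arg), call. = FALSE)
  g
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer node count.
#' @export
n_atoms <- function(g) length(.check_molgraph(g)$atoms)

#' Number of bonds in a molecular graph
#' @param g a `molgraph`.
#' @return integer edge count.
#' @export
n_bonds <- function(g) nrow(.check_molgraph(g)$edges)

# weighted degree in quarter units, for all nodes
.wdeg4 <- function(g) {
  d <- integer(length(g$atoms))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      d[g$edges[r, 1]] <- d[g$edges[r, 1]] + g$edges[r, 3]
      d[g$edges[r, 2]] <- d[g$edges[r, 2]] + g$edges[r, 3]
    }
  }
  d
}

#' Weighted degree of a node
#'
#' The sum of incident bond weights of a heavy atom, the quantity on which
#' the first (degree) lower bound sorts and pairs nodes.
#'
#' @param g a `molgraph`.
#' @param node node index (1-based); if `NULL`, all nodes.
#' @return numeric weighted degree(s).
#' @export
weighted_degree <- function(g, node = NULL) {
  .check_molgraph(g)
  d <- .q(.wdeg4(g))
  if (is.null(node)) return(d)
  node <- as.integer(node)
  if (any(node < 1L | node > length(g$atoms)))
    stop("unknown node index", call. = FALSE)
  d[node]
}

#' Total bond weight of a molecular graph
#'
#' @param g a `molgraph`.
#' @return the sum of bond weights over all edges (0 for an edgeless graph).
#' @export
total_bond_weight <- function(g) {
  .check_molgraph(g)
  .q(sum(g$edges[, 3]))
}

# adjacency matrix in quarter units (dense; molecules are small)
.adj4 <- function(g) {
  n <- length(g$atoms)
  W <- matrix(0L, n, n)
  if (nrow(g$edges)) {
    W[g$edges[, 1:2, drop = FALSE]] <- g$edges[, 3]
    W[g$edges[, 2:1, drop = FALSE]] <- g$edges[, 3]
  }
  W
}

.python_bin <- function() {
  p <- Sys.getenv("MCESDIST_PYTHON", unset = Sys.which("python"))
  if (!nzchar(p) || (basename(p) != p && !file.exists(p)))
    stop("python interpreter not found; SMILES parsing and the 'scipy' ",
         "solver backend require python (set MCESDIST_PYTHON to override)",
         call. = FALSE)
  p
}

.run_python_tool <- function(script, input) {
  path <- system.file("python", script, package = "mcesdist")
  if (!nzchar(path)) stop("bundled python helper not found: ", script)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(input, auto_unbox = TRUE, digits = NA), tf)
  out <- suppressWarnings(system2(.python_bin(), c(path, tf),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("python helper '", script, "' failed: ",
         paste(out, collapse = "\n"), call. = FALSE)
  jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
}

#' Parse SMILES strings into molecular graphs
#'
#' Heavy-atom graphs are produced through RDKit (invoked as a bundled python
#' helper): hydrogens are dropped, aromaticity is taken from RDKit's
#' perception after sanitization (so kekulized input such as `C1=CC=CC=C1`
#' is re-perceived as aromatic), and bond orders map to weights 1 / 1.5 / 2
#' (3 for triple bonds unless `allow_triple = FALSE`). Atom type is the bare
#' element symbol; charge, isotopes and stereochemistry are ignored.
#' Multi-fragment SMILES (`.`) stay one disconnected graph.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers, recycled against `smiles`.
#' @param allow_triple if `FALSE`, structures containing triple bonds are
#'   rejected with an error.
#' @return A single `molgraph` when one SMILES is given, otherwise a list of
#'   `molgraph` objects. A structure with zero heavy atoms yields an empty
#'   graph carrying attribute `empty_input = TRUE`, with a warning.
#' @export
mol_from_smiles <- function(smiles, ids = NULL, allow_triple = TRUE) {
  smiles <- as.character(smiles)
  if (!length(smiles)) return(list())
  if (is.null(ids)) ids <- smiles
  ids <- rep_len(as.character(ids), length(smiles))
  res <- .run_python_tool("parse_smiles.py", as.list(smiles))
  out <- vector("list", length(smiles))
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!is.null(r$error))
      stop(sprintf("cannot parse SMILES '%s': %s", smiles[i], r$error),
           call. = FALSE)
    atoms <- unlist(r$atoms)
    if (length(atoms) == 0L) {
      warning(sprintf("SMILES '%s' has no heavy atoms; returning empty graph",
                      smiles[i]))
      g <- structure(list(atoms = character(0),
                          edges = matrix(integer(0), ncol = 3,
                                         dimnames = list(NULL, c("u", "v", "w4"))),
                          id = ids[i]),
                     class = "molgraph")
      attr(g, "empty_input") <- TRUE
      out[[i]] <- g
      next
    }
    bonds <- lapply(r$bonds, function(b)
      c(b[[1]] + 1, b[[2]] + 1, b[[3]]))
    out[[i]] <- mol_from_edges(atoms, bonds, id = ids[i],
                               allow_triple = allow_triple)
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Read a SMILES list file
#'
#' One record per line: a SMILES string, optionally followed by a
#' whitespace-separated identifier. Blank lines and lines starting with
#' `#` are skipped.
#'
#' @param path file path.
#' @param ... passed to [mol_from_smiles()].
#' @return a list of `molgraph` objects.
#' @export
read_smiles_file <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else p[[1]],
                character(1))
  res <- mol_from_smiles(smiles, ids = ids, ...)
  if (inherits(res, "molgraph")) list(res) else res
}

#' Read / write the edge-list JSON fixture dialect
#'
#' The JSON form `{"atoms": ["C", ...], "bonds": [[u, v, w], ...]}` with
#' 0-based node indices; used to exercise the toolchain without SMILES
#' parsing.
#'
#' @param path file path.
#' @return `mol_from_json`: a `molgraph`; `mol_to_json` invisibly returns
#'   `path`.
#' @export
mol_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$atoms)) stop("JSON fixture lacks an 'atoms' field")
  bonds <- lapply(x$bonds, function(b) c(b[[1]] + 1, b[[2]] + 1, b[[3]]))
  mol_from_edges(unlist(x$atoms), bonds,
                 id = if (!is.null(x$id)) x$id else NULL)
}

#' @rdname mol_from_json
#' @param g a `molgraph` to serialize.
#' @export
mol_to_json <- function(g, path) {
  .check_molgraph(g)
  bonds <- lapply(seq_len(nrow(g$edges)), function(r)
    list(g$edges[r, 1] - 1L, g$edges[r, 2] - 1L, .q(g$edges[r, 3])))
  x <- list(atoms = as.list(g$atoms), bonds = bonds)
  if (!is.null(g$id)) x$id <- g$id
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
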
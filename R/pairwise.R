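# Batch pairwise myopic distances over structure lists: long-form tables
# (lower triangle, one record per unordered pair), nearest-neighbor and
# coverage statistics, and lossless CSV round trips. Values at or above
# the threshold are censored — they mean "at least this dissimilar".

.new_table <- function(ids, records, threshold) {
  structure(list(ids = ids, records = records, threshold = threshold),
            class = "mces_table")
}

.empty_records <- function() {
  data.frame(id1 = character(0), id2 = character(0), value = numeric(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' @export
print.mces_table <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf("<mces distance table: %d structures, %d/%d pairs, T = %g>\n",
              n, nrow(x$records), n * (n - 1) / 2, x$threshold))
  invisible(x)
}

.missing_pairs <- function(table) {
  ids <- table$ids
  if (length(ids) < 2L) return(data.frame(id1 = character(0), id2 = character(0)))
  all_pairs <- t(utils::combn(ids, 2L))
  have <- paste(table$records$id1, table$records$id2)
  miss <- !(paste(all_pairs[, 1], all_pairs[, 2]) %in% have)
  data.frame(id1 = all_pairs[miss, 1], id2 = all_pairs[miss, 2])
}

.structure_ids <- function(structures) {
  ids <- vapply(seq_along(structures), function(i) {
    g <- structures[[i]]
    if (!is.null(g$id)) as.character(g$id)
    else if (!is.null(names(structures)) && nzchar(names(structures)[i]))
      names(structures)[i]
    else sprintf("s%03d", i)
  }, character(1))
  if (anyDuplicated(ids))
    stop("structure ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ids
}

#' Pairwise myopic MCES distances over a structure list
#'
#' Computes the complete lower-triangle table of myopic distances. Each
#' pair is an independent deterministic computation, so results do not
#' depend on worker count or visit order; with `checkpoint` set, finished
#' chunks are persisted and a killed run can be resumed via `resume_from`.
#'
#' @param structures list of `molgraph` objects with unique ids.
#' @param T distance threshold (default 10).
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param resume_from an existing partial `mces_table` (or path to one)
#'   whose pairs are reused rather than recomputed; its threshold must
#'   match.
#' @param checkpoint optional CSV path; the table is rewritten there after
#'   every completed chunk.
#' @param solver,time_limit passed to [myopic_distance()].
#' @return an `mces_table`: `ids`, `records` (`id1`, `id2`, `value`,
#'   `provenance`), `threshold`. Self-distances (zero) are implicit.
#' @export
pairwise_distances <- function(structures, T = 10, workers = 1L,
                               resume_from = NULL, checkpoint = NULL,
                               solver = "bb", time_limit = NULL) {
  ids <- .structure_ids(structures)
  if (length(structures) < 2L)
    return(.new_table(ids, .empty_records(), T))
  if (is.character(resume_from)) resume_from <- read_table(resume_from)
  done <- .empty_records()
  if (!is.null(resume_from)) {
    stopifnot(inherits(resume_from, "mces_table"))
    if (!isTRUE(all.equal(resume_from$threshold, T)))
      stop("resume_from table was computed at T = ", resume_from$threshold,
           ", not ", T, call. = FALSE)
    done <- resume_from$records
  }
  pairs <- t(utils::combn(seq_along(ids), 2L))
  key <- paste(ids[pairs[, 1]], ids[pairs[, 2]])
  todo <- which(!(key %in% paste(done$id1, done$id2)))

  compute_one <- function(p) {
    r <- myopic_distance(structures[[pairs[p, 1]]], structures[[pairs[p, 2]]],
                         T = T, solver = solver, time_limit = time_limit)
    data.frame(id1 = ids[pairs[p, 1]], id2 = ids[pairs[p, 2]],
               value = r$value, provenance = r$provenance,
               stringsAsFactors = FALSE)
  }

  records <- done
  if (length(todo)) {
    # deterministic sharding by pair index; chunking only affects
    # checkpoint granularity, never values
    chunks <- split(todo, ceiling(seq_along(todo) / max(50L, workers * 25L)))
    for (ch in chunks) {
      res <- if (workers > 1L) {
        parallel::mclapply(ch, compute_one, mc.cores = workers)
      } else lapply(ch, compute_one)
      bad <- vapply(res, function(x) !is.data.frame(x), logical(1))
      if (any(bad))
        stop("worker failure on ", sum(bad), " pair(s): ",
             conditionMessage(attr(res[[which(bad)[1]]], "condition")),
             call. = FALSE)
      records <- rbind(records, do.call(rbind, res))
      if (!is.null(checkpoint))
        write_table(.new_table(ids, .sort_records(records, ids), T), checkpoint)
    }
  }
  .new_table(ids, .sort_records(records, ids), T)
}

.sort_records <- function(records, ids) {
  o <- order(match(records$id1, ids), match(records$id2, ids))
  rec <- records[o, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Nearest-neighbor distances within a distance table
#'
#' For each query structure, the minimum stored distance to any other
#' structure — the per-structure statistic whose histogram shows how
#' densely a set covers itself. Minima at or above the threshold are
#' censored: the true nearest neighbor is at least that far.
#'
#' @param table a complete `mces_table`.
#' @param query_ids subset of ids (default: all).
#' @return data frame with `id`, `min_distance`, `censored`.
#' @export
nearest_neighbor_distances <- function(table, query_ids = NULL) {
  stopifnot(inherits(table, "mces_table"))
  miss <- .missing_pairs(table)
  if (nrow(miss))
    stop("table is incomplete (", nrow(miss), " missing pairs)", call. = FALSE)
  if (is.null(query_ids)) query_ids <- table$ids
  unknown <- setdiff(query_ids, table$ids)
  if (length(unknown) == length(query_ids) && length(query_ids)) {
    warning("none of the query ids occur in the table")
    return(data.frame(id = character(0), min_distance = numeric(0),
                      censored = logical(0)))
  }
  if (length(unknown))
    stop("query ids not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rec <- table$records
  out <- lapply(query_ids, function(id) {
    v <- c(rec$value[rec$id1 == id], rec$value[rec$id2 == id])
    data.frame(id = id, min_distance = min(v),
               censored = min(v) >= table$threshold)
  })
  do.call(rbind, out)
}

#' Coverage of a structure set by a background set
#'
#' For each dataset structure, the distance to its `k`-th closest
#' background structure — small values mean the region around that
#' structure is covered by the background (e.g. training) set, values at
#' the threshold are censored ("at least T away from everything").
#'
#' @param dataset,background lists of `molgraph` objects.
#' @param T distance threshold.
#' @param k which order statistic (1 = nearest).
#' @param workers,solver,time_limit as in [pairwise_distances()].
#' @return data frame with `id`, `distance`, `censored`, one row per
#'   dataset structure.
#' @export
coverage_profile <- function(dataset, background, T = 10, k = 1L,
                             workers = 1L, solver = "bb", time_limit = NULL) {
  if (!length(background)) stop("background set is empty", call. = FALSE)
  if (k > length(background))
    stop("k exceeds the background size", call. = FALSE)
  ids <- .structure_ids(dataset)
  compute_row <- function(i) {
    v <- vapply(background, function(bg)
      myopic_distance(dataset[[i]], bg, T = T, solver = solver,
                      time_limit = time_limit)$value, numeric(1))
    kv <- sort(v, partial = k)[k]
    data.frame(id = ids[i], distance = kv, censored = kv >= T,
               stringsAsFactors = FALSE)
  }
  res <- if (workers > 1L) {
    parallel::mclapply(seq_along(dataset), compute_row, mc.cores = workers)
  } else lapply(seq_along(dataset), compute_row)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write / read a distance table as annotated CSV
#'
#' Long-form lower-triangle CSV with a `#`-prefixed header block holding
#' the tool version, threshold and the ordered id list, so the round trip
#' is lossless (including provenance).
#'
#' @param table an `mces_table`.
#' @param path file path.
#' @return `write_table` invisibly returns `path`; `read_table` returns
#'   the `mces_table`.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "mces_table"))
  header <- c(
    sprintf("# mcesdist %s",
            as.character(utils::packageVersion("mcesdist"))),
    sprintf("# threshold: %g", table$threshold),
    sprintf("# ids: %s", paste(table$ids, collapse = ",")),
    "id1,id2,value,provenance")
  rec <- table$records
  body <- if (nrow(rec)) sprintf("%s,%s,%g,%s", rec$id1, rec$id2,
                                 rec$value, rec$provenance) else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  thr_line <- grep("^# threshold:", lines)
  ids_line <- grep("^# ids:", lines)
  if (!length(thr_line) || !length(ids_line))
    stop("malformed table file (line 1): missing '# threshold:'/'# ids:' ",
         "header block", call. = FALSE)
  threshold <- as.numeric(sub("^# threshold:\\s*", "", lines[thr_line[1]]))
  ids <- strsplit(sub("^# ids:\\s*", "", lines[ids_line[1]]), ",")[[1]]
  col_line <- which(lines == "id1,id2,value,provenance")
  if (!length(col_line))
    stop("malformed table file: no column header line", call. = FALSE)
  body_idx <- seq.int(col_line[1] + 1L, length.out = length(lines) - col_line[1])
  rec <- .empty_records()
  for (li in body_idx) {
    if (!nzchar(trimws(lines[li]))) next
    parts <- strsplit(lines[li], ",", fixed = TRUE)[[1]]
    if (length(parts) != 4L || is.na(suppressWarnings(as.numeric(parts[3]))))
      stop("malformed table record at line ", li, ": '", lines[li], "'",
           call. = FALSE)
    if (!all(parts[1:2] %in% ids))
      stop("malformed table record at line ", li, ": unknown id", call. = FALSE)
    rec <- rbind(rec, data.frame(id1 = parts[1], id2 = parts[2],
                                 value = as.numeric(parts[3]),
                                 provenance = parts[4],
                                 stringsAsFactors = FALSE))
  }
  .new_table(ids, .sort_records(rec, ids), threshold)
}

#' Export a table as a square symmetric distance matrix
#'
#' The hand-off format for embedding tools that accept precomputed
#' distances (UMAP, t-SNE, MDS): values are mirrored across the diagonal,
#' which is zero.
#'
#' @param table a complete `mces_table`.
#' @param path optional CSV path; if `NULL` the matrix is returned only.
#' @return the symmetric numeric matrix, invisibly when `path` is given.
#' @export
as_distance_matrix <- function(table, path = NULL) {
  stopifnot(inherits(table, "mces_table"))
  miss <- .missing_pairs(table)
  if (nrow(miss))
    stop("table is incomplete (", nrow(miss), " missing pairs)", call. = FALSE)
  ids <- table$ids
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  rec <- table$records
  D[cbind(match(rec$id1, ids), match(rec$id2, ids))] <- rec$value
  D[cbind(match(rec$id2, ids), match(rec$id1, ids))] <- rec$value
  if (!is.null(path)) {
    utils::write.csv(D, path)
    return(invisible(D))
  }
  D
}
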
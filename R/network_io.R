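#' Construct a weighted PPI network
#'
#' A `weighted_network` is an undirected weighted graph over protein
#' identifiers: no self-loops, no duplicate edges, weights in (0, 1].
#'
#' @param edges data frame with columns `from`, `to` (character) and
#'   `weight` (numeric in (0, 1]). Unordered pairs; duplicates (in either
#'   orientation) are collapsed keeping the maximum weight and self-loops
#'   are dropped.
#' @param nodes optional character vector of node identifiers. Nodes
#'   appearing in `edges` are always included; extra ids declare isolated
#'   nodes.
#' @param name network label, e.g. `"combinedscore"` or `"experimental"`.
#' @return an object of class `weighted_network` with elements `nodes`
#'   (character), `edges` (data.frame from/to/weight with from < to) and
#'   `name`.
#' @export
weighted_network <- function(edges, nodes = NULL, name = "combinedscore") {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    stop("edge weights must be finite and in (0, 1]")
  }
  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0) {
    message(n_loops, " self-loop(s) dropped")
  }
  from2 <- pmin(from[keep], to[keep])
  to2 <- pmax(from[keep], to[keep])
  w <- w[keep]
  key <- paste(from2, to2, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    from2 <- vapply(parts, `[`, "", 1L)
    to2 <- vapply(parts, `[`, "", 2L)
    w <- unname(w)
  }
  nodes <- sort(unique(c(from2, to2, as.character(nodes))))
  structure(
    list(
      nodes = nodes,
      edges = data.frame(from = from2, to = to2, weight = w,
                         stringsAsFactors = FALSE),
      name = name
    ),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' Parses a whitespace-delimited file with columns protein1, protein2,
#' combined_score (integer 0..`score_scale`). An optional single header
#' row is detected by a non-numeric third column. Raw scores are divided
#' by `score_scale`, duplicate pairs collapse to the maximum weight and
#' self-loops are dropped (with a message).
#'
#' @param path path to the edge-list file.
#' @param score_scale positive number; raw scores are divided by it
#'   (STRING combined scores are integers 0-1000, so the default maps
#'   them into (0, 1]).
#' @param name network label stored on the result.
#' @param min_score optional raw-score cutoff; edges with score strictly
#'   below it are discarded before normalization. `NULL` (default) keeps
#'   every edge.
#' @return a [weighted_network()].
#' @export
read_string_edgelist <- function(path, score_scale = 1000, name = "combinedscore",
                                 min_score = NULL) {
  stopifnot(is.numeric(score_scale), score_scale > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d: expected 3 columns, found %d",
                 bad[1], length(fields[[bad[1]]])))
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  # a header row is only plausible when data rows follow it
  start <- if (is.na(first_score) && length(fields) > 1L) 2L else 1L
  if (is.na(first_score) && length(fields) == 1L) {
    stop(sprintf("non-numeric score at line 1: '%s'", fields[[1]][3]))
  }
  m <- do.call(rbind, fields[start:length(fields)])
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score)) {
    stop(sprintf("non-numeric score at line %d: '%s'",
                 which(is.na(score))[1] + start - 1L, m[which(is.na(score))[1], 3]))
  }
  out_of_range <- score < 0 | score > score_scale
  if (any(out_of_range)) {
    stop(sprintf("score outside [0, %g] at line %d",
                 score_scale, which(out_of_range)[1] + start - 1L))
  }
  if (!is.null(min_score)) {
    keep <- score >= min_score
    m <- m[keep, , drop = FALSE]
    score <- score[keep]
  }
  keep <- score > 0
  weighted_network(
    data.frame(from = m[keep, 1], to = m[keep, 2], weight = score[keep] / score_scale,
               stringsAsFactors = FALSE),
    name = name
  )
}

#' Write a network back to the STRING edge-list format
#'
#' Inverse of [read_string_edgelist()]: weights are multiplied by
#' `score_scale` and written as "protein1 protein2 combined_score" with a
#' header row.
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @param score_scale scale used to restore raw scores.
#' @export
write_string_edgelist <- function(net, path, score_scale = 1000) {
  stopifnot(inherits(net, "weighted_network"))
  df <- data.frame(protein1 = net$edges$from, protein2 = net$edges$to,
                   combined_score = net$edges$weight * score_scale)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column identifier mapping table
#'
#' @param path TSV file with columns source_id, target_id (no header
#'   required; a header row whose first field is "source_id" is skipped).
#' @return named character vector: `names` are source ids, values are
#'   canonical target ids. Applying the map twice equals applying it once.
#' @export
read_id_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("source_id", "target_id"))
  if (nrow(df) > 0 && df$source_id[1] == "source_id") df <- df[-1, , drop = FALSE]
  map <- stats::setNames(as.character(df$target_id), as.character(df$source_id))
  map[!duplicated(names(map))]
}

#' Rename network nodes through an identifier mapping
#'
#' Node ids are replaced by their canonical id; ids absent from the map
#' are kept verbatim (and counted in a message). When the mapping merges
#' two nodes, parallel edges collapse to the maximum weight; edges that
#' become self-loops are dropped.
#'
#' @param net a [weighted_network()].
#' @param map named character vector as returned by [read_id_mapping()].
#' @return a [weighted_network()] over canonical ids.
#' @export
apply_mapping <- function(net, map) {
  stopifnot(inherits(net, "weighted_network"))
  translate <- function(ids) {
    hit <- ids %in% names(map)
    ids[hit] <- unname(map[ids[hit]])
    ids
  }
  n_unmapped <- sum(!net$nodes %in% names(map))
  if (n_unmapped > 0 && length(map) > 0) {
    message(n_unmapped, " node id(s) not in mapping kept verbatim")
  }
  suppressMessages(weighted_network(
    data.frame(from = translate(net$edges$from), to = translate(net$edges$to),
               weight = net$edges$weight, stringsAsFactors = FALSE),
    nodes = translate(net$nodes),
    name = net$name
  ))
}

#' Summarize a network against a training protein set
#'
#' Mirrors the usual per-network summary table for PPI-based function
#' prediction: node count, edge count and the percentage of training
#' proteins covered by the network.
#'
#' @param net a [weighted_network()].
#' @param training_ids character vector of training protein ids.
#' @return list with `n_proteins`, `n_interactions`, `coverage` (percent
#'   of `training_ids` present among the network nodes).
#' @export
network_summary <- function(net, training_ids) {
  stopifnot(inherits(net, "weighted_network"))
  training_ids <- unique(as.character(training_ids))
  if (length(training_ids) == 0L) {
    stop("coverage undefined for an empty training set")
  }
  list(
    n_proteins = length(net$nodes),
    n_interactions = nrow(net$edges),
    coverage = 100 * sum(training_ids %in% net$nodes) / length(training_ids)
  )
}

# Dense weighted adjacency matrix in node order; used by the embedding
# stage. Symmetric, zero diagonal.
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  i <- idx[net$edges$from]
  j <- idx[net$edges$to]
  A[cbind(i, j)] <- net$edges$weight
  A[cbind(j, i)] <- net$edges$weight
  A
}
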
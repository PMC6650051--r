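#' Parse a Gene Ontology OBO 1.2 file
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, is_obsolete) and
#' builds a DAG over the non-obsolete terms. Only `is_a` links are kept;
#' `relationship:` lines (part_of, regulates, ...) are ignored, as is
#' everything outside `[Term]` stanzas. `is_a` edges pointing to obsolete
#' or undeclared terms are dropped.
#'
#' @param path path to an OBO 1.2 file.
#' @param namespace optional namespace filter (e.g.
#'   `"biological_process"`); `NULL` keeps all namespaces.
#' @return an object of class `ontology_dag`: list with `terms`
#'   (character), `parents` (named list, child id -> character vector of
#'   is_a parents), `name` and `namespace` (named character vectors).
#' @export
parse_obo <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); ns <- character(0)
  obsolete <- logical(0); parents <- list()
  for (k in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]  # stop at next stanza header of other type
    field <- function(tag) sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ":"), chunk, value = TRUE))
    id <- field("id")
    if (length(id) == 0L) stop("[Term] stanza without an id (stanza ", k, ")")
    id <- trimws(id[1])
    is_a_raw <- field("is_a")
    # "GO:0000002 ! mitochondrial genome maintenance" -> "GO:0000002"
    is_a <- trimws(sub("!.*$", "", is_a_raw))
    ids <- c(ids, id)
    nms <- c(nms, if (length(field("name"))) field("name")[1] else id)
    ns <- c(ns, if (length(field("namespace"))) field("namespace")[1] else NA_character_)
    obsolete <- c(obsolete, any(grepl("^is_obsolete: *true", chunk)))
    parents[[id]] <- is_a[nzchar(is_a)]
  }
  keep <- !obsolete
  if (!is.null(namespace)) keep <- keep & (ns %in% namespace)
  terms <- ids[keep]
  parents <- parents[terms]
  parents <- lapply(parents, function(p) p[p %in% terms])
  dag <- structure(
    list(terms = terms,
         parents = parents,
         name = stats::setNames(nms[keep], terms),
         namespace = stats::setNames(ns[keep], terms)),
    class = "ontology_dag"
  )
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("is_a graph is cyclic: ", paste(cyc, collapse = " -> "))
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag: %d terms, %d is_a edges>\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

# Kahn topological sort; returns one cycle (as an id path) or NULL.
find_cycle <- function(dag) {
  indeg <- stats::setNames(integer(length(dag$terms)), dag$terms)
  for (ps in dag$parents) for (p in ps) indeg[p] <- indeg[p] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in dag$parents[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(dag$terms)) return(NULL)
  # walk parent links inside the residual set until a repeat gives the cycle
  residual <- names(indeg)[indeg > 0L]
  path <- residual[1L]
  repeat {
    nxt <- intersect(dag$parents[[path[length(path)]]], residual)[1L]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
  }
}

#' Ancestors of a term via is_a
#'
#' @param dag an [parse_obo()] DAG.
#' @param term a term id present in `dag`.
#' @return character vector of strict ancestors (the term itself
#'   excluded), sorted.
#' @export
term_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term)
  out <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  sort(unique(out))
}

#' Strict descendants of a term via is_a
#'
#' Used to assemble descendant-aware positive sets when training per-term
#' classifiers: a protein annotated with any descendant of *t* counts as
#' a positive for *t*.
#'
#' @inheritParams term_ancestors
#' @return character vector of strict descendants, sorted.
#' @export
term_descendants <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term)
  children <- children_map(dag)
  out <- character(0)
  frontier <- children[[term]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(children[frontier], use.names = FALSE))
  }
  sort(unique(out))
}

children_map <- function(dag) {
  ch <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (child in names(dag$parents)) {
    for (p in dag$parents[[child]]) ch[[p]] <- c(ch[[p]], child)
  }
  ch
}

#' Build a propagated binary annotation matrix
#'
#' Filters raw annotations to the accepted (experimental) evidence codes,
#' drops unknown terms with a warning, and closes each protein's label
#' set upward over is_a (the true-path rule). Proteins left without any
#' accepted annotation are dropped.
#'
#' @param raw data frame with columns `protein`, `term`, `evidence` (a
#'   GAF-like TSV read with [read_annotations()]).
#' @param dag an `ontology_dag`.
#' @param accepted_evidence evidence codes retained; defaults to the
#'   experimental set EXP, IDA, IPI, IMP, IGI, IEP.
#' @return binary matrix (0/1) proteins x terms, class
#'   `annotation_matrix`; rows are sorted protein ids, columns sorted
#'   term ids; attribute `evidence` records the filter.
#' @export
propagate_annotations <- function(raw, dag,
                                  accepted_evidence = c("EXP", "IDA", "IPI",
                                                        "IMP", "IGI", "IEP")) {
  stopifnot(is.data.frame(raw), all(c("protein", "term", "evidence") %in% names(raw)),
            inherits(dag, "ontology_dag"))
  keep <- raw$evidence %in% accepted_evidence
  raw <- raw[keep, , drop = FALSE]
  unknown <- !raw$term %in% dag$terms
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) to unknown/obsolete terms dropped")
    raw <- raw[!unknown, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no annotations left after evidence/term filtering")
  anc_cache <- new.env(parent = emptyenv())
  closure <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- c(t, term_ancestors(dag, t))
    anc_cache[[t]]
  }
  per_protein <- split(as.character(raw$term), as.character(raw$protein))
  labels <- lapply(per_protein, function(ts) {
    unique(unlist(lapply(unique(ts), closure), use.names = FALSE))
  })
  proteins <- sort(names(labels))
  terms <- sort(unique(unlist(labels, use.names = FALSE)))
  M <- matrix(0L, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  for (p in proteins) M[p, labels[[p]]] <- 1L
  structure(M, evidence = accepted_evidence, class = c("annotation_matrix", "matrix", "array"))
}

#' Read a GAF-like annotation table
#'
#' @param path TSV with columns protein_id, go_id, evidence_code
#'   (header optional, detected by a first field of "protein_id").
#' @return data frame with columns `protein`, `term`, `evidence`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "!", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("annotation table needs 3 columns: protein_id, go_id, evidence_code")
  df <- df[, 1:3]
  names(df) <- c("protein", "term", "evidence")
  if (nrow(df) > 0 && df$protein[1] == "protein_id") df <- df[-1, , drop = FALSE]
  df
}

#' Select the prediction vocabulary: frequent, deepest terms
#'
#' Candidate terms are those annotating at least `min_count` proteins in
#' the propagated matrix. Among the candidates, only the deepest are
#' retained: a candidate is dropped whenever some other candidate is its
#' strict is_a descendant, so the retained set is an antichain (no is_a
#' path between any two retained terms).
#'
#' @param ann a propagated [propagate_annotations()] matrix.
#' @param dag the `ontology_dag` the annotations were propagated over.
#' @param min_count minimum number of annotated proteins per term.
#' @return object of class `term_vocabulary`: list with `terms`
#'   (lexicographically sorted) and `min_count`.
#' @export
select_term_vocabulary <- function(ann, dag, min_count = 100) {
  stopifnot(inherits(ann, "annotation_matrix"), inherits(dag, "ontology_dag"))
  counts <- colSums(ann)
  candidates <- colnames(ann)[counts >= min_count]
  candidates <- intersect(candidates, dag$terms)
  keep <- vapply(candidates, function(t) {
    !any(term_descendants(dag, t) %in% candidates)
  }, logical(1))
  terms <- sort(candidates[keep])
  if (length(terms) == 0L) message("empty term vocabulary at min_count = ", min_count)
  structure(list(terms = terms, min_count = min_count), class = "term_vocabulary")
}

#' @export
print.term_vocabulary <- function(x, ...) {
  cat(sprintf("<term_vocabulary: %d terms (min_count %d)>\n",
              length(x$terms), x$min_count))
  invisible(x)
}

#' Write an ontology DAG as an OBO 1.2 file
#'
#' Emits one `[Term]` stanza per term with id, name, namespace and is_a
#' lines; the inverse of [parse_obo()] for the fields this package
#' consumes.
#'
#' @param dag an `ontology_dag`.
#' @param path output file.
#' @export
write_obo_file <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", dag$name[[t]]),
               if (!is.na(dag$namespace[[t]]))
                 paste0("namespace: ", dag$namespace[[t]]),
               paste0("is_a: ", dag$parents[[t]], " ! ", dag$parents[[t]]),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a vocabulary as one term id per line
#' @param vocab a `term_vocabulary`.
#' @param path output file.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$terms, path)
  invisible(path)
}
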
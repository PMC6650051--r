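#' Homology oracle backed by a tabular hit list
#'
#' Wraps a precomputed homology table (BLAST tabular / outfmt-6
#' compatible: the query, subject and E-value columns are used, extra
#' columns are ignored) behind a simple interface answering "which
#' subjects hit this query at E <= threshold". Running the alignment
#' itself is deliberately outside this package.
#'
#' @param table data frame with columns `query`, `subject`, `evalue`, or
#'   a path to a TSV in that layout (12-column BLAST tabular accepted:
#'   columns 1, 2 and 11 are used).
#' @param symmetric treat hits as symmetric (a hit query->subject also
#'   counts subject->query).
#' @return object of class `homology_oracle`.
#' @export
homology_oracle <- function(table, symmetric = FALSE) {
  if (is.character(table)) {
    df <- utils::read.table(table, sep = "\t", header = FALSE, quote = "",
                            stringsAsFactors = FALSE)
    cols <- if (ncol(df) >= 12) c(1L, 2L, 11L) else c(1L, 2L, 3L)
    df <- df[, cols]
    names(df) <- c("query", "subject", "evalue")
  } else {
    df <- as.data.frame(table)[, c("query", "subject", "evalue")]
  }
  df$query <- as.character(df$query)
  df$subject <- as.character(df$subject)
  df$evalue <- as.numeric(df$evalue)
  if (any(df$evalue <= 0)) stop("E-values must be positive")
  if (symmetric) {
    df <- rbind(df, data.frame(query = df$subject, subject = df$query,
                               evalue = df$evalue))
  }
  structure(list(hits = df, symmetric = symmetric), class = "homology_oracle")
}

#' @rdname homology_oracle
#' @param oracle a `homology_oracle`.
#' @param query query protein id.
#' @param threshold E-value threshold.
#' @return for `homology_hits`, the character vector of subjects hit at
#'   E <= threshold (empty when there is no hit).
#' @export
homology_hits <- function(oracle, query, threshold) {
  stopifnot(inherits(oracle, "homology_oracle"))
  h <- oracle$hits
  unique(h$subject[h$query == query & h$evalue <= threshold])
}

#' Random hold-out split over well-annotated proteins
#'
#' Selects the proteins meeting the well-annotated rule (at least
#' `min_terms` annotated terms in `ann`) and samples `holdout_size` of
#' them uniformly (seeded) for hold-out evaluation; the remainder is the
#' training pool.
#'
#' @param ann propagated annotation matrix; the selection rule counts
#'   its columns, so pass a matrix including electronic annotations if
#'   the selection should count them.
#' @param min_terms minimum annotation count to qualify as
#'   well-annotated.
#' @param holdout_size number of hold-out proteins; if fewer qualify,
#'   all of them are taken with a warning.
#' @param seed integer seed.
#' @return object of class `split_spec`: list with `train`, `holdout`,
#'   `seed`, `min_terms`.
#' @export
make_holdout_split <- function(ann, min_terms = 1, holdout_size = 1000,
                               seed = 1L) {
  ann <- unclass(ann)
  counts <- rowSums(ann)
  eligible <- rownames(ann)[counts >= min_terms]
  if (length(eligible) == 0L) {
    warning("no protein meets the well-annotated rule; empty hold-out")
    holdout <- character(0)
  } else if (length(eligible) < holdout_size) {
    warning("only ", length(eligible), " eligible proteins; taking all as hold-out")
    holdout <- eligible
  } else {
    set.seed(seed)
    holdout <- sort(sample(eligible, holdout_size))
  }
  structure(list(train = setdiff(rownames(ann), holdout),
                 holdout = holdout, seed = as.integer(seed),
                 min_terms = min_terms),
            class = "split_spec")
}

#' Temporal validation set: proteins annotated only after the snapshot
#'
#' Returns the proteins with zero vocabulary annotations in the earlier
#' annotation snapshot and at least one in the later snapshot — the
#' proteins whose first vocabulary annotation arrived in between.
#'
#' @param ann_t0 annotation matrix at the training snapshot.
#' @param ann_t1 annotation matrix at the later snapshot.
#' @param vocab a [select_term_vocabulary()] vocabulary shared by both.
#' @return character vector of temporal-validation protein ids.
#' @export
make_temporal_split <- function(ann_t0, ann_t1, vocab) {
  ann_t0 <- unclass(ann_t0); ann_t1 <- unclass(ann_t1)
  v0 <- intersect(vocab$terms, colnames(ann_t0))
  v1 <- intersect(vocab$terms, colnames(ann_t1))
  count0 <- rowSums(ann_t0[, v0, drop = FALSE])
  count1 <- rowSums(ann_t1[, v1, drop = FALSE])
  gained <- rownames(ann_t1)[count1 > 0]
  annotated_before <- rownames(ann_t0)[count0 > 0]
  sort(setdiff(gained, annotated_before))
}

#' Remove evaluation proteins with training-set homologs
#'
#' Drops every evaluation protein with at least one training protein at
#' E-value <= `evalue_threshold` according to the oracle. Raising the
#' threshold widens the homology definition, so the filtered set size is
#' non-increasing in the threshold.
#'
#' @param eval_ids evaluation protein ids.
#' @param train_ids training protein ids.
#' @param oracle a [homology_oracle()].
#' @param evalue_threshold positive E-value cutoff (typical sweep: 1e-5,
#'   1e-4, 1e-3, 1e-2).
#' @return the filtered evaluation id vector (original order).
#' @export
homolog_removal <- function(eval_ids, train_ids, oracle, evalue_threshold) {
  stopifnot(evalue_threshold > 0)
  has_homolog <- vapply(eval_ids, function(q) {
    any(homology_hits(oracle, q, evalue_threshold) %in% train_ids)
  }, logical(1))
  eval_ids[!has_homolog]
}

#' Write / read a split as one protein id per line
#'
#' A DCF sidecar `<path>.meta` records the rule and seed.
#'
#' @param ids character vector of protein ids.
#' @param path output file.
#' @param meta optional named list written to the sidecar.
#' @export
write_split <- function(ids, path, meta = NULL) {
  writeLines(ids, path)
  if (!is.null(meta)) write.dcf(as.data.frame(meta), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) readLines(path, warn = FALSE)
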
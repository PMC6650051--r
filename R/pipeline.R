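#' Run the three-stage prediction pipeline end to end
#'
#' Stage 1 embeds the PPI network (diffusion-state SVD or biased-walk
#' skip-gram); stage 2 trains the deep maxout network on the training
#' proteins' embeddings against their vocabulary annotations and
#' extracts the third-hidden-layer functional representation; stage 3
#' scores the evaluation proteins with the chosen head — per-term
#' calibrated SVMs on the functional representation (`"svm"`), the
#' network's own sigmoid outputs (`"sigmoid"`), SVMs on the raw
#' embedding with no maxout stage (`"raw_svm"`), or the Naive frequency
#' baseline (`"naive"`). The result is evaluated with the term-centric
#' and protein-centric metrics.
#'
#' @param net a [weighted_network()].
#' @param dag an `ontology_dag`.
#' @param ann propagated [propagate_annotations()] matrix.
#' @param vocab a [select_term_vocabulary()] vocabulary.
#' @param train_ids,test_ids disjoint protein id sets; training proteins
#'   must be annotated, test proteins are scored and evaluated.
#' @param embedding `"node2vec"` or `"mashup"`.
#' @param embedding_dim dimension of the raw embedding.
#' @param head classifier head: `"svm"`, `"sigmoid"`, `"raw_svm"` or
#'   `"naive"`.
#' @param dmnn_cfg a [dmnn_config()] (ignored by `raw_svm`/`naive`).
#' @param grid SVM hyperparameter grid (heads using SVMs).
#' @param svm_folds CV folds for the SVM grid search.
#' @param restart_prob,walk_length,walks_per_node,p,q,window,negatives,epochs
#'   embedding-stage parameters (see [rwr_diffusion()],
#'   [node2vec_walks()], [skipgram_embed()]).
#' @param seed master seed; stage seeds are derived from it.
#' @param threshold decision threshold for term-centric metrics.
#' @param out_dir optional directory; when given, the embedding,
#'   representation, predictions and report are written there with
#'   provenance sidecars.
#' @return list with `report` (an `evaluation_report`), `scores`,
#'   `embedding`, `representation` (NULL for `raw_svm`/`naive`),
#'   `model`, `classifiers`, `head`.
#' @export
run_pipeline <- function(net, dag, ann, vocab, train_ids, test_ids,
                         embedding = c("node2vec", "mashup"),
                         embedding_dim = 128,
                         head = c("svm", "sigmoid", "raw_svm", "naive"),
                         dmnn_cfg = dmnn_config(hidden_dim = 64, epochs = 100),
                         grid = svm_grid(), svm_folds = 5,
                         restart_prob = 0.5, walk_length = 10,
                         walks_per_node = 10, p = 1.0, q = 2.0,
                         window = 5, negatives = 5, epochs = 5,
                         seed = 1L, threshold = 0.5, out_dir = NULL) {
  embedding <- match.arg(embedding)
  head <- match.arg(head)
  stopifnot(length(intersect(train_ids, test_ids)) == 0L)
  ann_m <- unclass(ann)
  train_ids <- intersect(train_ids, rownames(ann_m))
  vterms <- intersect(vocab$terms, colnames(ann_m))
  if (length(vterms) == 0L) stop("stage embed: vocabulary shares no terms with annotations")

  if (head == "naive") {
    scores <- naive_baseline(ann_m[train_ids, , drop = FALSE], vocab, test_ids)
    report <- evaluate_report_safe(scores, ann_m, vocab, threshold)
    return(list(report = report, scores = scores, embedding = NULL,
                representation = NULL, model = NULL, classifiers = NULL,
                head = head))
  }

  emb <- tryCatch({
    if (embedding == "mashup") {
      diff <- rwr_diffusion(net, restart_prob = restart_prob)
      mashup_embed(diff, d = embedding_dim, network = net$name)
    } else {
      corpus <- node2vec_walks(net, walk_length = walk_length,
                               walks_per_node = walks_per_node,
                               p = p, q = q, seed = seed)
      skipgram_embed(corpus, d = embedding_dim, window = window,
                     negatives = negatives, epochs = epochs,
                     seed = seed + 1L, network = net$name)
    }
  }, error = function(e) stop("stage embed failed: ", conditionMessage(e)))

  train_ids <- intersect(train_ids, rownames(emb))
  test_ids_emb <- intersect(test_ids, rownames(emb))
  Y <- ann_m[train_ids, vterms, drop = FALSE]

  model <- NULL
  repr_train <- NULL
  repr_test <- NULL
  if (head %in% c("svm", "sigmoid")) {
    model <- tryCatch({
      cfg <- dmnn_cfg
      cfg$seed <- seed + 2L
      m <- build_dmnn(ncol(emb), length(vterms), cfg)
      train_dmnn(m, unclass(emb)[train_ids, , drop = FALSE], Y, cfg)
    }, error = function(e) stop("stage dmnn failed: ", conditionMessage(e)))
    repr_train <- extract_representation(model, emb[train_ids, , drop = FALSE])
    repr_test <- extract_representation(model, emb[test_ids_emb, , drop = FALSE])
  }

  classifiers <- NULL
  scores <- withCallingHandlers({
    if (head == "sigmoid") {
      P <- predict_sigmoid(model, emb[test_ids_emb, , drop = FALSE])
      colnames(P) <- vterms
      score_matrix(unclass(P), terms = vterms, method = "dmnn_sigmoid")
    } else {
      feat_train <- if (head == "svm") repr_train else emb[train_ids, , drop = FALSE]
      feat_test <- if (head == "svm") repr_test else emb[test_ids_emb, , drop = FALSE]
      classifiers <- train_term_svms(feat_train, ann, vocab, dag, grid = grid,
                                     folds = svm_folds, seed = seed + 3L)
      predict_posteriors(classifiers, feat_test, vocab)
    }
  }, error = function(e) message("stage classify failed"))

  report <- evaluate_report_safe(scores, ann_m, vocab, threshold)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_embedding(emb, file.path(out_dir, "embedding.tsv"))
    if (!is.null(repr_test)) {
      write_embedding(repr_test, file.path(out_dir, "representation.tsv"))
    }
    write_predictions(scores, file.path(out_dir, "predictions.tsv"))
    write_evaluation_report(report, file.path(out_dir, "report.tsv"))
    write.dcf(data.frame(head = head, embedding = embedding,
                         embedding_dim = embedding_dim, seed = seed),
              file.path(out_dir, "run.meta"))
  }

  list(report = report, scores = scores, embedding = emb,
       representation = repr_test, model = model, classifiers = classifiers,
       head = head)
}

# evaluate against the truth restricted to vocabulary terms; proteins
# missing from the score matrix (e.g. absent from the network) are
# dropped from the evaluation with a warning.
evaluate_report_safe <- function(scores, ann_m, vocab, threshold) {
  vterms <- intersect(vocab$terms, colnames(ann_m))
  truth <- ann_m[, vterms, drop = FALSE]
  common <- intersect(rownames(scores), rownames(truth))
  has_truth <- common[rowSums(truth[common, , drop = FALSE]) > 0]
  if (length(has_truth) < length(rownames(scores))) {
    warning(length(rownames(scores)) - length(has_truth),
            " scored protein(s) without vocabulary truth dropped from evaluation")
  }
  evaluate_predictions(score_matrix(unclass(scores)[has_truth, , drop = FALSE],
                                    terms = colnames(scores),
                                    method = attr(scores, "method") %||% "unknown"),
                       truth[has_truth, , drop = FALSE],
                       threshold = threshold)
}

#' Compare evaluation reports across methods
#'
#' Aligns per-term F1 vectors over the shared vocabulary, tabulates the
#' median metrics side by side and runs the paired significance tests
#' (Wilcoxon signed-rank for two methods, Friedman with Holm-corrected
#' pairwise comparisons for more).
#'
#' @param ... two or more named `evaluation_report` objects.
#' @param metric per-term column used for the significance tests.
#' @return list with `summary` (data frame of medians and Fmax per
#'   method), `per_term` (term x method matrix of `metric`), `tests`
#'   (a [paired_tests()] report).
#' @export
compare_runs <- function(..., metric = "f1") {
  reports <- list(...)
  if (length(reports) < 2L) stop("need at least two reports")
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- vapply(reports, function(r) r$method, "")
  }
  term_sets <- lapply(reports, function(r) r$per_term$term)
  shared <- Reduce(intersect, term_sets)
  if (length(shared) == 0L) stop("reports share no vocabulary terms")
  if (any(lengths(term_sets) != length(shared))) {
    stop("reports disagree on the term vocabulary")
  }
  M <- vapply(reports, function(r) {
    r$per_term[[metric]][match(shared, r$per_term$term)]
  }, numeric(length(shared)))
  rownames(M) <- shared
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, median_f1 = r$median_f1, median_mcc = r$median_mcc,
               median_auprc = r$median_auprc, fmax = r$fmax,
               tau_star = r$tau_star)
  }))
  keep <- stats::complete.cases(M)
  list(summary = summary, per_term = M,
       tests = paired_tests(M[keep, , drop = FALSE]))
}
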
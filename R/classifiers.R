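#' Default hyperparameter grid for the per-term SVMs
#'
#' Log-spaced RBF grid; ties during selection break toward the smaller
#' `C`, then the smaller `gamma` (the simpler model).
#'
#' @param cost values of the soft-margin cost C.
#' @param gamma values of the RBF kernel width.
#' @return data frame of all (C, gamma) combinations.
#' @export
svm_grid <- function(cost = 2^seq(-5, 9, by = 2), gamma = 2^seq(-11, 3, by = 2)) {
  expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
}

scale_features <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$mu), 2, scaling$sd, "/")
}

# stratified fold assignment: positives and negatives are split into
# folds separately so every fold sees (close to) the class ratio.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

# Platt's sigmoid calibration: fit P(y=1|f) = 1/(1+exp(A f + B)) on
# decision values by minimizing cross-entropy against the
# prior-smoothed targets (N+ + 1)/(N+ + 2) and 1/(N- + 2).
platt_fit <- function(decision, y) {
  n_pos <- sum(y); n_neg <- sum(!y)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  target <- ifelse(y, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * decision + par[2]
    p <- 1 / (1 + exp(z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(target * log(p) + (1 - target) * log(1 - p))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS")
  list(A = fit$par[1], B = fit$par[2])
}

platt_apply <- function(calib, decision) {
  1 / (1 + exp(calib$A * decision + calib$B))
}

# decision values from an e1071 svm, oriented so that larger means more
# likely positive
svm_decision <- function(fit, X) {
  dv_att <- attr(stats::predict(fit, X, decision.values = TRUE),
                 "decision.values")
  dv <- dv_att[, 1]
  # e1071 reports "first/second": positive sign means the first class label
  if (startsWith(colnames(dv_att)[1], "FALSE")) dv <- -dv
  dv
}

#' Train one calibrated RBF SVM per vocabulary term
#'
#' For each term *t* in the vocabulary the positive set consists of the
#' training proteins annotated with *t* or any is_a descendant of *t*;
#' all remaining training proteins are negatives. Hyperparameters (C,
#' gamma) are chosen by grid search maximizing the mean F1 over
#' stratified k-fold cross-validation (ties toward smaller C, then
#' smaller gamma). Platt scaling is then fitted on the out-of-fold
#' decision values of the winning configuration, and the final SVM is
#' refitted on the full training set.
#'
#' Terms with fewer positives than folds are trained with a reduced fold
#' count (minimum 2) with a warning; terms with no positives (or no
#' negatives) are skipped with a warning.
#'
#' @param X [embedding_matrix()] or functional representation; rows must
#'   cover all annotated training proteins.
#' @param ann propagated [propagate_annotations()] matrix.
#' @param vocab a [select_term_vocabulary()] vocabulary.
#' @param dag the `ontology_dag` (for the descendant-aware positive
#'   rule).
#' @param grid data frame of candidate (cost, gamma) rows; see
#'   [svm_grid()].
#' @param folds CV folds for the grid search.
#' @param seed seed for the fold assignment.
#' @return list of `term_classifier` objects (one per trained term),
#'   each holding the fitted SVM, the Platt calibration, the selected
#'   hyperparameters and the CV F1 achieved.
#' @export
train_term_svms <- function(X, ann, vocab, dag, grid = svm_grid(),
                            folds = 10, seed = 1L) {
  stopifnot(inherits(vocab, "term_vocabulary"), inherits(dag, "ontology_dag"))
  X <- unclass(X); ann <- unclass(ann)
  proteins <- intersect(rownames(X), rownames(ann))
  if (length(proteins) == 0L) stop("X covers none of the annotated proteins")
  Xt <- X[proteins, , drop = FALSE]
  # standardize features once over the training set (RBF kernels need
  # comparable scales); constant dimensions pass through unchanged
  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scaling <- list(mu = mu, sd = sdv)
  Xt <- scale_features(Xt, scaling)
  # iterate in (cost, gamma) lexicographic order so the strict-improvement
  # rule breaks ties toward the smallest C, then the smallest gamma
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  out <- list()
  set.seed(seed)
  for (term in vocab$terms) {
    fam <- intersect(c(term, term_descendants(dag, term)), colnames(ann))
    y <- rowSums(ann[proteins, fam, drop = FALSE]) > 0
    n_pos <- sum(y)
    if (n_pos == 0L || n_pos == length(y)) {
      warning("term ", term, " skipped: needs both positives and negatives")
      next
    }
    k <- folds
    if (n_pos < folds || sum(!y) < folds) {
      k <- max(2L, min(n_pos, sum(!y)))
      warning("term ", term, ": only ", n_pos, " positives; using ", k, " folds")
    }
    fold_id <- stratified_folds(y, k)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      f1s <- numeric(k)
      dv_oof <- numeric(length(y))
      ok <- TRUE
      for (f in seq_len(k)) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
        fit <- e1071::svm(Xt[tr, , drop = FALSE], factor(y[tr], c(TRUE, FALSE)),
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        dv <- svm_decision(fit, Xt[!tr, , drop = FALSE])
        dv_oof[!tr] <- dv
        cm <- confusion_counts(dv > 0, y[!tr])
        f1s[f] <- confusion_metrics(cm)$f1
      }
      if (!ok) next
      mean_f1 <- mean(f1s)
      if (is.null(best) || mean_f1 > best$f1 + 1e-12) {
        best <- list(cost = grid$cost[g], gamma = grid$gamma[g],
                     f1 = mean_f1, dv_oof = dv_oof)
      }
    }
    if (is.null(best)) {
      warning("term ", term, " skipped: no valid CV configuration")
      next
    }
    calib <- platt_fit(best$dv_oof, y)
    fit <- e1071::svm(Xt, factor(y, c(TRUE, FALSE)), kernel = "radial",
                      cost = best$cost, gamma = best$gamma, scale = FALSE)
    out[[term]] <- structure(
      list(term = term, fit = fit, calibration = calib, scaling = scaling,
           cost = best$cost, gamma = best$gamma, cv_f1 = best$f1,
           n_positive = n_pos),
      class = "term_classifier")
  }
  out
}

#' Posterior probabilities from a library of term classifiers
#'
#' @param classifiers list of `term_classifier` objects from
#'   [train_term_svms()].
#' @param X matrix of representations with the training dimensionality.
#' @param vocab optional [select_term_vocabulary()]; terms in the
#'   vocabulary without a trained classifier get all-zero scores.
#' @return a [score_matrix()] of Platt-calibrated posteriors.
#' @export
predict_posteriors <- function(classifiers, X, vocab = NULL) {
  X <- unclass(X)
  terms <- if (is.null(vocab)) names(classifiers) else vocab$terms
  S <- matrix(0, nrow(X), length(terms),
              dimnames = list(rownames(X), terms))
  for (term in names(classifiers)) {
    cl <- classifiers[[term]]
    if (ncol(X) != ncol(cl$fit$SV)) stop("representation dimension mismatch")
    dv <- svm_decision(cl$fit, scale_features(X, cl$scaling))
    S[, term] <- pmin(pmax(platt_apply(cl$calibration, dv), 0), 1)
  }
  score_matrix(S, terms = terms, method = "svm")
}

#' Naive annotation-frequency baseline
#'
#' Every test protein receives, for term *t*, the relative frequency of
#' *t* among the training proteins — the database prior with no
#' protein-specific signal (all rows identical).
#'
#' @param train_ann propagated training annotation matrix.
#' @param vocab a [select_term_vocabulary()] vocabulary.
#' @param test_proteins character vector of proteins to score.
#' @return a [score_matrix()].
#' @export
naive_baseline <- function(train_ann, vocab, test_proteins) {
  train_ann <- unclass(train_ann)
  if (nrow(train_ann) == 0L) stop("empty training annotation matrix")
  freq <- vapply(vocab$terms, function(t) {
    if (t %in% colnames(train_ann)) mean(train_ann[, t]) else 0
  }, numeric(1))
  S <- matrix(freq, length(test_proteins), length(vocab$terms), byrow = TRUE,
              dimnames = list(test_proteins, vocab$terms))
  score_matrix(S, terms = vocab$terms, method = "naive")
}

#' PPI-homolog annotation-transfer baseline
#'
#' For a target protein *p*, collect the homolog set H(p): all annotated
#' training proteins homologous (E-value at or below the threshold) to
#' at least one PPI partner of *p*. The score for term *t* is the
#' fraction of H(p) annotated with *t*; proteins with an empty homolog
#' set (including proteins absent from the network) score 0 everywhere.
#'
#' @param net a [weighted_network()].
#' @param train_ann propagated training annotation matrix.
#' @param homology a [homology_oracle()].
#' @param vocab a [select_term_vocabulary()] vocabulary.
#' @param test_proteins proteins to score.
#' @param evalue_threshold homology E-value cutoff.
#' @return a [score_matrix()].
#' @export
ppi_homolog_baseline <- function(net, train_ann, homology, vocab,
                                 test_proteins, evalue_threshold = 1e-2) {
  stopifnot(inherits(net, "weighted_network"))
  train_ann <- unclass(train_ann)
  partners <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]
    partners[[a]] <- c(partners[[a]], b)
    partners[[b]] <- c(partners[[b]], a)
  }
  S <- matrix(0, length(test_proteins), length(vocab$terms),
              dimnames = list(test_proteins, vocab$terms))
  vterms <- intersect(vocab$terms, colnames(train_ann))
  for (p in test_proteins) {
    prt <- partners[[p]]
    if (is.null(prt)) next
    H <- unique(unlist(lapply(prt, function(x) {
      homology_hits(homology, x, evalue_threshold)
    }), use.names = FALSE))
    H <- intersect(H, rownames(train_ann))
    if (length(H) == 0L) next
    S[p, vterms] <- colSums(train_ann[H, vterms, drop = FALSE]) / length(H)
  }
  score_matrix(S, terms = vocab$terms, method = "ppi_homolog")
}

#' Write predictions in CAFA-style TSV
#'
#' One row per (protein, term) with the score to three decimals; zero
#' scores are omitted.
#'
#' @param scores a [score_matrix()].
#' @param path output file.
#' @export
write_predictions <- function(scores, path) {
  idx <- which(unclass(scores) > 0, arr.ind = TRUE)
  df <- data.frame(protein = rownames(scores)[idx[, 1]],
                   term = colnames(scores)[idx[, 2]],
                   score = sprintf("%.3f", scores[idx]))
  df <- df[order(df$protein, df$term), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
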
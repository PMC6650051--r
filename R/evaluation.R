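#' Score matrix container
#'
#' Protein x term matrix of posterior probabilities in \[0, 1\] with a
#' method tag; the common currency between all prediction heads and the
#' evaluation metrics.
#'
#' @param scores numeric matrix with rownames = protein ids.
#' @param terms term ids (column names).
#' @param method provenance tag.
#' @return the matrix with class `score_matrix`.
#' @export
score_matrix <- function(scores, terms = colnames(scores), method = "unknown") {
  stopifnot(is.matrix(scores))
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  colnames(scores) <- terms
  structure(scores, method = method, class = c("score_matrix", "matrix", "array"))
}

#' Confusion counts from binary predictions and truth
#'
#' @param predicted logical (or 0/1) vector of predictions.
#' @param truth logical (or 0/1) vector of true labels.
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  stopifnot(length(predicted) == length(truth))
  list(tp = sum(predicted & truth), fp = sum(predicted & !truth),
       fn = sum(!predicted & truth), tn = sum(!predicted & !truth))
}

#' Precision, recall, F1 and MCC from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 their harmonic mean,
#' and MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any
#' zero denominator yields 0 for that metric, the convention under which
#' a degenerate always-negative classifier scores 0 rather than NA.
#'
#' @param c list with nonnegative counts `tp`, `fp`, `fn`, `tn`.
#' @return list with `precision`, `recall`, `f1`, `mcc`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(all(c(c$tp, c$fp, c$fn, c$tn) >= 0))
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(c$tp, c$tp + c$fp)
  recall <- safe_div(c$tp, c$tp + c$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  den <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  mcc <- if (den == 0) 0 else (c$tp * c$tn - c$fp * c$fn) / sqrt(den)
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area over the descending-score threshold sweep:
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}, with tied scores treated as a
#' single threshold (no linear interpolation).
#'
#' @param scores numeric score vector.
#' @param labels binary truth vector of the same length.
#' @return area in \[0, 1\]; `NA` (with a warning) when there are no
#'   positive labels.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) {
    warning("AUPRC undefined without positive labels; returning NA")
    return(NA_real_)
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  r_prev <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1L)
    p <- tp / sum(pred)
    r <- tp / n_pos
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

# averaged precision/recall/F at a single threshold (CAFA protocol):
# precision averaged over the m proteins with a nonempty predicted set,
# recall averaged over all n proteins.
protein_centric_at_tau <- function(scores, truth, tau) {
  pred <- scores >= tau
  n <- nrow(scores)
  npred <- rowSums(pred)
  has_pred <- npred > 0
  m <- sum(has_pred)
  tp <- rowSums(pred & truth == 1)
  recall_bar <- sum(tp / rowSums(truth == 1)) / n
  if (m == 0) {
    return(list(precision = 0, recall = recall_bar, f = 0, m = 0))
  }
  precision_bar <- sum((tp / pmax(npred, 1))[has_pred]) / m
  f <- if (precision_bar + recall_bar == 0) 0 else
    2 * precision_bar * recall_bar / (precision_bar + recall_bar)
  list(precision = precision_bar, recall = recall_bar, f = f, m = m)
}

#' Protein-centric Fmax over a threshold grid
#'
#' Sweeps the decision threshold tau over `grid`; at each tau the
#' per-protein precision over the predicted set \{t : score >= tau\} is
#' averaged over the m proteins with at least one prediction at or above
#' tau, the per-protein recall is averaged over all n proteins, and F is
#' their harmonic mean. Fmax is the maximum F over the grid and tau* the
#' largest threshold attaining it (the most conservative maximizing
#' prediction set). Thresholds with an empty prediction set everywhere
#' are skipped.
#'
#' @param scores a [score_matrix()].
#' @param truth binary annotation matrix aligned on the same proteins and
#'   terms; every evaluated protein must have at least one true term.
#' @param grid threshold grid (CAFA convention 0.01..1.00 step 0.01).
#' @return list with `fmax`, `tau_star` and `curve` (data frame tau /
#'   precision / recall / f / m).
#' @export
fmax <- function(scores, truth, grid = seq(0.01, 1, by = 0.01)) {
  if (length(grid) == 0) stop("empty threshold grid")
  aligned <- align_matrices(scores, truth)
  scores <- aligned$scores; truth <- aligned$truth
  if (any(rowSums(truth == 1) == 0)) {
    stop("every evaluated protein needs at least one true term")
  }
  rows <- lapply(grid, function(tau) {
    pc <- protein_centric_at_tau(scores, truth, tau)
    data.frame(tau = tau, precision = pc$precision, recall = pc$recall,
               f = pc$f, m = pc$m)
  })
  curve <- do.call(rbind, rows)
  usable <- curve[curve$m > 0, , drop = FALSE]
  if (nrow(usable) == 0L) {
    return(list(fmax = 0, tau_star = NA_real_, curve = curve))
  }
  best <- max(usable$f)
  tau_star <- max(usable$tau[usable$f == best])
  list(fmax = best, tau_star = tau_star, curve = curve)
}

#' Protein-centric F at a fixed threshold
#'
#' Same averaged-precision/recall protocol as [fmax()] but evaluated at a
#' single carried-over threshold (e.g. the tau* selected on a hold-out
#' set, applied to a temporal validation set).
#'
#' @inheritParams fmax
#' @param tau threshold in (0, 1\].
#' @return the F value; 0 with a warning when no protein has any
#'   prediction at or above `tau`.
#' @export
f_tau <- function(scores, truth, tau) {
  stopifnot(tau > 0, tau <= 1)
  aligned <- align_matrices(scores, truth)
  pc <- protein_centric_at_tau(aligned$scores, aligned$truth, tau)
  if (pc$m == 0) {
    warning("no protein has a prediction at or above tau = ", tau)
    return(0)
  }
  pc$f
}

align_matrices <- function(scores, truth) {
  scores <- unclass(scores); truth <- unclass(truth)
  if (!is.null(rownames(scores)) && !is.null(rownames(truth))) {
    common <- intersect(rownames(scores), rownames(truth))
    if (length(common) == 0L) stop("score and truth matrices share no proteins")
    scores <- scores[common, , drop = FALSE]
    truth <- truth[common, , drop = FALSE]
  }
  if (!is.null(colnames(scores)) && !is.null(colnames(truth))) {
    common_t <- intersect(colnames(scores), colnames(truth))
    if (length(common_t) == 0L) stop("score and truth matrices share no terms")
    scores <- scores[, common_t, drop = FALSE]
    truth <- truth[, common_t, drop = FALSE]
  }
  if (!all(dim(scores) == dim(truth))) stop("score/truth matrices are not aligned")
  list(scores = scores, truth = truth)
}

# lower median: the 50th percentile taken as an element of the vector
# (for even lengths, the lower of the two central order statistics).
lower_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Term-centric and protein-centric evaluation report
#'
#' Per term: F1 and MCC at decision threshold `threshold` plus AUPRC;
#' terms without hold-out positives get NA metrics and are excluded from
#' the medians with a warning. Protein-centric: Fmax and tau*. Medians
#' are lower medians, matching the two-decimal reporting granularity of
#' the selection protocol.
#'
#' @param scores a [score_matrix()].
#' @param truth binary annotation matrix.
#' @param threshold decision threshold for term-centric binary calls.
#' @param grid threshold grid for [fmax()].
#' @return object of class `evaluation_report`: list with `per_term`
#'   (data frame term/f1/mcc/auprc), `median_f1`, `median_mcc`,
#'   `median_auprc`, `fmax`, `tau_star`, `curve`, `method`.
#' @export
evaluate_predictions <- function(scores, truth, threshold = 0.5,
                                 grid = seq(0.01, 1, by = 0.01)) {
  method <- attr(scores, "method") %||% "unknown"
  aligned <- align_matrices(scores, truth)
  s <- aligned$scores; y <- aligned$truth
  per_term <- do.call(rbind, lapply(colnames(s), function(t) {
    if (sum(y[, t]) == 0) {
      return(data.frame(term = t, f1 = NA_real_, mcc = NA_real_,
                        auprc = NA_real_))
    }
    cm <- confusion_metrics(confusion_counts(s[, t] >= threshold, y[, t] == 1))
    data.frame(term = t, f1 = cm$f1, mcc = cm$mcc,
               auprc = suppressWarnings(auprc(s[, t], y[, t])))
  }))
  if (anyNA(per_term$f1)) {
    warning(sum(is.na(per_term$f1)),
            " term(s) without positives excluded from medians")
  }
  keep <- rowSums(y == 1) > 0
  fm <- fmax(s[keep, , drop = FALSE], y[keep, , drop = FALSE], grid = grid)
  structure(list(per_term = per_term,
                 median_f1 = lower_median(per_term$f1),
                 median_mcc = lower_median(per_term$mcc),
                 median_auprc = lower_median(per_term$auprc),
                 fmax = fm$fmax, tau_star = fm$tau_star, curve = fm$curve,
                 method = method),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report '%s': %d terms>\n", x$method, nrow(x$per_term)))
  cat(sprintf("  median F1    %.3f\n  median MCC   %.3f\n  median AUPRC %.3f\n",
              x$median_f1, x$median_mcc, x$median_auprc))
  cat(sprintf("  Fmax %.3f at tau* = %.2f\n", x$fmax, x$tau_star))
  invisible(x)
}

#' Class-centroid separation of a representation, per term
#'
#' Min-max standardizes every representation dimension to \[0, 1\] over
#' the analyzed proteins (constant dimensions map to 0 with a warning),
#' computes the Euclidean distance between the positive-class and
#' negative-class centroids for each term, and correlates those
#' distances with the per-term F1 scores. A positive correlation
#' indicates that terms whose two classes are farther apart in the
#' representation space are also predicted more accurately.
#'
#' @param X an [embedding_matrix()] (or plain matrix).
#' @param labels binary protein x term matrix over the same proteins.
#' @param f1_per_term numeric vector of per-term F1 scores, one per
#'   column of `labels`.
#' @return list with `distance` (named per-term centroid distances) and
#'   `correlation` (Pearson correlation with `f1_per_term`).
#' @export
centroid_distance_analysis <- function(X, labels, f1_per_term) {
  X <- unclass(X); labels <- unclass(labels)
  stopifnot(nrow(X) == nrow(labels), ncol(labels) == length(f1_per_term))
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) warning(sum(span == 0), " constant dimension(s) standardized to 0")
  Xs <- sweep(X, 2, rng[1, ])
  Xs <- sweep(Xs, 2, ifelse(span == 0, 1, span), "/")
  Xs[, span == 0] <- 0
  dist_t <- vapply(seq_len(ncol(labels)), function(t) {
    pos <- labels[, t] == 1
    if (!any(pos) || all(pos)) stop("both classes must be nonempty for every term")
    sqrt(sum((colMeans(Xs[pos, , drop = FALSE]) -
                colMeans(Xs[!pos, , drop = FALSE]))^2))
  }, numeric(1))
  names(dist_t) <- colnames(labels)
  correlation <- if (length(dist_t) < 2 || stats::sd(dist_t) == 0 ||
                     stats::sd(f1_per_term) == 0) NA_real_
    else stats::cor(dist_t, f1_per_term)
  list(distance = dist_t, correlation = correlation)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all sign
# assignments through a generating-function DP over midranks (doubled to
# integers, so ties are handled exactly). Zero differences must already
# be removed.
wilcox_signed_exact <- function(d) {
  r <- rank(abs(d))  # midranks
  w_obs <- sum(r[d > 0])
  ir <- as.integer(round(2 * r))
  total <- sum(ir)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (x in ir) {
    f <- f + c(numeric(x), f[seq_len(total + 1L - x)])
  }
  f <- f / 2^length(ir)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired significance tests between methods' per-term scores
#'
#' Two methods: two-tailed Wilcoxon signed-rank test on the paired
#' per-term scores (zero differences dropped; exact distribution when the
#' number of nonzero differences is at most 25 and there are no ties,
#' normal approximation otherwise). More than two methods: Friedman test
#' over the term x method score matrix, followed by Holm-corrected
#' pairwise Wilcoxon comparisons.
#'
#' @param ... two or more named numeric vectors of per-term scores, all
#'   aligned on the same terms; alternatively a single matrix/data frame
#'   with one column per method.
#' @param alpha significance level for the rejection report.
#' @return list with `method` ("wilcoxon" or "friedman_holm"), `p_value`
#'   (global for Friedman), `pairwise` (data frame a / b / p / p_holm /
#'   reject) and `alpha`.
#' @export
paired_tests <- function(..., alpha = 0.05) {
  args <- list(...)
  if (length(args) == 1L && (is.matrix(args[[1]]) || is.data.frame(args[[1]]))) {
    M <- as.matrix(args[[1]])
  } else {
    if (length(args) < 2L) stop("need at least two methods to compare")
    lens <- lengths(args)
    if (length(unique(lens)) != 1L) stop("score vectors must be aligned (equal length)")
    M <- do.call(cbind, args)
    if (is.null(colnames(M))) colnames(M) <- paste0("method", seq_along(args))
  }
  if (ncol(M) < 2L) stop("need at least two methods to compare")
  wilcox_pair <- function(a, b) {
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0L) return(1.0)
    if (length(d) <= 25) wilcox_signed_exact(d)
    else suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  }
  pairs <- utils::combn(colnames(M), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(a = pr[1], b = pr[2], p = wilcox_pair(M[, pr[1]], M[, pr[2]]))
  }))
  if (ncol(M) == 2L) {
    pw$p_holm <- pw$p
    pw$reject <- pw$p_holm <= alpha
    return(list(method = "wilcoxon", p_value = pw$p[1], pairwise = pw,
                alpha = alpha))
  }
  fr <- stats::friedman.test(M)
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  pw$reject <- pw$p_holm <= alpha
  list(method = "friedman_holm", p_value = fr$p.value, pairwise = pw,
       alpha = alpha)
}

#' Write an evaluation report as TSV
#'
#' Per-term rows plus a trailing summary block (commented lines).
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report$per_term, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_lines <- sprintf(
    "# %s\t%s",
    c("method", "median_f1", "median_mcc", "median_auprc", "fmax", "tau_star"),
    c(report$method, format(c(report$median_f1, report$median_mcc,
                              report$median_auprc, report$fmax,
                              report$tau_star), digits = 6)))
  cat(summary_lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
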
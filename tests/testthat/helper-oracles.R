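# Independent brute-force oracles and fixture builders shared by the
# unit and acceptance tests. Oracles re-derive each quantity from its
# defining formula with a code path disjoint from the package's.

# literal confusion-metric formulas, zero-denominator -> 0
bf_confusion <- function(tp, fp, fn, tn) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  p <- div0(tp, tp + fp)
  r <- div0(tp, tp + fn)
  f1 <- div0(2 * p * r, p + r)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(precision = p, recall = r, f1 = f1, mcc = mcc)
}

# AUPRC by explicit threshold enumeration over the sorted unique scores
bf_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(ths, function(th) {
    tp <- sum(labels == 1 & scores >= th)
    c(p = tp / sum(scores >= th), r = tp / sum(labels == 1))
  }, c(p = 0, r = 0)))
  sum(diff(c(0, pts[, "r"])) * pts[, "p"])
}

# protein-centric averaged F at one threshold, written as literal loops
bf_f_at_tau <- function(S, Y, tau) {
  n <- nrow(S)
  m <- 0; psum <- 0; rsum <- 0
  for (s in seq_len(n)) {
    pred <- which(S[s, ] >= tau)
    truth <- which(Y[s, ] == 1)
    tp <- length(intersect(pred, truth))
    if (length(pred) > 0) {
      m <- m + 1
      psum <- psum + tp / length(pred)
    }
    rsum <- rsum + tp / length(truth)
  }
  if (m == 0) return(list(f = NA_real_, m = 0))
  P <- psum / m
  R <- rsum / n
  list(f = if (P + R == 0) 0 else 2 * P * R / (P + R), m = m)
}

bf_fmax <- function(S, Y, grid = seq(0.01, 1, by = 0.01)) {
  best <- -Inf; tau_star <- NA_real_
  for (tau in grid) {
    r <- bf_f_at_tau(S, Y, tau)
    if (r$m == 0) next
    if (r$f >= best) {
      best <- r$f
      tau_star <- tau
    }
  }
  list(fmax = best, tau_star = tau_star)
}

# is there an upward is_a path a ~> b (b a strict ancestor of a)?
bf_reachable <- function(dag, a, b) {
  frontier <- dag$parents[[a]]
  seen <- character(0)
  while (length(frontier) > 0) {
    if (b %in% frontier) return(TRUE)
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

# brute-force deepest-term filter: drop any candidate with a candidate
# strict descendant (pairwise reachability in the child -> parent DAG:
# d is a descendant of t iff t is reachable from d going upward)
bf_deepest <- function(dag, candidates) {
  keep <- vapply(candidates, function(t) {
    !any(vapply(setdiff(candidates, t), function(d) bf_reachable(dag, d, t),
                logical(1)))
  }, logical(1))
  sort(candidates[keep])
}

# random DAG over n terms: term i may pick parents among terms < i
random_dag <- function(n, p_edge = 0.25) {
  ids <- sprintf("T:%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    ps <- ids[seq_len(i - 1)][stats::runif(i - 1) < p_edge]
    if (length(ps) == 0) ps <- ids[sample.int(i - 1, 1)]
    parents[[ids[i]]] <- ps
  }
  structure(list(terms = ids, parents = parents,
                 name = stats::setNames(ids, ids),
                 namespace = stats::setNames(rep("biological_process", n), ids)),
            class = "ontology_dag")
}

# tiny ontology_dag built straight from a child -> parents list
toy_dag <- function(parents) {
  ids <- names(parents)
  structure(list(terms = ids, parents = parents,
                 name = stats::setNames(ids, ids),
                 namespace = stats::setNames(rep("biological_process",
                                                 length(ids)), ids)),
            class = "ontology_dag")
}

toy_vocab <- function(terms) {
  structure(list(terms = terms, min_count = 1), class = "term_vocabulary")
}

# random score/truth instance where every protein has >= 1 true term
random_instance <- function(n_prot, n_term) {
  S <- matrix(round(stats::runif(n_prot * n_term), 2), n_prot, n_term,
              dimnames = list(sprintf("p%02d", seq_len(n_prot)),
                              sprintf("t%02d", seq_len(n_term))))
  Y <- matrix(stats::rbinom(n_prot * n_term, 1, 0.4), n_prot, n_term,
              dimnames = dimnames(S))
  empty <- rowSums(Y) == 0
  Y[cbind(which(empty), sample.int(n_term, sum(empty), replace = TRUE))] <- 1L
  list(S = S, Y = Y)
}

write_obo <- function(stanzas) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", stanzas), f)
  f
}

obo_term <- function(id, is_a = character(0), obsolete = FALSE,
                     namespace = "biological_process") {
  c("[Term]", paste0("id: ", id), paste0("name: ", id),
    paste0("namespace: ", namespace),
    paste0("is_a: ", is_a, " ! parent"),
    if (obsolete) "is_obsolete: true", "")
}
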
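#' Specification of the synthetic guilt-by-association testbed
#'
#' Defines a desk-scale data-generating process with the structure the
#' method assumes: proteins fall into communities (planted-partition
#' network), each community carries a handful of leaf terms in a toy
#' ontology, and community members receive their community's terms with
#' high probability (plus background noise) — interacting proteins tend
#' to share function.
#'
#' @param n_proteins number of proteins.
#' @param k_communities number of planted communities.
#' @param p_in,p_out within/between-community edge probabilities.
#' @param weight_noise standard deviation of the edge-weight jitter
#'   around 0.8 (within) and 0.3 (between); weights are clipped to
#'   \[0.01, 1\].
#' @param terms_per_community leaf terms carried by each community.
#' @param annotation_tpr probability a community member is annotated
#'   with each of its community's leaves.
#' @param annotation_fpr background probability of receiving a foreign
#'   community's leaf.
#' @param dag_depth number of is_a links from a leaf up to the root.
#' @param seed integer seed.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 300, k_communities = 3,
                           p_in = 0.3, p_out = 0.02, weight_noise = 0.05,
                           terms_per_community = 3, annotation_tpr = 0.9,
                           annotation_fpr = 0.05, dag_depth = 2, seed = 0L) {
  stopifnot(p_out >= 0, p_in >= p_out, p_in <= 1,
            annotation_tpr >= 0, annotation_tpr <= 1,
            annotation_fpr >= 0, annotation_fpr <= 1,
            n_proteins >= k_communities, dag_depth >= 1,
            terms_per_community >= 1, weight_noise >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 k_communities = as.integer(k_communities),
                 p_in = p_in, p_out = p_out, weight_noise = weight_noise,
                 terms_per_community = as.integer(terms_per_community),
                 annotation_tpr = annotation_tpr,
                 annotation_fpr = annotation_fpr,
                 dag_depth = as.integer(dag_depth), seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Community assignment used by the generator
#'
#' Contiguous blocks of (near-)equal size, fully determined by the
#' generator settings.
#'
#' @param spec a [synthetic_spec()].
#' @return named integer vector protein id -> community (1..k).
#' @export
community_assignment <- function(spec) {
  ids <- synthetic_ids(spec$n_proteins)
  stats::setNames(sort(rep_len(seq_len(spec$k_communities), spec$n_proteins)),
                  ids)
}

#' Simulate a planted-partition weighted PPI network
#'
#' Edges appear independently with probability `p_in` inside a community
#' and `p_out` between communities. Within-community weights jitter
#' around 0.8 and between-community weights around 0.3 (clipped to
#' \[0.01, 1\]), mimicking confidence scores that are higher for
#' functionally coherent interactions.
#'
#' @param spec a [synthetic_spec()].
#' @return a [weighted_network()]; the community assignment is attached
#'   as attribute `"communities"`.
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ids <- synthetic_ids(spec$n_proteins)
  comm <- community_assignment(spec)
  pairs <- utils::combn(spec$n_proteins, 2)
  same <- comm[pairs[1, ]] == comm[pairs[2, ]]
  prob <- ifelse(same, spec$p_in, spec$p_out)
  present <- stats::runif(ncol(pairs)) < prob
  base <- ifelse(same[present], 0.8, 0.3)
  w <- pmin(1, pmax(0.01, base + stats::rnorm(sum(present), 0, spec$weight_noise)))
  net <- suppressMessages(weighted_network(
    data.frame(from = ids[pairs[1, present]], to = ids[pairs[2, present]],
               weight = w, stringsAsFactors = FALSE),
    nodes = ids, name = "synthetic"))
  attr(net, "communities") <- comm
  net
}

#' Simulate a toy ontology and community-correlated annotations
#'
#' Builds a toy DAG (one root; per community a chain of `dag_depth - 1`
#' internal terms; `terms_per_community` leaves under each community
#' branch) and samples experimental annotations: each protein receives
#' each leaf of its own community with probability `annotation_tpr` and
#' each foreign leaf with probability `annotation_fpr`. The returned
#' matrix is is_a-propagated.
#'
#' @param spec a [synthetic_spec()].
#' @param communities named community assignment covering all proteins
#'   (defaults to the generator's own assignment).
#' @return list with `dag` (an `ontology_dag`), `ann` (propagated
#'   [propagate_annotations()] matrix; zero rows if no protein was
#'   annotated), `leaves` (character vector of leaf term ids) and `raw`
#'   (the raw annotation tuples).
#' @export
simulate_ontology_annotations <- function(spec,
                                          communities = community_assignment(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$k_communities
  root <- "T:0000"
  terms <- root
  parents <- list()
  parents[[root]] <- character(0)
  leaves <- character(0)
  leaf_comm <- integer(0)
  for (c in seq_len(k)) {
    chain <- root
    if (spec$dag_depth > 1) {
      for (dpt in seq_len(spec$dag_depth - 1L)) {
        id <- sprintf("T:%d%03d", c, dpt)
        parents[[id]] <- chain[length(chain)]
        terms <- c(terms, id)
        chain <- c(chain, id)
      }
    }
    for (s in seq_len(spec$terms_per_community)) {
      id <- sprintf("T:%dL%02d", c, s)
      parents[[id]] <- chain[length(chain)]
      terms <- c(terms, id)
      leaves <- c(leaves, id)
      leaf_comm <- c(leaf_comm, c)
    }
  }
  dag <- structure(list(terms = terms, parents = parents,
                        name = stats::setNames(terms, terms),
                        namespace = stats::setNames(rep("biological_process",
                                                        length(terms)), terms)),
                   class = "ontology_dag")
  set.seed(spec$seed + 1L)
  ids <- names(communities)
  prob <- matrix(spec$annotation_fpr, length(ids), length(leaves))
  for (j in seq_along(leaves)) {
    prob[communities == leaf_comm[j], j] <- spec$annotation_tpr
  }
  hit <- matrix(stats::runif(length(prob)), nrow(prob)) < prob
  idx <- which(hit, arr.ind = TRUE)
  raw <- data.frame(protein = ids[idx[, 1]], term = leaves[idx[, 2]],
                    evidence = rep("EXP", nrow(idx)), stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("no protein received any annotation; empty matrix")
    ann <- structure(matrix(0L, 0, 0), evidence = "EXP",
                     class = c("annotation_matrix", "matrix", "array"))
  } else {
    ann <- propagate_annotations(raw, dag)
  }
  list(dag = dag, ann = ann, leaves = leaves, raw = raw)
}

#' Simulate a homology hit table
#'
#' Marks `ceiling(clone_fraction * length(eval_ids))` evaluation
#' proteins as having a training homolog: each selected evaluation
#' protein is paired with one random training protein at an E-value
#' drawn log-uniformly from \[1e-10, 1e-1\].
#'
#' @param eval_ids evaluation protein ids.
#' @param train_ids training protein ids.
#' @param clone_fraction fraction of evaluation proteins given a
#'   homolog.
#' @param seed integer seed.
#' @return data frame with columns `query`, `subject`, `evalue`
#'   (possibly empty), suitable for [homology_oracle()].
#' @export
simulate_homology <- function(eval_ids, train_ids, clone_fraction, seed = 0L) {
  stopifnot(clone_fraction >= 0, clone_fraction <= 1)
  n_hit <- ceiling(clone_fraction * length(eval_ids))
  if (n_hit == 0L) {
    return(data.frame(query = character(0), subject = character(0),
                      evalue = numeric(0)))
  }
  set.seed(seed)
  queries <- sort(sample(eval_ids, n_hit))
  data.frame(query = queries,
             subject = sample(train_ids, n_hit, replace = TRUE),
             evalue = 10^stats::runif(n_hit, -10, -1),
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper: network, toy ontology, propagated annotations
#' and the leaf-term vocabulary (all leaves that annotate at least
#' `min_count` proteins, reduced to the deepest-term antichain).
#'
#' @param spec a [synthetic_spec()].
#' @param min_count vocabulary frequency threshold; the desk-scale
#'   default (10) plays the role the genome-scale 100-protein rule plays
#'   on real corpora.
#' @return list with `net`, `dag`, `ann`, `vocab`, `communities`,
#'   `leaves`.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), min_count = 10) {
  net <- simulate_network(spec)
  oa <- simulate_ontology_annotations(spec, attr(net, "communities"))
  vocab <- select_term_vocabulary(oa$ann, oa$dag, min_count = min_count)
  list(net = net, dag = oa$dag, ann = oa$ann, vocab = vocab,
       communities = attr(net, "communities"), leaves = oa$leaves)
}
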
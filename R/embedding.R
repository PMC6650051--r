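#' Random walk with restart diffusion states
#'
#' For each node *i* the diffusion state \eqn{s_i} solves
#' \deqn{s_i = r e_i + (1 - r) P^T s_i}
#' where `P` is the row-normalized weighted adjacency matrix and `r` the
#' restart probability. Isolated nodes keep all restart mass at home
#' (diffusion state = indicator vector), the limit of the defining
#' equation. Networks with up to `direct_solve_max` nodes are solved
#' exactly as the linear system; larger ones by power iteration to an L1
#' tolerance.
#'
#' @param net a [weighted_network()].
#' @param restart_prob restart probability in (0, 1); 0.5 is the value
#'   that works best for Mashup-style embeddings of STRING networks.
#' @param tol L1 convergence tolerance for power iteration.
#' @param max_iter maximum power iterations before a convergence error.
#' @param direct_solve_max networks at or below this size use a direct
#'   linear solve.
#' @return matrix with rows/cols named by nodes; row *i* is the diffusion
#'   state of node *i* (each row sums to 1).
#' @export
rwr_diffusion <- function(net, restart_prob = 0.5, tol = 1e-8,
                          max_iter = 10000, direct_solve_max = 2000) {
  stopifnot(inherits(net, "weighted_network"),
            restart_prob > 0, restart_prob < 1)
  if (length(net$nodes) == 0L) stop("empty network")
  A <- adjacency_matrix(net)
  if (any(A < 0)) stop("negative edge weight")
  deg <- rowSums(A)
  n <- nrow(A)
  P <- A / ifelse(deg > 0, deg, 1)
  isolated <- deg == 0
  if (any(isolated)) diag(P)[isolated] <- 1  # restart mass stays home
  r <- restart_prob
  if (n <= direct_solve_max) {
    # D[i, ] = s_i^T  with  s_i = r (I - (1-r) P^T)^{-1} e_i
    D <- r * t(solve(diag(n) - (1 - r) * t(P)))
  } else {
    D <- diag(n)
    for (it in seq_len(max_iter)) {
      D_new <- r * diag(n) + (1 - r) * (D %*% P)
      delta <- max(rowSums(abs(D_new - D)))
      D <- D_new
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop(sprintf("RWR power iteration did not converge in %d iterations (residual %.3g)",
                   max_iter, delta))
    }
  }
  dimnames(D) <- list(net$nodes, net$nodes)
  attr(D, "restart_prob") <- r
  D
}

#' Tag a numeric matrix as an embedding
#'
#' @param vectors numeric matrix, one row per protein (rownames are the
#'   protein ids).
#' @param method provenance tag: `"mashup"`, `"node2vec"` or
#'   `"string2go"`.
#' @param network source network name.
#' @return the matrix with class `embedding_matrix` and provenance
#'   attributes `method`, `network`.
#' @export
embedding_matrix <- function(vectors, method, network = "") {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (any(!is.finite(vectors))) stop("embedding contains non-finite values")
  structure(vectors, method = method, network = network,
            class = c("embedding_matrix", "matrix", "array"))
}

#' Mashup-style embedding: truncated SVD of diffusion states
#'
#' The diffusion state matrix is factored by singular value
#' decomposition and the embedding is \eqn{U_d \sqrt{\Sigma_d}}. An
#' optional elementwise log transform `log(s + 1/n)` of the diffusion
#' states is available (off by default).
#'
#' @param diff diffusion matrix from [rwr_diffusion()].
#' @param d embedding dimension; clamped to the number of nodes with a
#'   warning if larger. 800 is the dimension reported to work best on
#'   genome-scale STRING networks.
#' @param log_transform apply `log(s + 1/n)` before the SVD.
#' @param network network name recorded as provenance.
#' @return an [embedding_matrix()] with method `"mashup"`.
#' @export
mashup_embed <- function(diff, d = 800, log_transform = FALSE, network = "") {
  stopifnot(is.matrix(diff))
  if (d <= 0) stop("embedding dimension must be positive")
  n <- nrow(diff)
  if (d > n) {
    warning("d = ", d, " clamped to number of nodes (", n, ")")
    d <- n
  }
  X <- if (log_transform) log(diff + 1 / n) else diff
  s <- svd(X, nu = d, nv = 0)
  # fix sign per component for cross-platform reproducibility
  U <- s$u
  for (j in seq_len(d)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  emb <- U %*% diag(sqrt(s$d[seq_len(d)]), d)
  rownames(emb) <- rownames(diff)
  colnames(emb) <- paste0("dim", seq_len(d))
  embedding_matrix(emb, method = "mashup", network = network)
}

#' Second-order biased random walks (node2vec sampling)
#'
#' Generates `walks_per_node` truncated walks from every node. The first
#' step samples neighbors proportionally to edge weight; subsequent steps
#' from node *v* (having arrived from *t*) reweight each neighbor *x* by
#' `1/p` if `x == t`, `1` if *x* is adjacent to *t*, and `1/q` otherwise,
#' multiplied by the edge weight `w(v, x)`. `q > 1` biases the walk
#' toward the previous node's neighborhood (breadth-first-like, close
#' neighbors).
#'
#' @param net a [weighted_network()].
#' @param walk_length maximum walk length (number of nodes per walk).
#' @param walks_per_node walks started from each node.
#' @param p return parameter.
#' @param q in-out parameter; 2 biases toward close neighbors.
#' @param seed integer seed for reproducible sampling.
#' @return object of class `walk_corpus`: list with `walks` (list of
#'   character vectors), and the sampling parameters.
#' @export
node2vec_walks <- function(net, walk_length = 10, walks_per_node = 10,
                           p = 1.0, q = 2.0, seed = 1L) {
  stopifnot(inherits(net, "weighted_network"), p > 0, q > 0, walk_length >= 1)
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  ei <- idx[net$edges$from]; ej <- idx[net$edges$to]
  for (k in seq_along(ei)) {
    nbr[[ei[k]]] <- c(nbr[[ei[k]]], ej[k]); wts[[ei[k]]] <- c(wts[[ei[k]]], net$edges$weight[k])
    nbr[[ej[k]]] <- c(nbr[[ej[k]]], ei[k]); wts[[ej[k]]] <- c(wts[[ej[k]]], net$edges$weight[k])
  }
  set.seed(seed)
  walks <- vector("list", n * walks_per_node)
  w_i <- 0L
  for (rep in seq_len(walks_per_node)) {
    for (start in seq_len(n)) {
      walk <- integer(walk_length)
      walk[1L] <- start
      len <- 1L
      if (length(nbr[[start]]) > 0L) {
        walk[2L] <- sample_one(nbr[[start]], wts[[start]])
        len <- 2L
        while (len < walk_length) {
          v <- walk[len]; t_prev <- walk[len - 1L]
          nb <- nbr[[v]]
          if (length(nb) == 0L) break
          bias <- node2vec_bias(nb, t_prev, nbr[[t_prev]], p, q)
          walk[len + 1L] <- sample_one(nb, wts[[v]] * bias)
          len <- len + 1L
        }
      }
      w_i <- w_i + 1L
      walks[[w_i]] <- net$nodes[walk[seq_len(len)]]
    }
  }
  structure(list(walks = walks, walk_length = walk_length,
                 walks_per_node = walks_per_node, p = p, q = q, seed = seed,
                 nodes = net$nodes),
            class = "walk_corpus")
}

# second-order bias factors for candidate next nodes `nb`, previous node
# `t_prev` with neighbor set `t_nbr`
node2vec_bias <- function(nb, t_prev, t_nbr, p, q) {
  bias <- rep(1 / q, length(nb))
  bias[nb %in% t_nbr] <- 1
  bias[nb == t_prev] <- 1 / p
  bias
}

sample_one <- function(items, weights) {
  if (length(items) == 1L) return(items)
  items[sample.int(length(items), 1L, prob = weights)]
}

#' Skip-gram embedding of a walk corpus
#'
#' Trains a skip-gram model with negative sampling (single-threaded
#' stochastic gradient descent, unigram^0.75 negative-sampling
#' distribution, linearly decaying learning rate) over the walk corpus
#' and returns one vector per node. Nodes of the source network that
#' never appear in the corpus receive zero vectors with a warning.
#'
#' @param corpus a [node2vec_walks()] corpus.
#' @param d embedding dimension.
#' @param window symmetric context window size.
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param alpha initial learning rate.
#' @param seed integer seed; training is deterministic given the seed.
#' @param network network name recorded as provenance.
#' @return an [embedding_matrix()] with method `"node2vec"`.
#' @export
skipgram_embed <- function(corpus, d = 128, window = 5, negatives = 5,
                           epochs = 5, alpha = 0.025, seed = 1L, network = "") {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (d <= 0) stop("embedding dimension must be positive")
  if (length(corpus$walks) == 0L) stop("empty walk corpus")
  vocab <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  walk_idx <- lapply(corpus$walks, function(w) match(w, vocab))
  counts <- tabulate(unlist(walk_idx, use.names = FALSE), nbins = length(vocab))
  set.seed(seed)
  emb <- skipgram_train_cpp(walk_idx, length(vocab), counts, as.integer(d),
                            as.integer(window), as.integer(negatives),
                            as.integer(epochs), alpha)
  rownames(emb) <- vocab
  all_nodes <- corpus$nodes
  missing <- setdiff(all_nodes, vocab)
  if (length(missing) > 0L) {
    warning(length(missing), " node(s) absent from corpus get zero vectors")
    emb <- rbind(emb, matrix(0, length(missing), d, dimnames = list(missing, NULL)))
  }
  emb <- emb[all_nodes, , drop = FALSE]
  colnames(emb) <- paste0("dim", seq_len(d))
  embedding_matrix(emb, method = "node2vec", network = network)
}

#' Write / read embeddings as TSV with a metadata sidecar
#'
#' Format: protein_id then `d` floats per row (9 significant digits),
#' tab-separated, no header. Provenance (method, network, dimension) goes
#' to `<path>.meta` in DCF form.
#'
#' @param emb an [embedding_matrix()].
#' @param path output TSV path.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  df <- data.frame(id = rownames(emb),
                   signif(unclass(emb), 9),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(method = attr(emb, "method"),
                     network = attr(emb, "network"),
                     d = ncol(emb))
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_embedding
#' @return for `read_embedding`, the [embedding_matrix()].
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- paste0("dim", seq_len(ncol(m)))
  meta_path <- paste0(path, ".meta")
  method <- "unknown"; network <- ""
  if (file.exists(meta_path)) {
    meta <- read.dcf(meta_path)
    method <- unname(meta[1, "method"]); network <- unname(meta[1, "network"])
  }
  embedding_matrix(m, method = method, network = network)
}
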
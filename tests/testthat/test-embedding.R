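random_net <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  e <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(e)) < p
  weighted_network(data.frame(from = e[keep, 1], to = e[keep, 2],
                              weight = stats::runif(sum(keep), 0.1, 1)),
                   nodes = ids)
}

test_that("diffusion states solve the restart equation", {
  # closed form on the two-node graph: s1 = (2/3, 1/3) at restart 0.5
  net <- weighted_network(data.frame(from = "a", to = "b", weight = 0.7))
  D <- rwr_diffusion(net, restart_prob = 0.5)
  expect_equal(unname(D["a", ]), c(2 / 3, 1 / 3), tolerance = 1e-10)

  iso <- weighted_network(data.frame(from = character(0), to = character(0),
                                     weight = numeric(0)), nodes = "solo")
  expect_equal(unname(rwr_diffusion(iso)[1, 1]), 1.0)

  D2 <- rwr_diffusion(random_net(12, seed = 4))
  expect_equal(unname(rowSums(D2)), rep(1, 12), tolerance = 1e-8)
  expect_true(all(D2 >= 0))
  expect_true(all(diag(D2) >= 0.5))
})

test_that("power iteration agrees with the direct linear solve", {
  for (seed in 1:3) {
    net <- random_net(20, p = 0.25, seed = seed)
    direct <- rwr_diffusion(net)
    power <- rwr_diffusion(net, direct_solve_max = 0)
    expect_lt(max(abs(direct - power)), 1e-6)
  }
})

test_that("RWR and SVD embedding are permutation-equivariant", {
  net <- random_net(10, seed = 9)
  D <- rwr_diffusion(net)
  perm <- sample(net$nodes)
  # relabel nodes through a permutation map and recompute
  relabeled <- apply_mapping(net, stats::setNames(perm, net$nodes))
  D2 <- rwr_diffusion(relabeled)
  expect_equal(D2[perm, perm], `dimnames<-`(unclass(D), list(perm, perm)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mashup embedding is a truncated SVD with expected properties", {
  net <- random_net(10, seed = 5)
  D <- rwr_diffusion(net)
  expect_error(mashup_embed(D, d = 0), "positive")
  expect_warning(emb <- mashup_embed(D, d = 50), "clamped")
  expect_equal(ncol(emb), 10)

  # identical diffusion rows give identical embedding rows
  Ddup <- rbind(D, D[1, , drop = FALSE])
  rownames(Ddup) <- c(rownames(D), "copy")
  Ddup <- cbind(Ddup, 0)
  e2 <- mashup_embed(Ddup, d = 4)
  expect_equal(unname(e2["copy", ]), unname(e2[1, ]), tolerance = 1e-10)

  # the embedding Gram is the rank-d truncation of U Sigma U^T, so its
  # reconstruction error is non-increasing in d (Eckart-Young) ...
  sv <- svd(unclass(D))
  target <- sv$u %*% diag(sv$d) %*% t(sv$u)
  err <- vapply(c(2, 4), function(d) {
    E <- mashup_embed(D, d = d)
    norm(target - E %*% t(E), "F")
  }, numeric(1))
  expect_lte(err[2], err[1] + 1e-12)
  expect_equal(err[2], sqrt(sum(sv$d[5:10]^2)), tolerance = 1e-8)

  # ... and vanishes at full rank
  Efull <- mashup_embed(D, d = 10)
  expect_equal(Efull %*% t(Efull), target, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("second-order walk bias matches the enumerated transition law", {
  # triangle a-b-c plus pendant d-c, unit weights, at c having come from
  # b: neighbor weights 1 (a, shared), 1 (b, return), 1/q (d)
  bias <- string2go:::node2vec_bias(nb = c("a", "b", "d"), t_prev = "b",
                                    t_nbr = c("a", "c"), p = 1, q = 2)
  probs <- bias / sum(bias)
  expect_equal(probs, c(0.4, 0.4, 0.2))
  # p modifies only the return step
  bias_p <- string2go:::node2vec_bias(c("a", "b", "d"), "b", c("a", "c"),
                                      p = 4, q = 2)
  expect_equal(bias_p, c(1, 0.25, 0.5))
})

test_that("walks stay on edges, respect length and handle isolated nodes", {
  net <- random_net(12, p = 0.3, seed = 2)
  corpus <- node2vec_walks(net, walk_length = 7, walks_per_node = 3, seed = 5)
  expect_length(corpus$walks, 36)
  adj <- paste(net$edges$from, net$edges$to)
  for (w in corpus$walks) {
    expect_lte(length(w), 7)
    if (length(w) > 1) {
      steps <- paste(pmin(w[-length(w)], w[-1]), pmax(w[-length(w)], w[-1]))
      expect_true(all(steps %in% adj))
    }
  }
  iso <- weighted_network(data.frame(from = "a", to = "b", weight = 1),
                          nodes = c("a", "b", "z"))
  corp_iso <- node2vec_walks(iso, walk_length = 5, walks_per_node = 2, seed = 1)
  lone <- Filter(function(w) w[1] == "z", corp_iso$walks)
  expect_true(all(lengths(lone) == 1))

  # reproducibility under the same seed
  c1 <- node2vec_walks(net, seed = 42)
  c2 <- node2vec_walks(net, seed = 42)
  expect_identical(c1$walks, c2$walks)
})

test_that("skip-gram embeddings separate planted communities", {
  set.seed(1)
  cliques <- lapply(0:1, function(g) t(utils::combn(sprintf("c%d_%d", g, 1:10), 2)))
  e <- do.call(rbind, cliques)
  net <- weighted_network(data.frame(from = e[, 1], to = e[, 2], weight = 1))
  corpus <- node2vec_walks(net, walk_length = 10, walks_per_node = 10, seed = 3)
  emb <- skipgram_embed(corpus, d = 16, seed = 4)
  expect_equal(dim(emb), c(20, 16))
  cs <- emb / sqrt(rowSums(emb^2))
  sim <- cs %*% t(cs)
  g1 <- startsWith(rownames(emb), "c0")
  within <- mean(c(sim[g1, g1][upper.tri(sim[g1, g1])],
                   sim[!g1, !g1][upper.tri(sim[!g1, !g1])]))
  between <- mean(sim[g1, !g1])
  expect_gt(within, between)

  # identical seed, identical result
  emb2 <- skipgram_embed(corpus, d = 16, seed = 4)
  expect_identical(unclass(emb), unclass(emb2))

  # nodes never visited by the corpus get zero vectors, with a warning
  iso <- weighted_network(data.frame(from = "a", to = "b", weight = 1),
                          nodes = c("a", "b", "z"))
  corp2 <- node2vec_walks(iso, walk_length = 4, walks_per_node = 2, seed = 1)
  corp2$walks <- Filter(function(w) w[1] != "z", corp2$walks)
  expect_warning(emb3 <- skipgram_embed(corp2, d = 4, seed = 1), "zero vectors")
  expect_equal(unname(emb3["z", ]), rep(0, 4))
  expect_error(skipgram_embed(corp2, d = 0), "positive")
})

test_that("embedding TSV round trip preserves vectors and provenance", {
  net <- random_net(8, seed = 6)
  emb <- mashup_embed(rwr_diffusion(net), d = 4, network = "combinedscore")
  f <- tempfile()
  write_embedding(emb, f)
  back <- read_embedding(f)
  expect_equal(unclass(back), unclass(emb), tolerance = 1e-8)
  expect_equal(attr(back, "method"), "mashup")
  expect_equal(attr(back, "network"), "combinedscore")
})
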
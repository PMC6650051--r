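sep_fixture <- function(n = 200, din = 16, vterms = 5, seed = 42) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * din), n, din,
              dimnames = list(sprintf("p%03d", seq_len(n)), NULL))
  W <- matrix(stats::rnorm(din * vterms), din, vterms)
  Y <- (X %*% W > 0) * 1L
  colnames(Y) <- paste0("t", seq_len(vterms))
  list(X = X, Y = Y)
}

test_that("configuration bounds are validated", {
  expect_error(dmnn_config(hidden_dim = 0), "hidden_dim")
  expect_error(dmnn_config(maxout_pieces = 0), "maxout_pieces")
  expect_error(dmnn_config(dropout_rate = 1), "dropout_rate")
  expect_error(dmnn_config(epochs = 0), "epochs")
  expect_error(build_dmnn(0, 5), "input_dim")
})

test_that("a one-piece block with inactive dropout is an affine map", {
  cfg <- dmnn_config(hidden_dim = 6, maxout_pieces = 1, dropout_rate = 0,
                     seed = 3)
  m <- build_dmnn(4, 2, cfg)
  X <- matrix(stats::rnorm(12), 3, 4)
  H <- string2go:::dmnn_forward(m, X, training = FALSE)
  # inference batch-norm at init: x / sqrt(1 + eps); then one affine piece
  manual <- X
  for (l in 1:3) {
    ly <- m$layers[[l]]
    manual <- sweep((manual / sqrt(1 + string2go:::bn_eps)) %*% ly$W[[1]],
                    2, ly$b[[1]], "+")
  }
  expect_equal(H$h3, manual, tolerance = 1e-12)
  # doubling the input doubles the (bias-free) hidden response
  m0 <- m
  for (l in 1:3) m0$layers[[l]]$b[[1]] <- rep(0, 6)
  h1 <- string2go:::dmnn_forward(m0, X, training = FALSE)$h3
  h2 <- string2go:::dmnn_forward(m0, 2 * X, training = FALSE)$h3
  expect_equal(h2, 2 * h1, tolerance = 1e-10)
})

test_that("maxout takes the elementwise maximum and is piece-symmetric", {
  cfg <- dmnn_config(hidden_dim = 3, maxout_pieces = 3, dropout_rate = 0,
                     seed = 5)
  m <- build_dmnn(2, 2, cfg)
  X <- matrix(stats::rnorm(10), 5, 2)
  fw <- string2go:::dmnn_forward(m, X, training = FALSE)
  # layer-1 activations equal the max over manually computed pieces
  ly <- m$layers[[1]]
  Y1 <- sweep(X, 2, sqrt(ly$run_var + string2go:::bn_eps), "/")
  pieces <- lapply(1:3, function(j) sweep(Y1 %*% ly$W[[j]], 2, ly$b[[j]], "+"))
  expect_equal(fw$caches[[1]]$act, pmax(pieces[[1]], pieces[[2]], pieces[[3]]),
               tolerance = 1e-12)
  # scalar check: pieces producing (x, 2x, -x) at x = 1 yield 2
  ms <- build_dmnn(1, 1, dmnn_config(hidden_dim = 1, maxout_pieces = 3,
                                     dropout_rate = 0, seed = 1))
  scalars <- c(1, 2, -1)
  for (j in 1:3) {
    ms$layers[[1]]$W[[j]] <- matrix(scalars[j] * sqrt(1 + string2go:::bn_eps))
    ms$layers[[1]]$b[[j]] <- 0
  }
  a1 <- string2go:::dmnn_forward(ms, matrix(1), training = FALSE)$caches[[1]]$act
  expect_equal(unname(a1[1, 1]), 2)

  # permuting the pieces of a block leaves the forward pass unchanged
  mp <- m
  perm <- c(3, 1, 2)
  mp$layers[[2]]$W <- mp$layers[[2]]$W[perm]
  mp$layers[[2]]$b <- mp$layers[[2]]$b[perm]
  expect_equal(string2go:::dmnn_forward(mp, X, training = FALSE)$p, fw$p,
               tolerance = 1e-14)
})

test_that("training fits separable multi-label data and logs decreasing loss", {
  fx <- sep_fixture()
  cfg <- dmnn_config(hidden_dim = 32, epochs = 150, seed = 7)
  m <- train_dmnn(build_dmnn(16, 5, cfg), fx$X, fx$Y, cfg)
  expect_length(m$loss_log, 150)
  expect_lte(m$loss_log[150], m$loss_log[1])
  P <- predict_sigmoid(m, fx$X)
  expect_true(all(P > 0 & P < 1))
  expect_equal(ncol(P), 5)
  f1s <- vapply(1:5, function(t) {
    confusion_metrics(confusion_counts(P[, t] >= 0.5, fx$Y[, t] == 1))$f1
  }, numeric(1))
  expect_gte(mean(f1s), 0.95)
})

test_that("degenerate all-zero targets drive every output below 0.5", {
  fx <- sep_fixture(n = 80, din = 8, vterms = 3)
  Y0 <- fx$Y * 0L
  cfg <- dmnn_config(hidden_dim = 8, epochs = 30, batch_size = 40, seed = 2)
  m <- train_dmnn(build_dmnn(8, 3, cfg), fx$X, Y0, cfg)
  expect_true(all(predict_sigmoid(m, fx$X) < 0.5))
})

test_that("misaligned inputs are rejected", {
  fx <- sep_fixture(n = 30, din = 4, vterms = 2)
  cfg <- dmnn_config(hidden_dim = 4, epochs = 2, seed = 1)
  m <- build_dmnn(4, 2, cfg)
  expect_error(train_dmnn(m, fx$X, fx$Y[1:10, ], cfg), "row counts")
  Yswap <- fx$Y[rev(seq_len(nrow(fx$Y))), ]
  expect_error(train_dmnn(m, fx$X, Yswap, cfg), "aligned")
  expect_error(extract_representation(train_dmnn(m, fx$X, fx$Y, cfg),
                                      fx$X[, 1:2]), "dimension")
})

test_that("representation extraction is deterministic and label-free", {
  fx <- sep_fixture(n = 60, din = 8, vterms = 3)
  cfg <- dmnn_config(hidden_dim = 12, epochs = 20, batch_size = 30, seed = 9)
  m <- train_dmnn(build_dmnn(8, 3, cfg), fx$X, fx$Y, cfg)
  R1 <- extract_representation(m, fx$X)
  R2 <- extract_representation(m, fx$X)
  expect_identical(unclass(R1), unclass(R2))
  expect_equal(dim(R1), c(60, 12))
  expect_equal(attr(R1, "method"), "string2go")
  # duplicated input row yields a duplicated representation row
  Xdup <- rbind(fx$X, dup = fx$X[1, ])
  Rd <- extract_representation(m, Xdup)
  expect_equal(unname(Rd["dup", ]), unname(Rd[1, ]))
})

test_that("hidden-width selection follows rounded-median argmax with low tie-break", {
  expect_equal(pick_hidden_dim(c(300, 500), c(0.40, 0.40)), 300)
  expect_equal(pick_hidden_dim(c(300, 500), c(0.10, 0.30)), 500)
  expect_equal(pick_hidden_dim(700, 0.2), 700)
  expect_equal(pick_hidden_dim(c(1000, 300, 700), c(0.25, 0.25, 0.25)), 300)

  fx <- sep_fixture(n = 60, din = 8, vterms = 3)
  cfg <- dmnn_config(hidden_dim = 8, epochs = 10, batch_size = 30, seed = 4)
  sel <- select_hidden_dim(c(8, 12), fx$X, fx$Y, cfg, folds = 3, seed = 1)
  expect_true(sel$hidden_dim %in% c(8, 12))
  expect_equal(sel$report$candidate, c(8, 12))
  expect_equal(sel$report$rounded, round(sel$report$median_f1, 2))
  expect_equal(sel$hidden_dim,
               pick_hidden_dim(sel$report$candidate, sel$report$rounded))
})
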
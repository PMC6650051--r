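two_cluster_fixture <- function(n = 40, d = 4, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(1 + stats::rnorm(n / 2 * d, 0, 0.1), n / 2, d),
             matrix(-1 + stats::rnorm(n / 2 * d, 0, 0.1), n / 2, d))
  rownames(X) <- sprintf("p%02d", seq_len(n))
  dag <- toy_dag(list(t1 = character(0), t2 = "t1"))
  ann <- matrix(0L, n, 2, dimnames = list(rownames(X), c("t1", "t2")))
  ann[seq_len(n / 2), ] <- 1L
  class(ann) <- c("annotation_matrix", "matrix", "array")
  list(X = X, dag = dag, ann = ann)
}

test_that("separable clusters reach CV F1 of 1 and calibrated scores above 0.5", {
  fx <- two_cluster_fixture()
  cl <- train_term_svms(fx$X, fx$ann, toy_vocab("t1"), fx$dag,
                        grid = svm_grid(cost = 2^(0:4), gamma = 2^(-3:0)),
                        folds = 5, seed = 9)
  expect_equal(cl$t1$cv_f1, 1.0)
  S <- predict_posteriors(cl, fx$X, toy_vocab("t1"))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(S[1:20, "t1"] > 0.5))
  expect_true(all(S[21:40, "t1"] < 0.5))
})

test_that("positives include proteins annotated only with a descendant", {
  fx <- two_cluster_fixture()
  # p01 carries only the child term; it must still be a positive for t1
  ann <- fx$ann
  ann[1:20, "t1"] <- 0L
  ann[1:20, "t2"] <- 1L
  class(ann) <- c("annotation_matrix", "matrix", "array")
  cl <- train_term_svms(fx$X, ann, toy_vocab("t1"), fx$dag,
                        grid = svm_grid(cost = 1, gamma = 0.25),
                        folds = 3, seed = 2)
  expect_equal(cl$t1$n_positive, 20)
  S <- predict_posteriors(cl, fx$X)
  expect_gt(min(S[1:20, "t1"]), 0.5)
})

test_that("a one-point grid is selected as-is and ranking survives calibration", {
  fx <- two_cluster_fixture()
  cl <- train_term_svms(fx$X, fx$ann, toy_vocab("t1"), fx$dag,
                        grid = svm_grid(cost = 8, gamma = 0.5),
                        folds = 4, seed = 3)
  expect_equal(cl$t1$cost, 8)
  expect_equal(cl$t1$gamma, 0.5)
  dv <- string2go:::svm_decision(cl$t1$fit,
                                 string2go:::scale_features(fx$X, cl$t1$scaling))
  post <- predict_posteriors(cl, fx$X)[, "t1"]
  expect_equal(stats::cor(dv, post, method = "spearman"), 1)
})

test_that("terms without positives are skipped and sparse terms reduce folds", {
  fx <- two_cluster_fixture()
  ann <- fx$ann
  ann[, "t2"] <- 0L
  ann[1:3, "t2"] <- 1L
  class(ann) <- c("annotation_matrix", "matrix", "array")
  vocab2 <- toy_vocab("t2")
  # t2 now has 3 positives < 10 folds: reduced-fold warning
  expect_warning(
    cl <- train_term_svms(fx$X, ann, vocab2,
                          toy_dag(list(t1 = character(0), t2 = character(0))),
                          grid = svm_grid(cost = 1, gamma = 0.25),
                          folds = 10, seed = 1),
    "positives")
  expect_true("t2" %in% names(cl))
  ann0 <- ann
  ann0[, "t2"] <- 0L
  class(ann0) <- c("annotation_matrix", "matrix", "array")
  expect_warning(
    cl0 <- train_term_svms(fx$X, ann0, vocab2,
                           toy_dag(list(t1 = character(0), t2 = character(0))),
                           grid = svm_grid(cost = 1, gamma = 0.25),
                           folds = 3, seed = 1),
    "skipped")
  expect_length(cl0, 0)
  # skipped terms score zero for every protein
  S <- predict_posteriors(cl0, fx$X, vocab2)
  expect_true(all(S == 0))
})

test_that("naive baseline scores the training frequency for every protein", {
  ann <- matrix(0L, 10, 2, dimnames = list(sprintf("p%02d", 1:10), c("t", "u")))
  ann[1:4, "t"] <- 1L
  S <- naive_baseline(ann, toy_vocab(c("t", "u", "absent")), c("q1", "q2", "q3"))
  expect_equal(unname(S[, "t"]), rep(0.4, 3))
  expect_equal(unname(S[, "absent"]), rep(0, 3))
  expect_equal(apply(S, 2, stats::sd), c(t = 0, u = 0, absent = 0))
})

test_that("PPI-homolog transfer scores the fraction of annotated homologs", {
  net <- weighted_network(data.frame(from = c("p", "r"), to = c("x", "x"),
                                     weight = 0.9))
  train_ann <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                      dimnames = list(c("h1", "h2"), c("t1", "t2")))
  vocab <- toy_vocab(c("t1", "t2"))
  one <- homology_oracle(data.frame(query = "x", subject = "h1", evalue = 1e-8))
  S1 <- ppi_homolog_baseline(net, train_ann, one, vocab, "p")
  expect_equal(unname(S1["p", ]), c(1, 0))  # sole homolog has t1 only
  both <- homology_oracle(data.frame(query = c("x", "x"), subject = c("h1", "h2"),
                                     evalue = c(1e-8, 1e-8)))
  S2 <- ppi_homolog_baseline(net, train_ann, both, vocab, "p")
  expect_equal(unname(S2["p", "t1"]), 0.5)  # one of two homologs has t1
  S3 <- ppi_homolog_baseline(net, train_ann, both, vocab, "ghost")
  expect_equal(unname(S3["ghost", ]), c(0, 0))  # absent from the network
  # E-value above threshold: no transfer
  far <- homology_oracle(data.frame(query = "x", subject = "h1", evalue = 0.5))
  expect_true(all(ppi_homolog_baseline(net, train_ann, far, vocab, "p",
                                       evalue_threshold = 1e-2) == 0))
})

test_that("descendant-aware positive sets are nested along is_a", {
  set.seed(21)
  dag <- toy_dag(list(root = character(0), a = "root", b = "a"))
  n <- 30
  ann <- matrix(0L, n, 3, dimnames = list(sprintf("p%02d", 1:n),
                                          c("root", "a", "b")))
  ann[1:18, "root"] <- 1L
  ann[1:12, "a"] <- 1L
  ann[1:6, "b"] <- 1L
  pos_for <- function(t) {
    fam <- c(t, term_descendants(dag, t))
    rownames(ann)[rowSums(ann[, intersect(fam, colnames(ann)), drop = FALSE]) > 0]
  }
  expect_true(all(pos_for("b") %in% pos_for("a")))
  expect_true(all(pos_for("a") %in% pos_for("root")))
})
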
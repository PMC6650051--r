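test_that("confusion metrics follow the defining formulas and conventions", {
  m <- confusion_metrics(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-4)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-4)

  perfect <- confusion_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)

  degenerate <- confusion_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$f1, 0)
  expect_equal(degenerate$mcc, 0)
})

test_that("AUPRC is the step-interpolated area and flags missing positives", {
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6, tolerance = 1e-12)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_warning(v <- auprc(c(0.5, 0.2), c(0, 0)), "undefined")
  expect_true(is.na(v))
  # tied scores collapse into one threshold
  expect_equal(auprc(c(0.5, 0.5), c(1, 0)), 0.5)
})

test_that("Fmax on the worked two-protein example is exact", {
  S <- matrix(c(0.9, 0.2, 0.6, 0.4), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("t1", "t2")))
  Y <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE, dimnames = dimnames(S))
  fm <- fmax(score_matrix(S), Y)
  expect_equal(fm$fmax, 1.0)
  expect_equal(fm$tau_star, 0.40)
  # identity scores give a perfect score at the top threshold
  fm2 <- fmax(score_matrix(Y), Y)
  expect_equal(fm2$fmax, 1.0)
  expect_equal(fm2$tau_star, 1.0)
})

test_that("f_tau matches Fmax at tau* and warns on empty prediction sets", {
  set.seed(12)
  inst <- random_instance(8, 5)
  fm <- fmax(score_matrix(inst$S), inst$Y)
  expect_identical(f_tau(score_matrix(inst$S), inst$Y, fm$tau_star), fm$fmax)
  S0 <- matrix(0.3, 2, 2, dimnames = list(c("a", "b"), c("t", "u")))
  Y0 <- matrix(1L, 2, 2, dimnames = dimnames(S0))
  expect_warning(v <- f_tau(score_matrix(S0), Y0, 1.0), "no protein")
  expect_equal(v, 0)
})

test_that("threshold-sweep invariants hold on random instances", {
  set.seed(4)
  for (rep in 1:5) {
    inst <- random_instance(10, 5)
    fm <- fmax(score_matrix(inst$S), inst$Y)
    expect_true(all(diff(fm$curve$recall) <= 1e-12))  # recall non-increasing
    expect_true(all(diff(fm$curve$m) <= 0))
    expect_true(all(fm$curve$f <= fm$fmax + 1e-12))
    # invariance under joint protein reordering
    ord <- sample.int(10)
    fm2 <- fmax(score_matrix(inst$S[ord, ]), inst$Y[ord, ])
    expect_equal(fm2$fmax, fm$fmax)
    expect_equal(fm2$tau_star, fm$tau_star)
  }
})

test_that("evaluation report aggregates per-term metrics with lower medians", {
  set.seed(8)
  inst <- random_instance(12, 6)
  rep_ <- evaluate_predictions(score_matrix(inst$S, method = "toy"), inst$Y)
  expect_equal(nrow(rep_$per_term), 6)
  expect_equal(rep_$median_f1, sort(rep_$per_term$f1)[3])  # lower median
  expect_true(rep_$median_f1 >= min(rep_$per_term$f1) &&
                rep_$median_f1 <= max(rep_$per_term$f1))
  f <- tempfile()
  write_evaluation_report(rep_, f)
  expect_true(any(grepl("median_f1", readLines(f))))
})

test_that("centroid distances behave geometrically and correlate with F1", {
  X <- rbind(matrix(5, 10, 2), matrix(0, 10, 2)) +
    matrix(c(0, 1e-9), 20, 2)  # avoid exactly constant dims
  labels <- cbind(t1 = rep(c(1, 0), each = 10), t2 = rep(c(1, 0), 10))
  res <- centroid_distance_analysis(X, labels, c(0.9, 0.1))
  expect_equal(unname(res$distance["t1"]), sqrt(2), tolerance = 1e-6)
  expect_equal(unname(res$distance["t2"]), 0, tolerance = 1e-6)
  expect_equal(res$correlation, 1)
  # identical class distributions give zero distance
  block <- matrix(stats::rnorm(20), 10, 2)
  r2 <- centroid_distance_analysis(rbind(block, block),
                                   cbind(t1 = rep(c(1, 0), each = 10)), 0.5)
  expect_equal(max(abs(r2$distance)), 0, tolerance = 1e-9)
  expect_warning(
    centroid_distance_analysis(cbind(rep(1, 4), c(0, 0, 1, 1)),
                               cbind(t = c(1, 1, 0, 0)), 0.5),
    "constant")
})

test_that("paired tests use the exact signed-rank law and Holm correction", {
  x <- as.numeric(1:10)
  same <- paired_tests(a = x, b = x)
  expect_equal(same$p_value, 1.0)
  expect_false(any(same$pairwise$reject))

  shifted <- paired_tests(a = x + 1, b = x)
  expect_equal(shifted$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_true(shifted$pairwise$reject)

  # untied case agrees with the reference exact implementation
  set.seed(2)
  a <- stats::rnorm(12)
  b <- a + stats::rnorm(12, 0.4, 0.3)
  ours <- paired_tests(a = a, b = b)$p_value
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)

  # three methods take the Friedman + Holm path
  set.seed(3)
  M <- cbind(m1 = stats::rnorm(15), m2 = stats::rnorm(15, 1),
             m3 = stats::rnorm(15, 2))
  fr <- paired_tests(M)
  expect_equal(fr$method, "friedman_holm")
  expect_equal(fr$pairwise$p_holm, stats::p.adjust(fr$pairwise$p, "holm"))
  expect_equal(nrow(fr$pairwise), 3)
})
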
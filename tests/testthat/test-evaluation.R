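# classifier contract that always predicts the training majority class
majority_classifier <- function() {
  list(
    name = "majority",
    fit = function(x, y) {
      lv <- levels(y)
      if (sum(y == lv[2]) > sum(y == lv[1])) 1 else -1
    },
    score = function(model, x) rep(model, nrow(x))
  )
}

test_that("confusion metrics match hand arithmetic", {
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  got <- confusion_metrics(y_true, y_pred, positive = "pos")
  expect_equal(unname(got), c(0.9, 0.8, 0.85, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9)))
  perfect <- confusion_metrics(y_true, y_true, "pos")
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  all_neg <- confusion_metrics(y_true, rep("neg", 20), "pos")
  expect_equal(unname(all_neg), c(0, 1, 0.5, 0))
  expect_error(confusion_metrics(y_true, y_pred[-1], "pos"), "length")
  expect_error(confusion_metrics(rep("pos", 5), rep("pos", 5), "pos"), "both classes")
})

test_that("AUC is the Mann-Whitney probability with midrank ties", {
  y <- c("n", "n", "p", "p")
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), y, "p"), 1)
  expect_equal(auc(rep(0.5, 4), y, "p"), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), y, "p"), 0.75)
  # orientation anti-symmetry (no ties)
  s <- c(0.3, 0.9, 0.2, 0.7, 0.55, 0.05)
  yy <- c("n", "p", "n", "p", "n", "p")
  expect_equal(auc(s, yy, "p") + auc(-s, yy, "p"), 1)
  expect_error(auc(s, rep("p", 6), "p"), "both classes")
})

test_that("average correlation equals the naive pairwise loop", {
  base <- rnorm(12)
  values <- cbind(g1 = base, g2 = base, g3 = rep(c(1, 2), 6), g4 = rep(c(1, 1, 2, 2), 3))
  em <- expression_matrix(values, rep(c("a", "b"), each = 6))
  expect_equal(avg_correlation(em, c(1L, 1L, 0L, 0L)), 1)       # duplicated pair
  expect_equal(avg_correlation(em, c(0L, 0L, 1L, 1L)), 0)       # orthogonal toy
  gen <- generate_expression(synthetic_spec(n_per_class = 10, n_relevant = 1,
                                            n_blocks = 1, block_size = 1,
                                            n_noise = 2, seed = 3))
  mask <- rep(1L, 4)
  pairs <- combn(4, 2)
  want <- mean(apply(pairs, 2, function(ij) {
    abs(pearson(gen$matrix$values[, ij[1]], gen$matrix$values[, ij[2]]))
  }))
  expect_equal(avg_correlation(gen$matrix, mask), want, tolerance = 1e-12)
  expect_error(avg_correlation(em, c(1L, 0L, 0L, 0L)), "at least 2")
})

test_that("k-fold CV is perfect on a separable gene and deterministic", {
  labels <- rep(c("a", "b"), each = 15)
  values <- cbind(sig = ifelse(labels == "a", 0, 1) + rnorm(30, 0, 0.01),
                  junk = rnorm(30))
  em <- expression_matrix(values, labels)
  for (clf in list(centroid_classifier(), svm_classifier())) {
    rep1 <- kfold_cv(em, c(1L, 0L), classifier = clf, k = 10, seed = 4)
    expect_equal(rep1$accuracy, 1)
    expect_equal(rep1$auc, 1)
    expect_equal(rep1$sensitivity, 1)
    expect_equal(rep1$n_selected, 1L)
    expect_true(is.na(rep1$avg_correlation))  # single gene: no pairs
  }
  a <- kfold_cv(em, c(1L, 1L), k = 5, seed = 9)
  b <- kfold_cv(em, c(1L, 1L), k = 5, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_false(is.na(a$avg_correlation))
  expect_error(kfold_cv(em, c(0L, 0L), k = 5, seed = 1), "at least one gene")
})

test_that("k-fold CV accuracy is chance-level after label shuffling", {
  accs <- vapply(1:20, function(s) {
    em <- mobpso:::with_seed(s, {
      labels <- sample(rep(c("a", "b"), each = 15))
      expression_matrix(matrix(rnorm(30 * 4), 30, 4,
                               dimnames = list(NULL, paste0("g", 1:4))),
                        labels)
    })
    kfold_cv(em, rep(1L, 4), classifier = centroid_classifier(),
             k = 5, seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("repeated hold-out aggregates the configured number of stratified splits", {
  # unbalanced classes: majority-vote accuracy on the test side is predictable
  labels <- c(rep("a", 12), rep("b", 24))
  em <- mobpso:::with_seed(1, {
    expression_matrix(matrix(rnorm(36 * 5), 36, 5,
                             dimnames = list(NULL, paste0("g", 1:5))),
                      labels)
  })
  summ <- repeated_holdout(em, identity_selector(), majority_classifier(),
                           n_repeats = 10, seed = 2)
  expect_equal(summ$n_repeats, 10)
  expect_length(summ$reports, 10)
  # stratified 2/3 split leaves 4 "a" and 8 "b" in every test set;
  # the majority classifier always predicts "b" (positive): accuracy 8/12
  expect_equal(summ$summary$mean[summ$summary$metric == "accuracy"], 8 / 12)
  expect_equal(summ$summary$sd[summ$summary$metric == "accuracy"], 0)
  expect_equal(summ$summary$mean[summ$summary$metric == "sensitivity"], 1)
  expect_equal(summ$summary$mean[summ$summary$metric == "specificity"], 0)
  # determinism under the same seed
  again <- repeated_holdout(em, identity_selector(), majority_classifier(),
                            n_repeats = 10, seed = 2)
  expect_identical(summ$summary, again$summary)
})

test_that("the pipeline selector plugs into the hold-out protocol", {
  gen <- generate_expression(synthetic_spec(n_per_class = 20, n_relevant = 3,
                                            n_blocks = 1, block_size = 3,
                                            n_noise = 14, seed = 8))
  summ <- repeated_holdout(gen$matrix,
                           mobpso_selector(top_k = 20,
                                           params = pso_params(swarm_size = 10,
                                                               iterations = 15)),
                           svm_classifier(), n_repeats = 3, seed = 7)
  acc <- summ$summary$mean[summ$summary$metric == "accuracy"]
  expect_gt(acc, 0.6)  # planted effect = 2 is easily detectable
  expect_true(all(summ$summary$sd >= 0, na.rm = TRUE))
})
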
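#' Confusion-matrix metrics for binary predictions
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy and F-score
#' `2 * precision * sensitivity / (precision + sensitivity)` (defined as 0
#' when both precision and sensitivity are 0).
#'
#' @param y_true,y_pred label vectors of equal length; `y_true` must contain
#'   both classes.
#' @param positive the label counted as positive.
#' @return named numeric vector `c(sensitivity, specificity, accuracy, fscore)`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  check_that(length(y_true) == length(y_pred),
             "y_true and y_pred differ in length")
  pos <- y_true == positive
  check_that(any(pos) && !all(pos), "y_true must contain both classes")
  pred_pos <- y_pred == positive
  tp <- sum(pos & pred_pos)
  fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos)
  fp <- sum(!pos & pred_pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  fscore <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec, accuracy = acc, fscore = fscore)
}

#' Area under the ROC curve (Mann-Whitney rank form)
#'
#' Probability that a random positive sample outscores a random negative one,
#' ties counting one half: `(sum of positive ranks - n_pos (n_pos + 1) / 2) /
#' (n_pos * n_neg)` with midranks.
#'
#' @param scores continuous decision scores (larger = more positive).
#' @param y_true label vector containing both classes.
#' @param positive the positive label.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, y_true, positive) {
  check_that(length(scores) == length(y_true),
             "scores and y_true differ in length")
  pos <- y_true == positive
  check_that(any(pos) && !all(pos), "both classes must be present")
  r <- rank(scores)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average absolute pairwise correlation of the selected genes
#'
#' Mean of `|pearson|` over all unordered pairs of selected genes — the
#' redundancy summary reported alongside the classification metrics. Computed
#' on the matrix as given (by convention, the full data).
#'
#' @param em an [expression_matrix()].
#' @param mask 0/1 selection vector (or character gene ids) selecting >= 2
#'   genes.
#' @return mean absolute correlation in `[0, 1]`.
#' @export
avg_correlation <- function(em, mask) {
  sel <- resolve_selection(em, mask)
  check_that(length(sel) >= 2, "avg_correlation needs at least 2 selected genes")
  r <- cor_matrix(em$values[, sel, drop = FALSE])
  mean(abs(r[upper.tri(r)]))
}

# mask (0/1 vector) or character gene ids -> integer column indices
resolve_selection <- function(em, mask) {
  if (is.character(mask)) {
    check_that(all(mask %in% em$gene_ids), "unknown gene identifiers in selection")
    match(mask, em$gene_ids)
  } else {
    mask <- as.integer(mask)
    check_that(length(mask) == n_genes(em),
               "mask length must equal the gene count")
    which(mask == 1L)
  }
}

#' Linear soft-margin SVM classifier (reference configuration)
#'
#' Wraps [e1071::svm()] (linear kernel) behind the package's classifier
#' contract: `fit(x, y)` with `y` a factor whose second level is the positive
#' class, and `score(model, x)` returning a continuous decision value oriented
#' so that positive scores favor the positive class.
#'
#' @param cost soft-margin cost parameter.
#' @return classifier contract list with `name`, `fit`, `score`.
#' @export
svm_classifier <- function(cost = 1) {
  list(
    name = "linear-svm",
    fit = function(x, y) {
      e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    },
    score = function(model, x) {
      pred <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # column name "A/B": positive decision values favor class A
      favored <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      pos <- levels(model$fitted)[2]
      if (favored == pos) drop(dv) else -drop(dv)
    }
  )
}

#' Nearest-centroid classifier (dependency-free baseline)
#'
#' Scores a sample by its Euclidean distance to the negative-class centroid
#' minus its distance to the positive-class centroid, so positive scores mean
#' "closer to the positive class".
#'
#' @return classifier contract list with `name`, `fit`, `score`.
#' @export
centroid_classifier <- function() {
  list(
    name = "centroid",
    fit = function(x, y) {
      lv <- levels(y)
      list(levels = lv,
           mu_neg = colMeans(x[y == lv[1], , drop = FALSE]),
           mu_pos = colMeans(x[y == lv[2], , drop = FALSE]))
    },
    score = function(model, x) {
      d_neg <- sqrt(rowSums(sweep(x, 2, model$mu_neg)^2))
      d_pos <- sqrt(rowSums(sweep(x, 2, model$mu_pos)^2))
      unname(d_neg - d_pos)
    }
  )
}

# stratified fold assignment: within each class, shuffled rep_len(1:k)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    check_that(length(idx) >= 1, "empty class in fold assignment")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

metrics_report <- function(cm, auc_value, avg_corr, n_selected) {
  structure(list(sensitivity = unname(cm["sensitivity"]),
                 specificity = unname(cm["specificity"]),
                 accuracy = unname(cm["accuracy"]),
                 fscore = unname(cm["fscore"]),
                 auc = auc_value,
                 avg_correlation = avg_corr,
                 n_selected = n_selected),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report (%d genes): sensitivity %.3f, ",
                     "specificity %.3f, accuracy %.3f, fscore %.3f, ",
                     "auc %.3f, avg |cor| %s\n"),
              x$n_selected, x$sensitivity, x$specificity, x$accuracy,
              x$fscore, x$auc,
              if (is.na(x$avg_correlation)) "NA" else
                sprintf("%.3f", x$avg_correlation)))
  invisible(x)
}

# fit on train rows, score test rows; returns continuous scores
fit_and_score <- function(classifier, x_train, y_train, x_test, class_order) {
  y <- factor(y_train, levels = class_order)
  model <- classifier$fit(x_train, y)
  classifier$score(model, x_test)
}

#' Stratified k-fold cross-validation of a fixed gene selection
#'
#' The gene set is fixed by `mask`; per fold a classifier is trained on the
#' remaining folds and scores the held-out fold. Held-out predictions and
#' scores are pooled over all folds into a single [metrics_report];
#' `avg_correlation` is computed once on the full matrix under the mask.
#'
#' @param em an [expression_matrix()].
#' @param mask 0/1 vector or character gene ids (>= 1 gene).
#' @param classifier a classifier contract (default [svm_classifier()]).
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling the stratified fold assignment.
#' @param positive the positive label (default class2 of `class_order`;
#'   class1 is the control group).
#' @return a `metrics_report`.
#' @export
kfold_cv <- function(em, mask, classifier = svm_classifier(), k = 10,
                     seed = 1, positive = em$class_order[2]) {
  sel <- resolve_selection(em, mask)
  check_that(length(sel) >= 1, "mask must select at least one gene")
  x <- em$values[, sel, drop = FALSE]
  labels <- em$labels
  neg <- setdiff(em$class_order, positive)
  folds <- with_seed(seed, stratified_folds(labels, k))
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    scores[test] <- fit_and_score(classifier,
                                  x[!test, , drop = FALSE], labels[!test],
                                  x[test, , drop = FALSE], c(neg, positive))
  }
  pred <- ifelse(scores > 0, positive, neg)
  cm <- confusion_metrics(labels, pred, positive)
  a <- auc(scores, labels, positive)
  corr <- if (length(sel) >= 2) avg_correlation(em, em$gene_ids[sel]) else NA_real_
  metrics_report(cm, a, corr, length(sel))
}

#' Repeated stratified hold-out evaluation of a selection procedure
#'
#' Per repeat: split the samples into a stratified train/test partition, run
#' the selector on the training part only, train the classifier on the
#' training samples restricted to the selected genes, score the test part and
#' collect a [metrics_report]. Returns per-metric means and standard
#' deviations over the repeats.
#'
#' @param em an [expression_matrix()].
#' @param selector selection-procedure contract: `function(train_em, seed)`
#'   returning a character vector of selected gene ids (see
#'   [mobpso_selector()]; `identity_selector()` keeps all genes).
#' @param classifier a classifier contract (default [svm_classifier()]).
#' @param n_repeats number of repeated splits (default 10).
#' @param train_fraction fraction of each class assigned to training
#'   (default 2/3).
#' @param seed RNG seed; repeat r hands `seed + r` to the selector.
#' @param positive the positive label (default class2).
#' @return object of class `repeated_eval_summary`: `summary` (data.frame with
#'   metric, mean, sd), `reports` (per-repeat `metrics_report`s), `n_repeats`.
#' @export
repeated_holdout <- function(em, selector, classifier = svm_classifier(),
                             n_repeats = 10, train_fraction = 2 / 3,
                             seed = 1, positive = em$class_order[2]) {
  check_that(n_repeats >= 1, "n_repeats must be positive")
  check_that(train_fraction > 0 && train_fraction < 1,
             "train_fraction must lie in (0, 1)")
  labels <- em$labels
  neg <- setdiff(em$class_order, positive)
  splits <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    train <- logical(length(labels))
    for (cls in em$class_order) {
      idx <- which(labels == cls)
      n_tr <- min(max(round(train_fraction * length(idx)), 2), length(idx) - 1)
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  }))
  reports <- lapply(seq_len(n_repeats), function(r) {
    train <- splits[[r]]
    genes <- selector(subset_samples(em, train), seed + r)
    check_that(length(genes) >= 1, "selector returned no genes")
    scores <- fit_and_score(classifier,
                            em$values[train, genes, drop = FALSE], labels[train],
                            em$values[!train, genes, drop = FALSE],
                            c(neg, positive))
    pred <- ifelse(scores > 0, positive, neg)
    cm <- confusion_metrics(labels[!train], pred, positive)
    a <- auc(scores, labels[!train], positive)
    corr <- if (length(genes) >= 2) avg_correlation(em, genes) else NA_real_
    metrics_report(cm, a, corr, length(genes))
  })
  fields <- c("sensitivity", "specificity", "accuracy", "fscore", "auc",
              "avg_correlation")
  vals <- sapply(fields, function(f) vapply(reports, `[[`, numeric(1), f))
  vals <- matrix(vals, nrow = n_repeats,
                 dimnames = list(NULL, fields))
  structure(list(summary = data.frame(metric = fields,
                                      mean = apply(vals, 2, mean),
                                      sd = apply(vals, 2, stats::sd),
                                      row.names = NULL),
                 reports = reports,
                 n_repeats = n_repeats),
            class = "repeated_eval_summary")
}

#' @export
print.repeated_eval_summary <- function(x, ...) {
  cat(sprintf("repeated_eval_summary over %d stratified hold-outs:\n",
              x$n_repeats))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Selector contract: keep every gene
#'
#' Baseline selection procedure for [repeated_holdout()].
#'
#' @return a `function(em, seed)` returning all gene ids.
#' @export
identity_selector <- function() {
  function(em, seed) em$gene_ids
}

#' Selector contract: the full marker-selection pipeline
#'
#' Wraps [select_markers()] for use in [repeated_holdout()]; the per-repeat
#' seed replaces `params$seed`.
#'
#' @param top_k genes kept after SNR ranking.
#' @param params a [pso_params()] template.
#' @return a `function(em, seed)` returning the picked marker gene ids.
#' @export
mobpso_selector <- function(top_k = 100, params = pso_params()) {
  function(em, seed) {
    params$seed <- as.integer(seed)
    select_markers(em, top_k = top_k, params = params)$genes
  }
}
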
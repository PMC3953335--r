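#' Per-group true-positive rates from a univariate logistic fit
#'
#' Fits `P(group = experiment | feature)` with intercept and slope by
#' iteratively reweighted least squares (max 50 iterations, ridge `1e-6` on
#' the normal equations so perfect separation converges instead of blowing
#' up). Each sample is predicted into the group with posterior >= 0.5, and the
#' true-positive rate of a group is the correctly predicted fraction within it.
#'
#' @param feature numeric expression vector of one gene.
#' @param labels per-sample class tags; must contain exactly two values with
#'   both groups non-empty.
#' @param ctr_label which label is the "control" group (default: first value
#'   of `labels` in order of appearance).
#' @return named numeric vector `c(tpr_ctr, tpr_exp)`.
#' @export
logistic_tpr <- function(feature, labels, ctr_label = labels[1]) {
  labels <- as.character(labels)
  check_that(length(feature) == length(labels),
             "feature and labels differ in length")
  is_exp <- labels != ctr_label
  check_that(any(is_exp) && !all(is_exp),
             "labels must contain both a control and an experiment group")
  X <- cbind(1, feature)
  y <- as.numeric(is_exp)
  beta <- c(0, 0)
  for (it in seq_len(50)) {
    p <- stats::plogis(drop(X %*% beta))
    wt <- p * (1 - p)
    H <- crossprod(X, X * wt) + diag(1e-6, 2)
    g <- crossprod(X, y - p)
    step <- drop(solve(H, g))
    if (!all(is.finite(step))) break
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  pred_exp <- stats::plogis(drop(X %*% beta)) >= 0.5
  c(tpr_ctr = mean(!pred_exp[!is_exp]), tpr_exp = mean(pred_exp[is_exp]))
}

#' tStat score of one feature
#'
#' Combines a scaling factor built from group means and coefficients of
#' variation with the product of per-group logistic true-positive rates:
#' `eta = (|mu_ctr - mu_all| / mu_all) * (cv_all / cv_ctr)` and
#' `score = eta * tpr_ctr * tpr_exp`. The score rewards a strong relative
#' mean shift of the control group, penalizes control-group noise, and
#' requires the feature to actually discriminate (logistic TPRs).
#'
#' Guards: when either mean is <= 1e-12 (possible after min-max
#' normalization) all values are shifted by +1 before computing means and
#' CVs — scores are used only for ranking and the shift is uniform;
#' `cv_ctr` is floored at 1e-12 and `eta` taken in absolute value so the
#' score is always finite and non-negative.
#'
#' @param feature numeric expression vector.
#' @param labels per-sample class tags (two groups, each with >= 2 samples).
#' @param ctr_label the control-group label.
#' @return list of class `tstat_parts` with fields `mu_ctr`, `mu_all`,
#'   `cv_ctr`, `cv_all`, `tp_product`, `eta`, `score`.
#' @export
tstat_feature <- function(feature, labels, ctr_label = labels[1]) {
  labels <- as.character(labels)
  is_ctr <- labels == ctr_label
  check_that(sum(is_ctr) >= 2 && sum(!is_ctr) >= 2,
             "each group needs at least 2 samples")
  x <- feature
  if (mean(x[is_ctr]) <= 1e-12 || mean(x) <= 1e-12) x <- x + 1
  mu_ctr <- mean(x[is_ctr])
  mu_all <- mean(x)
  cv_ctr <- stats::sd(x[is_ctr]) / mu_ctr
  cv_all <- stats::sd(x) / mu_all
  eta <- abs((mu_ctr - mu_all) / mu_all) * (cv_all / max(cv_ctr, 1e-12))
  eta <- abs(eta)
  tpr <- logistic_tpr(feature, labels, ctr_label)
  tp_product <- unname(tpr[1] * tpr[2])
  structure(list(mu_ctr = mu_ctr, mu_all = mu_all,
                 cv_ctr = cv_ctr, cv_all = cv_all,
                 tp_product = tp_product, eta = eta,
                 score = eta * tp_product),
            class = "tstat_parts")
}

#' tStat score of a candidate solution
#'
#' Mean of per-gene [tstat_feature()] scores over the selected genes. The
#' mean (rather than a sum) keeps solutions of different sizes comparable.
#'
#' @param em an [expression_matrix()].
#' @param mask 0/1 selection vector over `em$gene_ids` with >= 1 gene selected.
#' @param ctr_label the control-group label (default: class1 of
#'   `em$class_order`).
#' @return a single non-negative score.
#' @export
score_solution <- function(em, mask, ctr_label = em$class_order[1]) {
  mask <- as.integer(mask)
  check_that(length(mask) == n_genes(em), "mask length must equal gene count")
  sel <- which(mask == 1L)
  check_that(length(sel) >= 1, "mask must select at least one gene")
  mean(vapply(sel, function(j) {
    tstat_feature(em$values[, j], em$labels, ctr_label)$score
  }, numeric(1)))
}

#' Pick the most informative archive entry by tStat score
#'
#' Scores every archive entry with [score_solution()] on the training matrix
#' and returns the maximum-score entry; ties go to the entry selecting fewer
#' genes, then to earlier archive order.
#'
#' @param archive a non-empty `mobpso_archive` whose masks align with
#'   `em$gene_ids`.
#' @param em the [expression_matrix()] the archive was produced from.
#' @param ctr_label the control-group label.
#' @return the winning [archive_entry()], with the gene identifiers in
#'   element `genes` and its score in element `score`.
#' @export
pick_best <- function(archive, em, ctr_label = em$class_order[1]) {
  check_that(length(archive$entries) >= 1, "archive is empty")
  scores <- vapply(archive$entries, function(e) {
    score_solution(em, e$mask, ctr_label)
  }, numeric(1))
  sizes <- vapply(archive$entries, function(e) sum(e$mask), integer(1))
  best <- order(-scores, sizes, seq_along(scores))[1]
  entry <- archive$entries[[best]]
  entry$genes <- em$gene_ids[entry$mask == 1L]
  entry$score <- scores[best]
  entry
}

#' Consensus markers across repeated runs
#'
#' Counts, per gene, in how many of the per-run selections it appears;
#' consensus markers are the genes appearing in at least `min_count` runs
#' (the reference protocol: at least 5 of 10 runs). When an expression matrix
#' is supplied, each consensus gene is called up- or down-regulated by the
#' sign of its class1 - class2 mean difference.
#'
#' @param run_selections list (one element per run) of selected gene-id
#'   character vectors.
#' @param min_count minimum number of runs a consensus gene must appear in.
#' @param em optional [expression_matrix()] used for the up/down calls.
#' @return list of class `marker_report`: `per_run`, `counts` (named integer
#'   vector), `consensus`, `regulation` (named "up"/"down", only with `em`),
#'   `n_runs`, `min_count`.
#' @export
consensus_markers <- function(run_selections, min_count = 5, em = NULL) {
  check_that(length(run_selections) >= 1, "need at least one run")
  run_selections <- lapply(run_selections, function(s) unique(as.character(s)))
  all_genes <- unique(unlist(run_selections))
  counts <- vapply(all_genes, function(g) {
    sum(vapply(run_selections, function(s) g %in% s, logical(1)))
  }, integer(1))
  names(counts) <- all_genes
  consensus <- all_genes[counts >= min_count]
  regulation <- NULL
  if (!is.null(em) && length(consensus)) {
    c1 <- em$labels == em$class_order[1]
    diffs <- vapply(consensus, function(g) {
      j <- match(g, em$gene_ids)
      mean(em$values[c1, j]) - mean(em$values[!c1, j])
    }, numeric(1))
    regulation <- ifelse(diffs > 0, "up", "down")
    names(regulation) <- consensus
  }
  structure(list(per_run = run_selections, counts = counts,
                 consensus = consensus, regulation = regulation,
                 n_runs = length(run_selections),
                 min_count = as.integer(min_count)),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker_report: %d runs, consensus threshold >= %d\n",
              x$n_runs, x$min_count))
  cat(sprintf("  %d consensus markers of %d genes ever selected\n",
              length(x$consensus), length(x$counts)))
  if (length(x$consensus)) {
    reg <- if (is.null(x$regulation)) rep("", length(x$consensus)) else
      paste0(" (", x$regulation, ")")
    cat(paste0("  ", x$consensus, ": ", x$counts[x$consensus], "/",
               x$n_runs, reg, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Full selection pipeline: rank, reduce, normalize, optimize, pick
#'
#' Chains the standard stages: SNR relevance on the raw matrix, top-k
#' selection by absolute SNR, min-max normalization, feature-graph
#' construction (node weights recomputed on the normalized matrix), the
#' multiobjective binary PSO, and the tStat-based final pick.
#'
#' @param em an [expression_matrix()].
#' @param top_k genes kept after SNR ranking (default 100); clamped to the
#'   available gene count.
#' @param params a [pso_params()].
#' @param ctr_label control-group label for the tStat score.
#' @return list with `genes` (selected marker ids), `best` (the picked
#'   [archive_entry()]), `archive`, `graph`, and `matrix` (the normalized
#'   top-k matrix the optimizer saw).
#' @export
select_markers <- function(em, top_k = 100, params = pso_params(),
                           ctr_label = em$class_order[1]) {
  rel <- relevance(em)
  k <- min(top_k, n_genes(em))
  reduced <- minmax_normalize(select_top_k(em, rel, k))
  graph <- build_graph(reduced)
  archive <- run_mobpso(graph, params)
  best <- pick_best(archive, reduced, ctr_label)
  list(genes = best$genes, best = best, archive = archive,
       graph = graph, matrix = reduced)
}
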
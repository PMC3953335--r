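#' Construct a two-class expression matrix
#'
#' The central data container: a samples x genes numeric matrix with one
#' binary class label per sample. `class_order` fixes which label is "class1"
#' (the first element); SNR signs and the default control group follow it.
#'
#' @param values numeric matrix, samples in rows, genes in columns. No missing
#'   values are allowed.
#' @param labels character (or coercible) vector of per-sample class tags with
#'   exactly two distinct values, each present at least twice.
#' @param gene_ids unique gene identifiers; defaults to `colnames(values)`.
#' @param class_order length-2 character vector fixing (class1, class2);
#'   defaults to the labels in order of first appearance.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `labels`, `class_order`.
#' @export
expression_matrix <- function(values, labels, gene_ids = colnames(values),
                              class_order = NULL) {
  values <- as.matrix(values)
  check_that(is.numeric(values), "expression values must be numeric")
  check_that(!anyNA(values), "expression matrix contains missing values")
  labels <- as.character(labels)
  check_that(length(labels) == nrow(values),
             "need exactly one class label per sample (row)")
  classes <- unique(labels)
  check_that(length(classes) == 2,
             sprintf("expected exactly two classes, found %d (%s)",
                     length(classes), paste(classes, collapse = ", ")))
  check_that(min(table(labels)) >= 2, "each class needs at least 2 samples")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  check_that(length(gene_ids) == ncol(values),
             "gene_ids length must equal the number of columns")
  check_that(!anyDuplicated(gene_ids),
             sprintf("duplicate gene identifiers: %s",
                     paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (is.null(class_order)) class_order <- classes
  class_order <- as.character(class_order)
  check_that(length(class_order) == 2 && setequal(class_order, classes),
             "class_order must be a permutation of the two observed labels")
  colnames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids, labels = labels,
                 class_order = class_order),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes; classes %s (n=%d) / %s (n=%d)\n",
              nrow(x$values), ncol(x$values),
              x$class_order[1], sum(x$labels == x$class_order[1]),
              x$class_order[2], sum(x$labels == x$class_order[2])))
  invisible(x)
}

n_genes <- function(em) length(em$gene_ids)

# row subset keeping metadata consistent
subset_samples <- function(em, idx) {
  expression_matrix(em$values[idx, , drop = FALSE], em$labels[idx],
                    em$gene_ids, em$class_order)
}

# column subset (gene ids or indices), preserving requested order
subset_genes <- function(em, genes) {
  if (is.character(genes)) {
    check_that(all(genes %in% em$gene_ids),
               "unknown gene identifiers in subset")
    idx <- match(genes, em$gene_ids)
  } else {
    idx <- genes
  }
  expression_matrix(em$values[, idx, drop = FALSE], em$labels,
                    em$gene_ids[idx], em$class_order)
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load a delimited expression matrix
#'
#' Reads a TSV/CSV file whose header row holds gene identifiers plus one label
#' column, one row per sample. The delimiter is inferred from the file
#' extension (`.csv` -> comma, anything else -> tab). Lines starting with `#`
#' (provenance headers written by the `cmd_*` commands) are skipped.
#'
#' @param path path to the delimited text file.
#' @param label_column name of the class-label column (default `"class"`).
#' @return an [expression_matrix()] with `class_order` set to the labels in
#'   order of first appearance.
#' @export
load_matrix <- function(path, label_column = "class") {
  check_that(file.exists(path), sprintf("input file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", quote = "\"")
  check_that(label_column %in% names(df),
             sprintf("label column '%s' not found in %s", label_column, path))
  gene_cols <- setdiff(seq_along(df), match(label_column, names(df)))
  gene_ids <- names(df)[gene_cols]
  check_that(!anyDuplicated(gene_ids),
             sprintf("duplicate gene identifiers in header of %s: %s", path,
                     paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  for (j in gene_cols) {
    if (!is.numeric(df[[j]])) {
      stop(sprintf("non-numeric expression value in column '%s' of %s",
                   names(df)[j], path), call. = FALSE)
    }
    if (anyNA(df[[j]])) {
      stop(sprintf("missing expression value in column '%s' (row %d) of %s",
                   names(df)[j], which(is.na(df[[j]]))[1], path), call. = FALSE)
    }
  }
  labels <- as.character(df[[label_column]])
  n_cls <- length(unique(labels))
  check_that(n_cls == 2,
             sprintf("label column '%s' must contain exactly two classes, found %d",
                     label_column, n_cls))
  expression_matrix(as.matrix(df[gene_cols]), labels, gene_ids)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [load_matrix()]: header = gene ids + label column, one sample per
#' row. Optional `header_lines` are written first, each prefixed with `#`.
#'
#' @param em an [expression_matrix()].
#' @param path output file; extension selects the delimiter as in
#'   [load_matrix()].
#' @param label_column label column name (default `"class"`).
#' @param header_lines optional character vector of provenance comments.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(em, path, label_column = "class", header_lines = NULL) {
  df <- as.data.frame(em$values, check.names = FALSE)
  df[[label_column]] <- em$labels
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Signal-to-noise ratio of one gene between two classes
#'
#' `(mean(c1) - mean(c2)) / (sd(c1) + sd(c2))` with sample (n-1) standard
#' deviations. When both classes are constant (zero pooled sd) the denominator
#' is replaced by `1e-12`, keeping the score finite while preserving the
#' ranking intent (a constant-but-shifted gene is maximally informative).
#'
#' @param values_c1,values_c2 numeric vectors of expression in class1/class2,
#'   each of length >= 2.
#' @return a single SNR value; positive means higher expression in class1.
#' @export
snr <- function(values_c1, values_c2) {
  check_that(length(values_c1) >= 2 && length(values_c2) >= 2,
             "snr needs at least 2 values per class")
  denom <- stats::sd(values_c1) + stats::sd(values_c2)
  if (denom == 0) denom <- 1e-12
  (mean(values_c1) - mean(values_c2)) / denom
}

#' Per-gene SNR relevance vector
#'
#' Applies [snr()] gene-wise, with class1 taken from `class_order[1]`.
#'
#' @param em an [expression_matrix()].
#' @return named numeric vector of SNR scores aligned with `em$gene_ids`.
#' @export
relevance <- function(em) {
  c1 <- em$labels == em$class_order[1]
  out <- vapply(seq_len(n_genes(em)), function(j) {
    snr(em$values[c1, j], em$values[!c1, j])
  }, numeric(1))
  names(out) <- em$gene_ids
  out
}

#' Keep the k genes with largest absolute SNR
#'
#' Genes are ranked by decreasing `|SNR|`; ties are broken by original column
#' order. The output matrix holds the selected genes in rank order with values
#' untouched.
#'
#' @param em an [expression_matrix()].
#' @param rel relevance vector aligned with `em$gene_ids`
#'   (see [relevance()]).
#' @param k number of genes to keep; the field default is 100.
#' @return an [expression_matrix()] with `k` columns.
#' @export
select_top_k <- function(em, rel, k = 100) {
  check_that(length(rel) == n_genes(em),
             "relevance vector length must equal the gene count")
  check_that(k >= 1 && k <= n_genes(em),
             sprintf("k must be in [1, %d], got %s", n_genes(em), k))
  ord <- order(-abs(rel), seq_along(rel))
  subset_genes(em, ord[seq_len(k)])
}

#' Min-max normalize each gene to [0, 1]
#'
#' Per gene: `(x - min) / (max - min)`. A constant gene maps to all zeros
#' (it carries no class information, and zero is reproducible).
#'
#' @param em an [expression_matrix()].
#' @return an [expression_matrix()] with every value in `[0, 1]`.
#' @export
minmax_normalize <- function(em) {
  v <- em$values
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  den <- hi - lo
  den[den == 0] <- 1  # constant gene: numerator is 0, column becomes 0
  v <- sweep(sweep(v, 2, lo, "-"), 2, den, "/")
  expression_matrix(v, em$labels, em$gene_ids, em$class_order)
}
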
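#' Pearson correlation of two gene profiles
#'
#' `cov(x, y) / sqrt(var(x) var(y))`, clamped into `[-1, 1]` against rounding.
#' If either vector has zero variance the coefficient is undefined; it is
#' defined as 0 here (neutral dissimilarity 1), which keeps downstream edge
#' weights finite.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  check_that(length(x) == length(y), "pearson: vectors differ in length")
  check_that(length(x) >= 2, "pearson needs at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  min(max(stats::cor(x, y), -1), 1)
}

# full correlation matrix with the same conventions as pearson():
# zero-variance columns give rho = 0, values clamped to [-1, 1], diag = 1.
cor_matrix <- function(values) {
  r <- suppressWarnings(stats::cor(values))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

#' Pairwise gene dissimilarity matrix
#'
#' Entry (i, j) is `1 - pearson(gene_i, gene_j)`: 0 for perfectly correlated
#' genes, 2 for perfectly anti-correlated ones. Diagonal is 0.
#'
#' @param em an [expression_matrix()] with >= 2 genes.
#' @return symmetric genes x genes matrix with entries in `[0, 2]`.
#' @export
dissimilarity_matrix <- function(em) {
  check_that(n_genes(em) >= 2, "need at least 2 genes for a dissimilarity matrix")
  d <- 1 - cor_matrix(em$values)
  diag(d) <- 0
  dimnames(d) <- list(em$gene_ids, em$gene_ids)
  d
}

#' Construct a feature-dissimilarity graph
#'
#' A complete weighted graph over genes: node weight = SNR relevance, edge
#' weight = 1 - Pearson correlation. Invariants (symmetry, zero diagonal,
#' edge weights in `[0, 2]`) are validated.
#'
#' @param node_weights per-gene relevance vector.
#' @param edge_weights symmetric dissimilarity matrix with zero diagonal.
#' @param gene_ids gene identifiers.
#' @return an object of class `feature_graph`.
#' @export
feature_graph <- function(node_weights, edge_weights, gene_ids = names(node_weights)) {
  edge_weights <- as.matrix(edge_weights)
  p <- length(node_weights)
  check_that(p >= 2, "a feature graph needs at least 2 nodes")
  check_that(all(dim(edge_weights) == c(p, p)),
             "edge_weights must be square with one row/column per gene")
  check_that(max(abs(edge_weights - t(edge_weights))) < 1e-9,
             "edge_weights must be symmetric")
  check_that(all(abs(diag(edge_weights)) < 1e-12),
             "edge_weights must have a zero diagonal")
  check_that(all(edge_weights >= -1e-9 & edge_weights <= 2 + 1e-9),
             "edge weights must lie in [0, 2]")
  edge_weights <- pmin(pmax(edge_weights, 0), 2)
  diag(edge_weights) <- 0
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  check_that(length(gene_ids) == p && !anyDuplicated(gene_ids),
             "gene_ids must be unique and match the node count")
  node_weights <- as.numeric(node_weights)
  check_that(all(is.finite(node_weights)), "node weights must be finite")
  names(node_weights) <- gene_ids
  structure(list(node_weights = node_weights, edge_weights = edge_weights,
                 gene_ids = as.character(gene_ids)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  p <- length(x$gene_ids)
  cat(sprintf("feature_graph: complete graph on %d genes (%d edges)\n",
              p, p * (p - 1) / 2))
  cat(sprintf("  node weight (SNR) range: [%.4g, %.4g]\n",
              min(x$node_weights), max(x$node_weights)))
  cat(sprintf("  edge weight (1-cor) range: [%.4g, %.4g]\n",
              min(x$edge_weights[upper.tri(x$edge_weights)]),
              max(x$edge_weights[upper.tri(x$edge_weights)])))
  invisible(x)
}

#' Build the feature-dissimilarity graph of an expression matrix
#'
#' Node weights are the absolute SNR values from [relevance()] and edge
#' weights come from [dissimilarity_matrix()], both computed on the matrix as
#' given (the usual pipeline hands in the top-k, min-max-normalized matrix).
#' The magnitude is used because the SNR sign only encodes which class is
#' up-regulated: marker sets contain both up- and down-regulated genes, and
#' maximizing the signed mean would discard the down-regulated tail that the
#' |SNR| ranking deliberately kept.
#'
#' @param em an [expression_matrix()] with >= 2 genes.
#' @return a [feature_graph()].
#' @export
build_graph <- function(em) {
  feature_graph(abs(relevance(em)), dissimilarity_matrix(em), em$gene_ids)
}

#' Average edge and node weight of a selected subgraph
#'
#' For a selection of m >= 2 genes: `avg_edge` is the mean dissimilarity over
#' all `choose(m, 2)` selected pairs, `avg_node` the mean SNR over the m
#' selected genes. These are the two quantities the optimizer maximizes.
#'
#' @param graph a [feature_graph()].
#' @param mask 0/1 selection vector, one bit per gene, with >= 2 ones.
#' @return list with `avg_edge` and `avg_node`.
#' @export
subgraph_objectives <- function(graph, mask) {
  mask <- as.integer(mask)
  check_that(length(mask) == length(graph$gene_ids),
             "mask length must equal the gene count")
  check_that(all(mask %in% c(0L, 1L)), "mask must be binary")
  sel <- which(mask == 1L)
  m <- length(sel)
  check_that(m >= 2, "degenerate selection: fewer than 2 genes selected")
  ew <- graph$edge_weights[sel, sel]
  list(avg_edge = sum(ew) / (m * (m - 1)),  # symmetric, zero diagonal
       avg_node = mean(graph$node_weights[sel]))
}

#' Dump a feature graph as plain-text tables
#'
#' Writes a node table (gene, snr) and an edge list (gene_i, gene_j, weight)
#' as TSV files.
#'
#' @param graph a [feature_graph()].
#' @param node_path,edge_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_graph <- function(graph, node_path, edge_path) {
  nodes <- data.frame(gene = graph$gene_ids, snr = unname(graph$node_weights))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(graph$edge_weights), arr.ind = TRUE)
  edges <- data.frame(gene_i = graph$gene_ids[idx[, 1]],
                      gene_j = graph$gene_ids[idx[, 2]],
                      weight = graph$edge_weights[idx])
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
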
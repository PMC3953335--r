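# Independent oracles and fixture builders used across the suite.

# Peel-off non-dominated sorting: repeatedly remove the set dominated by
# nobody. Quadratic and slow on purpose; independent of the package's
# dominance-count implementation.
oracle_fronts <- function(fit) {
  dominated_by_some <- function(i, idx) {
    for (j in idx) {
      if (j != i && all(fit[j, ] <= fit[i, ]) && any(fit[j, ] < fit[i, ])) {
        return(TRUE)
      }
    }
    FALSE
  }
  idx <- seq_len(nrow(fit))
  fronts <- list()
  while (length(idx)) {
    nd <- idx[!vapply(idx, dominated_by_some, logical(1), idx = idx)]
    fronts[[length(fronts) + 1L]] <- nd
    idx <- setdiff(idx, nd)
  }
  fronts
}

# Direct transcription of the crowding-distance formula, one objective at a
# time, without the package's vectorized bookkeeping.
oracle_crowding <- function(fit) {
  n <- nrow(fit)
  d <- numeric(n)
  for (m in 1:2) {
    ord <- order(fit[, m], seq_len(n))
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- fit[ord[n], m] - fit[ord[1], m]
    if (rng > 0 && n > 2) {
      for (pos in 2:(n - 1)) {
        i <- ord[pos]
        d[i] <- d[i] + (fit[ord[pos + 1], m] - fit[ord[pos - 1], m]) / rng
      }
    }
  }
  d
}

# All length-n binary masks with at least `min_bits` ones, as a matrix.
all_masks <- function(n, min_bits = 2) {
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(g) <- NULL
  g[rowSums(g) >= min_bits, , drop = FALSE]
}

# Naive per-mask subgraph objectives: explicit double loop over selected
# pairs, no matrix subsetting.
oracle_objectives <- function(vw, ew, mask) {
  sel <- which(mask == 1)
  m <- length(sel)
  tot <- 0
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      tot <- tot + ew[sel[a], sel[b]]
    }
  }
  list(avg_edge = tot / (m * (m - 1) / 2), avg_node = mean(vw[sel]))
}

# Vectorized mask fitness used only for exhaustive enumeration: quadratic
# form over the edge matrix (zero diagonal), independent of evaluate_mask.
enumerate_fitness <- function(graph, masks) {
  m <- rowSums(masks)
  pair_sum <- rowSums((masks %*% graph$edge_weights) * masks) / 2
  avg_edge <- pair_sum / (m * (m - 1) / 2)
  avg_node <- drop(masks %*% graph$node_weights) / m
  cbind(-avg_edge, -avg_node)
}

# Exhaustive Pareto front of a fitness set by sort-and-sweep on unique pairs
# (minimization): sorted by (f1, f2), a pair survives iff its f2 strictly
# undercuts everything before it.
oracle_pareto_pairs <- function(fit) {
  u <- unique(round(fit, 12))
  u <- u[order(u[, 1], u[, 2]), , drop = FALSE]
  best2 <- Inf
  keep <- logical(nrow(u))
  for (i in seq_len(nrow(u))) {
    if (u[i, 2] < best2) {
      keep[i] <- TRUE
      best2 <- u[i, 2]
    }
  }
  u[keep, , drop = FALSE]
}

# Small deterministic expression fixture: one strong planted gene (g2), one
# moderate, one constant, plus noise genes.
make_fixture_em <- function(n_per_class = 10, seed = 7) {
  mobpso:::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("a", "b"), each = n_per_class)
    g1 <- rnorm(n)
    g2 <- rnorm(n, sd = 0.5) + ifelse(labels == "a", 3, 0)
    g3 <- rep(1.5, n)
    g4 <- rnorm(n)
    expression_matrix(cbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4), labels)
  })
}

# A 12-gene synthetic instance small enough for exhaustive enumeration.
make_small_graph <- function(seed) {
  gen <- generate_expression(synthetic_spec(
    n_per_class = 25, n_relevant = 3, n_blocks = 1, block_size = 4,
    n_noise = 5, effect = 2, within_block_corr = 0.8, seed = seed))
  build_graph(minmax_normalize(gen$matrix))
}

random_entry <- function(n_genes, rng_max = 1) {
  archive_entry(as.integer(runif(n_genes) < 0.5) |> pmax(c(1, 1, rep(0, n_genes - 2))),
                runif(2, -rng_max, rng_max))
}

archive_masks <- function(archive) {
  vapply(archive$entries, function(e) paste(e$mask, collapse = ""), character(1))
}
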
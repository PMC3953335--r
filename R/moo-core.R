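#' Pareto dominance between two fitness pairs (minimization)
#'
#' `a` dominates `b` iff `a` is no worse in both objectives and strictly
#' better in at least one.
#'
#' @param a,b numeric length-2 fitness vectors `(f1, f2)`.
#' @return logical.
#' @export
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

# fitness list/matrix coercion: rows = solutions, 2 columns
as_fitness_matrix <- function(fitnesses) {
  if (is.matrix(fitnesses)) {
    check_that(ncol(fitnesses) == 2, "fitness matrix must have 2 columns")
    return(fitnesses)
  }
  do.call(rbind, lapply(fitnesses, function(f) {
    check_that(length(f) == 2, "each fitness must have 2 objectives")
    as.numeric(f)
  }))
}

# D[i, j] = TRUE iff solution i dominates solution j (vectorized)
dominance_matrix <- function(fit) {
  f1 <- fit[, 1]; f2 <- fit[, 2]
  outer(f1, f1, "<=") & outer(f2, f2, "<=") &
    (outer(f1, f1, "<") | outer(f2, f2, "<"))
}

#' Fast non-dominated sorting into Pareto fronts
#'
#' Partitions solutions into successive fronts: front 1 holds everything
#' dominated by nobody, front r everything dominated only by members of
#' earlier fronts. Uses dominance-count bookkeeping over a precomputed
#' pairwise dominance matrix.
#'
#' @param fitnesses list of length-2 numeric vectors, or an n x 2 matrix.
#' @return list of integer index vectors, one per front, in rank order.
#' @export
non_dominated_sort <- function(fitnesses) {
  fit <- as_fitness_matrix(fitnesses)
  n <- nrow(fit)
  if (n == 0) return(list())
  D <- dominance_matrix(fit)
  counts <- colSums(D)
  fronts <- list()
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    front <- which(remaining & counts == 0)
    fronts[[length(fronts) + 1L]] <- front
    remaining[front] <- FALSE
    if (any(remaining)) {
      counts <- counts - colSums(D[front, , drop = FALSE])
    }
  }
  fronts
}

#' Crowding distance within one Pareto front
#'
#' Per objective the front is sorted; boundary members get `Inf` and each
#' interior member accumulates `(next - previous) / (max - min)`. An objective
#' with zero range contributes 0. Larger values mark less crowded (more
#' diverse) solutions.
#'
#' @param front_fitnesses list of length-2 fitness vectors or an n x 2 matrix
#'   of mutually non-dominated solutions.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(front_fitnesses) {
  fit <- as_fitness_matrix(front_fitnesses)
  n <- nrow(fit)
  if (n == 0) return(numeric(0))
  d <- numeric(n)
  for (m in 1:2) {
    ord <- order(fit[, m], seq_len(n))
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- fit[ord[n], m] - fit[ord[1], m]
    if (n > 2 && rng > 0) {
      inner <- ord[2:(n - 1)]
      d[inner] <- d[inner] +
        (fit[ord[3:n], m] - fit[ord[1:(n - 2)], m]) / rng
    }
  }
  d
}

#' Archive entry: selection mask plus its fitness
#'
#' @param mask binary selection vector.
#' @param fitness finite length-2 fitness `(f1, f2)`.
#' @return list of class `archive_entry`.
#' @export
archive_entry <- function(mask, fitness) {
  fitness <- as.numeric(fitness)
  check_that(length(fitness) == 2 && all(is.finite(fitness)),
             "archive entries need finite length-2 fitness")
  structure(list(mask = as.integer(mask), fitness = fitness),
            class = "archive_entry")
}

#' Create an empty bounded archive of non-dominated solutions
#'
#' @param cap maximum number of entries retained (default 100); overflow is
#'   resolved by keeping the entries with the largest crowding distance.
#' @return object of class `mobpso_archive`.
#' @export
new_archive <- function(cap = 100) {
  check_that(cap >= 1, "archive cap must be positive")
  structure(list(entries = list(), cap = as.integer(cap)),
            class = "mobpso_archive")
}

#' @export
print.mobpso_archive <- function(x, ...) {
  cat(sprintf("mobpso_archive: %d non-dominated entries (cap %d)\n",
              length(x$entries), x$cap))
  if (length(x$entries)) {
    fit <- archive_fitness(x)
    cat(sprintf("  f1 in [%.4g, %.4g]; f2 in [%.4g, %.4g]\n",
                min(fit[, 1]), max(fit[, 1]), min(fit[, 2]), max(fit[, 2])))
  }
  invisible(x)
}

archive_fitness <- function(archive) {
  as_fitness_matrix(lapply(archive$entries, `[[`, "fitness"))
}

mask_key <- function(mask) paste(mask, collapse = "")

#' Merge candidate solutions into a bounded non-dominated archive
#'
#' The candidates are merged with the current entries, exact duplicate masks
#' are collapsed (first occurrence wins), and only the first non-dominated
#' front of the union is retained. If that front exceeds the cap, the `cap`
#' members with the largest crowding distance survive (ties broken by earlier
#' insertion). Entries with non-finite fitness (infeasible masks) are ignored.
#'
#' @param archive a [new_archive()] result or prior update.
#' @param candidates list of [archive_entry()] objects.
#' @return the updated archive.
#' @export
update_archive <- function(archive, candidates = list()) {
  feasible <- Filter(function(e) all(is.finite(e$fitness)), candidates)
  entries <- c(archive$entries, feasible)
  if (!length(entries)) return(archive)
  keys <- vapply(entries, function(e) mask_key(e$mask), character(1))
  entries <- entries[!duplicated(keys)]
  fit <- as_fitness_matrix(lapply(entries, `[[`, "fitness"))
  front1 <- which(colSums(dominance_matrix(fit)) == 0)
  if (length(front1) > archive$cap) {
    cd <- crowding_distance(fit[front1, , drop = FALSE])
    keep <- order(-cd, seq_along(cd))[seq_len(archive$cap)]
    front1 <- front1[sort(keep)]  # preserve insertion order
  }
  archive$entries <- entries[front1]
  archive
}

#' Tabulate an archive
#'
#' @param x a `mobpso_archive`.
#' @param gene_ids optional gene identifiers used to render the selected set.
#' @param ... unused.
#' @return data.frame with columns `f1`, `f2`, `n_selected`, `genes`
#'   (semicolon-joined).
#' @export
as.data.frame.mobpso_archive <- function(x, gene_ids = NULL, ...) {
  if (!length(x$entries)) {
    return(data.frame(f1 = numeric(0), f2 = numeric(0),
                      n_selected = integer(0), genes = character(0)))
  }
  fit <- archive_fitness(x)
  genes <- vapply(x$entries, function(e) {
    sel <- which(e$mask == 1L)
    ids <- if (is.null(gene_ids)) as.character(sel) else gene_ids[sel]
    paste(ids, collapse = ";")
  }, character(1))
  data.frame(f1 = fit[, 1], f2 = fit[, 2],
             n_selected = vapply(x$entries, function(e) sum(e$mask), integer(1)),
             genes = genes, stringsAsFactors = FALSE)
}

#' Write an archive as TSV
#'
#' @param archive a `mobpso_archive`.
#' @param path output TSV path.
#' @param gene_ids optional gene identifiers for the `genes` column.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path, gene_ids = NULL, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(archive, gene_ids = gene_ids), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
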
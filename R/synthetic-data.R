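#' Specification for a synthetic two-class expression matrix
#'
#' Describes planted structure: `n_relevant` independent class-separating genes
#' (`REL_i`), `n_blocks` redundant blocks of `block_size` genes each
#' (`BLK_b_j`, all correlated with relevant prototype gene `REL_b`), and
#' `n_noise` class-independent genes (`NSE_k`). Defaults are the package's
#' reference study conditions: 50 samples per class, 5 relevant genes, two
#' 5-gene redundant blocks, 40 noise genes, a 2-sd class shift and 0.8 target
#' within-block correlation.
#'
#' @param n_per_class samples per class (>= 2).
#' @param n_relevant count of independent class-separating genes (>= 1).
#' @param n_blocks count of redundant blocks; must not exceed `n_relevant`
#'   since block `b` is seeded from prototype `REL_b`.
#' @param block_size genes per block (>= 1).
#' @param n_noise count of class-independent genes (>= 1).
#' @param effect between-class mean shift of relevant genes, in within-class
#'   standard-deviation units (>= 0). Applied to class2.
#' @param within_block_corr target pairwise correlation between a block member
#'   and its prototype's expression, in `[0, 1)`.
#' @param seed integer RNG seed; same spec + seed reproduces the matrix
#'   bit-for-bit.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 50, n_relevant = 5, n_blocks = 2,
                           block_size = 5, n_noise = 40, effect = 2,
                           within_block_corr = 0.8, seed = 1) {
  counts <- c(n_per_class = n_per_class, n_relevant = n_relevant,
              n_blocks = n_blocks, block_size = block_size, n_noise = n_noise)
  for (nm in names(counts)) {
    check_that(is.numeric(counts[[nm]]) && length(counts[[nm]]) == 1 &&
                 counts[[nm]] >= 1 && counts[[nm]] == round(counts[[nm]]),
               sprintf("invalid spec: %s must be a positive integer", nm))
  }
  check_that(n_per_class >= 2, "invalid spec: n_per_class must be >= 2")
  check_that(n_blocks <= n_relevant,
             "invalid spec: n_blocks must not exceed n_relevant (block b uses prototype REL_b)")
  check_that(effect >= 0, "invalid spec: effect must be >= 0")
  check_that(within_block_corr >= 0 && within_block_corr < 1,
             "invalid spec: within_block_corr must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_relevant = as.integer(n_relevant),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 n_noise = as.integer(n_noise),
                 effect = effect,
                 within_block_corr = within_block_corr,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class expression matrix with planted truth
#'
#' Base distribution is unit Gaussian noise per gene. Relevant genes and block
#' prototypes get a `+effect` mean shift in class2. Block member `BLK_b_j` is
#' `rho * REL_b + sqrt(1 - rho^2) * fresh noise` with
#' `rho = within_block_corr`, which gives an analytically controlled expected
#' correlation with the prototype. Noise genes are identically distributed in
#' both classes. Draw order is fixed (relevant genes, then blocks, then noise)
#' so identical spec + seed reproduces the matrix exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements
#'   * `matrix`: an [expression_matrix()] of `2 * n_per_class` samples
#'     (labels `class1`/`class2`) by
#'     `n_relevant + n_blocks * block_size + n_noise` genes;
#'   * `truth`: planted truth with `relevant_ids` (REL genes),
#'     `block_membership` (named integer vector mapping BLK gene -> block
#'     index), and `noise_ids`.
#' @export
generate_expression <- function(spec) {
  check_that(inherits(spec, "synthetic_spec"),
             "spec must be created by synthetic_spec()")
  with_seed(spec$seed, {
    n <- 2L * spec$n_per_class
    labels <- rep(c("class1", "class2"), each = spec$n_per_class)
    shift <- ifelse(labels == "class2", spec$effect, 0)

    rel <- matrix(stats::rnorm(n * spec$n_relevant), nrow = n) + shift
    rel_ids <- paste0("REL_", seq_len(spec$n_relevant))

    rho <- spec$within_block_corr
    blk_cols <- list()
    blk_ids <- character(0)
    blk_membership <- integer(0)
    for (b in seq_len(spec$n_blocks)) {
      proto <- rel[, b]
      for (j in seq_len(spec$block_size)) {
        blk_cols[[length(blk_cols) + 1L]] <-
          rho * proto + sqrt(1 - rho^2) * stats::rnorm(n)
        id <- paste0("BLK_", b, "_", j)
        blk_ids <- c(blk_ids, id)
        blk_membership[id] <- b
      }
    }
    blk <- do.call(cbind, blk_cols)

    nse <- matrix(stats::rnorm(n * spec$n_noise), nrow = n)
    nse_ids <- paste0("NSE_", seq_len(spec$n_noise))

    values <- cbind(rel, blk, nse)
    em <- expression_matrix(values, labels,
                            gene_ids = c(rel_ids, blk_ids, nse_ids),
                            class_order = c("class1", "class2"))
    truth <- list(relevant_ids = rel_ids,
                  block_membership = blk_membership,
                  noise_ids = nse_ids)
    list(matrix = em, truth = truth)
  })
}
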
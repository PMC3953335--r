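#' Parameters of the multiobjective binary particle swarm optimizer
#'
#' Defaults are the reference settings of the method: swarm of 25 particles,
#' 100 iterations, cognitive and social factors `c1 = c2 = 2`, inertia weight
#' decreasing linearly from 0.9 to 0.4, velocity clamp 6 and archive cap 100.
#'
#' @param swarm_size number of particles.
#' @param iterations number of swarm iterations.
#' @param c1,c2 cognitive and social acceleration factors.
#' @param w_max,w_min endpoints of the linearly decreasing inertia schedule
#'   (`w_max >= w_min > 0`).
#' @param v_max symmetric velocity clamp (> 0); keeps the sigmoid away from
#'   saturation.
#' @param archive_cap maximum archive size.
#' @param seed integer RNG seed for the whole run.
#' @param delta optional fixed discretization threshold: when non-`NULL` a bit
#'   is set iff `sigmoid(v) > delta` instead of the default stochastic rule
#'   (bit set with probability `sigmoid(v)`).
#' @return object of class `pso_params`.
#' @export
pso_params <- function(swarm_size = 25, iterations = 100, c1 = 2, c2 = 2,
                       w_max = 0.9, w_min = 0.4, v_max = 6,
                       archive_cap = 100, seed = 1, delta = NULL) {
  check_that(swarm_size >= 1, "swarm_size must be positive")
  check_that(iterations >= 1, "iterations must be positive")
  check_that(w_max >= w_min && w_min > 0, "need w_max >= w_min > 0")
  check_that(v_max > 0, "v_max must be positive")
  check_that(archive_cap >= 1, "archive_cap must be positive")
  if (!is.null(delta)) {
    check_that(delta > 0 && delta < 1, "delta must lie in (0, 1)")
  }
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 v_max = v_max, archive_cap = as.integer(archive_cap),
                 seed = as.integer(seed), delta = delta),
            class = "pso_params")
}

new_particle <- function(position, velocity, fitness) {
  list(position = position, velocity = velocity, fitness = fitness,
       pbest_position = position, pbest_fitness = fitness)
}

#' Initialize a binary particle swarm
#'
#' Each bit of each particle is a fair coin; all velocities start at zero and
#' each particle's personal best is its initial position. Draws `swarm_size`
#' blocks of `n_genes` uniforms from the current RNG stream (call under a
#' seeded context, as [run_mobpso()] does).
#'
#' @param n_genes number of bits per particle (>= 2).
#' @param params a [pso_params()].
#' @return list of particles (position, velocity, fitness, pbest).
#' @export
initialize_swarm <- function(n_genes, params) {
  check_that(n_genes >= 2, "need at least 2 genes")
  lapply(seq_len(params$swarm_size), function(i) {
    pos <- as.integer(stats::runif(n_genes) < 0.5)
    new_particle(pos, numeric(n_genes), c(Inf, Inf))
  })
}

#' Linearly decreasing inertia weight
#'
#' `w(t) = w_max - (w_max - w_min) * t / (iterations - 1)` for 0-based
#' iteration index `t`; constant `w_max` for a single-iteration run.
#'
#' @param t 0-based iteration index in `[0, iterations)`.
#' @param params a [pso_params()].
#' @return inertia weight.
#' @export
inertia_weight <- function(t, params) {
  check_that(t >= 0 && t < params$iterations, "iteration index out of range")
  if (params$iterations == 1) return(params$w_max)
  params$w_max - (params$w_max - params$w_min) * t / (params$iterations - 1)
}

#' Velocity update of one particle
#'
#' Per cell j: `v' = w * v + c1 * r1 * (pbest_j - x_j) + c2 * r2 * (gbest_j -
#' x_j)` with fresh `r1`, `r2 ~ U(0, 1)` per cell (the `r1` vector is drawn
#' before the `r2` vector), then clamped to `[-v_max, v_max]`.
#'
#' @param particle a swarm particle.
#' @param gbest global-guide selection mask (an archive member).
#' @param w inertia weight for this iteration.
#' @param params a [pso_params()].
#' @return clamped velocity vector.
#' @export
update_velocity <- function(particle, gbest, w, params) {
  n <- length(particle$velocity)
  check_that(length(gbest) == n, "gbest length must match the particle")
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  v <- w * particle$velocity +
    params$c1 * r1 * (particle$pbest_position - particle$position) +
    params$c2 * r2 * (gbest - particle$position)
  pmin(pmax(v, -params$v_max), params$v_max)
}

#' Discretize velocities into a binary position
#'
#' Default rule: bit j is set iff `u_j < S(v_j)` with `S(v) = 1 / (1 + e^-v)`
#' and fresh `u_j ~ U(0, 1)` — the standard sigmoid transfer of binary PSO.
#' With a fixed threshold `delta`, the deterministic rule
#' `bit = 1 iff S(v) > delta` is used instead and no uniforms are drawn.
#'
#' @param velocity real velocity vector.
#' @param delta optional fixed threshold in (0, 1); `NULL` for the stochastic
#'   sigmoid rule.
#' @return integer 0/1 selection mask.
#' @export
update_position <- function(velocity, delta = NULL) {
  s <- stats::plogis(velocity)
  if (is.null(delta)) {
    as.integer(stats::runif(length(velocity)) < s)
  } else {
    as.integer(s > delta)
  }
}

#' Fitness of a selection mask on a feature graph
#'
#' Both subgraph objectives are maximized; the optimizer minimizes, so
#' `f1 = -avg_edge` and `f2 = -avg_node` (negation is total and strictly
#' decreasing, hence Pareto-equivalent to any other decreasing transform).
#' Masks selecting fewer than 2 genes are infeasible and get `(Inf, Inf)`,
#' which is dominated by every feasible fitness.
#'
#' @param graph a [feature_graph()].
#' @param mask 0/1 selection vector.
#' @return length-2 numeric fitness `(f1, f2)`.
#' @export
evaluate_mask <- function(graph, mask) {
  if (sum(mask == 1) < 2) return(c(Inf, Inf))
  obj <- subgraph_objectives(graph, mask)
  c(-obj$avg_edge, -obj$avg_node)
}

#' Personal-best update under Pareto dominance
#'
#' The freshly evaluated position replaces the personal best if it dominates
#' it and is kept out if dominated; when the two are mutually non-dominated a
#' fair coin decides (one uniform draw).
#'
#' @param particle particle whose `fitness` was just evaluated.
#' @return the particle with updated `pbest_position` / `pbest_fitness`.
#' @export
update_pbest <- function(particle) {
  if (dominates(particle$fitness, particle$pbest_fitness)) {
    particle$pbest_position <- particle$position
    particle$pbest_fitness <- particle$fitness
  } else if (!dominates(particle$pbest_fitness, particle$fitness)) {
    if (stats::runif(1) < 0.5) {
      particle$pbest_position <- particle$position
      particle$pbest_fitness <- particle$fitness
    }
  }
  particle
}

#' Draw a global guide from the archive
#'
#' Uniform draw over archive entries; called fresh for every particle at every
#' iteration so different particles follow different non-dominated guides.
#'
#' @param archive a non-empty `mobpso_archive`.
#' @return the selected entry's mask.
#' @export
select_gbest <- function(archive) {
  check_that(length(archive$entries) >= 1, "cannot draw gbest from an empty archive")
  archive$entries[[sample.int(length(archive$entries), 1)]]$mask
}

#' Run the multiobjective binary PSO on a feature graph
#'
#' The full optimizer loop: initialize the swarm (fair-coin bits, zero
#' velocities), evaluate, seed the archive with the first non-dominated front
#' of the initial swarm, then per iteration compute the inertia weight and,
#' per particle, draw a gbest from the archive, update velocity then position,
#' evaluate, update the personal best, and finally merge the generation's
#' positions into the archive. Per-particle RNG draw order is fixed
#' (gbest draw, r1 vector, r2 vector, position uniforms, optional pbest coin),
#' so a run is bit-for-bit reproducible from `params$seed`.
#'
#' @param graph a [feature_graph()] with >= 2 genes.
#' @param params a [pso_params()].
#' @return the final `mobpso_archive` (mutually non-dominated, each entry
#'   selecting >= 2 genes), with a per-iteration log `data.frame`
#'   (`iteration`, `archive_size`, `best_f1`, `best_f2`) in attribute `"log"`.
#' @export
run_mobpso <- function(graph, params = pso_params()) {
  check_that(inherits(graph, "feature_graph"), "graph must be a feature_graph")
  n <- length(graph$gene_ids)
  with_seed(params$seed, {
    swarm <- initialize_swarm(n, params)
    swarm <- lapply(swarm, function(p) {
      p$fitness <- evaluate_mask(graph, p$position)
      p$pbest_fitness <- p$fitness
      p
    })
    archive <- update_archive(
      new_archive(params$archive_cap),
      lapply(Filter(function(p) all(is.finite(p$fitness)), swarm),
             function(p) archive_entry(p$position, p$fitness)))
    log <- vector("list", params$iterations + 1L)
    log[[1]] <- log_record(0L, archive)
    for (t in seq_len(params$iterations)) {
      w <- inertia_weight(t - 1L, params)
      generation <- vector("list", length(swarm))
      for (i in seq_along(swarm)) {
        p <- swarm[[i]]
        gbest <- select_gbest(archive)
        p$velocity <- update_velocity(p, gbest, w, params)
        p$position <- update_position(p$velocity, params$delta)
        p$fitness <- evaluate_mask(graph, p$position)
        p <- update_pbest(p)
        swarm[[i]] <- p
        if (all(is.finite(p$fitness))) {
          generation[[i]] <- archive_entry(p$position, p$fitness)
        }
      }
      archive <- update_archive(archive, Filter(Negate(is.null), generation))
      log[[t + 1L]] <- log_record(t, archive)
    }
    attr(archive, "log") <- do.call(rbind, log)
    attr(archive, "params") <- params
    archive
  })
}

log_record <- function(iteration, archive) {
  fit <- if (length(archive$entries)) archive_fitness(archive) else
    matrix(NA_real_, 0, 2)
  data.frame(iteration = iteration,
             archive_size = length(archive$entries),
             best_f1 = if (nrow(fit)) min(fit[, 1]) else NA_real_,
             best_f2 = if (nrow(fit)) min(fit[, 2]) else NA_real_)
}
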
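test_that("parameter defaults are the reference settings and are validated", {
  p <- pso_params()
  expect_equal(p$swarm_size, 25L)
  expect_equal(p$iterations, 100L)
  expect_equal(p$c1, 2)
  expect_equal(p$c2, 2)
  expect_equal(p$w_max, 0.9)
  expect_equal(p$w_min, 0.4)
  expect_equal(p$v_max, 6)
  expect_equal(p$archive_cap, 100L)
  expect_null(p$delta)
  expect_error(pso_params(w_max = 0.3, w_min = 0.4), "w_max")
  expect_error(pso_params(v_max = 0), "v_max")
  expect_error(pso_params(delta = 1.5), "delta")
})

test_that("swarm initialization is reproducible, zero-velocity and fair-coin", {
  p <- pso_params(swarm_size = 400, seed = 42)
  a <- mobpso:::with_seed(42, initialize_swarm(25, p))
  b <- mobpso:::with_seed(42, initialize_swarm(25, p))
  expect_identical(a, b)
  expect_true(all(vapply(a, function(q) all(q$velocity == 0), logical(1))))
  expect_true(all(vapply(a, function(q) identical(q$pbest_position, q$position),
                         logical(1))))
  bits <- unlist(lapply(a, `[[`, "position"))  # 10^4 bits
  expect_length(bits, 10000)
  frac <- mean(bits)
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
})

test_that("inertia weight decreases linearly between its endpoints", {
  p <- pso_params(iterations = 100)
  expect_equal(inertia_weight(0, p), 0.9)
  expect_equal(inertia_weight(99, p), 0.4)
  p101 <- pso_params(iterations = 101)
  expect_equal(inertia_weight(50, p101), 0.65)
  expect_error(inertia_weight(101, p101), "out of range")
})

test_that("velocity update follows the per-cell formula and the clamp", {
  p <- pso_params(seed = 1)
  still <- list(position = c(1L, 0L), velocity = c(0, 0),
                pbest_position = c(1L, 0L))
  expect_equal(mobpso:::with_seed(5, update_velocity(still, c(1L, 0L), 0.7, p)),
               c(0, 0))
  # reproduce the r1-then-r2 draw order independently
  part <- list(position = c(0L, 1L, 0L), velocity = c(1, -2, 0.5),
               pbest_position = c(1L, 1L, 1L))
  gbest <- c(1L, 0L, 0L)
  got <- mobpso:::with_seed(9, update_velocity(part, gbest, 0.6, p))
  want <- mobpso:::with_seed(9, {
    r1 <- runif(3); r2 <- runif(3)
    v <- 0.6 * part$velocity + 2 * r1 * (part$pbest_position - part$position) +
      2 * r2 * (gbest - part$position)
    pmin(pmax(v, -6), 6)
  })
  expect_equal(got, want)
  # clamp contract under extreme accelerations
  wild <- pso_params(c1 = 50, c2 = 50)
  for (s in 1:20) {
    v <- mobpso:::with_seed(s, update_velocity(part, gbest, 0.9, wild))
    expect_true(all(abs(v) <= wild$v_max))
  }
})

test_that("sigmoid discretization sets bits with probability S(v)", {
  freq0 <- mean(mobpso:::with_seed(7, update_position(rep(0, 10000))))
  expect_gte(freq0, 0.47)
  expect_lte(freq0, 0.53)
  freq6 <- mean(mobpso:::with_seed(8, update_position(rep(6, 10000))))
  expect_gte(freq6, plogis(6) - 0.01)  # 1/(1+e^-6) = 0.99753
  expect_true(all(mobpso:::with_seed(9, update_position(rep(-50, 100))) == 0))
  # fixed-threshold variant is deterministic
  expect_equal(update_position(c(0, 0), delta = 0.4), c(1L, 1L))
  expect_equal(update_position(c(0, 0), delta = 0.6), c(0L, 0L))
})

test_that("mask fitness negates the subgraph averages and flags infeasibility", {
  ew <- matrix(0, 3, 3)
  ew[1, 2] <- ew[2, 1] <- 1.2
  ew[1, 3] <- ew[3, 1] <- 0.6
  ew[2, 3] <- ew[3, 2] <- 0.9
  g <- feature_graph(c(0.9, 0.3, 0.6), ew, c("a", "b", "c"))
  expect_equal(evaluate_mask(g, c(1, 1, 1)), c(-0.9, -0.6))
  expect_equal(evaluate_mask(g, c(0, 0, 0)), c(Inf, Inf))
  expect_equal(evaluate_mask(g, c(0, 1, 0)), c(Inf, Inf))
  # better in both raw averages => dominating fitness
  a <- subgraph_objectives(g, c(1, 0, 1))
  b <- subgraph_objectives(g, c(0, 1, 1))
  stopifnot(a$avg_edge < b$avg_edge)  # fixture sanity
  expect_true(dominates(evaluate_mask(g, c(0, 1, 1)), evaluate_mask(g, c(1, 0, 1))) ==
                (b$avg_edge > a$avg_edge && b$avg_node > a$avg_node))
})

test_that("personal best follows dominance with a fair coin on ties", {
  base <- list(position = c(1L, 1L), velocity = c(0, 0),
               fitness = c(-1, -1), pbest_position = c(0L, 1L),
               pbest_fitness = c(-0.5, -0.5))
  up <- update_pbest(base)
  expect_equal(up$pbest_fitness, c(-1, -1))
  worse <- base
  worse$fitness <- c(Inf, Inf)
  expect_equal(update_pbest(worse)$pbest_fitness, c(-0.5, -0.5))
  tied <- base
  tied$fitness <- c(-1, 0)  # mutually non-dominated with (-0.5, -0.5)
  replaced <- mobpso:::with_seed(11, {
    mean(vapply(1:10000, function(i) {
      identical(update_pbest(tied)$pbest_fitness, c(-1, 0))
    }, logical(1)))
  })
  expect_gte(replaced, 0.47)
  expect_lte(replaced, 0.53)
})

test_that("gbest is a uniform draw over archive members", {
  single <- update_archive(new_archive(5), list(archive_entry(c(1, 1, 0), c(0, 0))))
  expect_equal(select_gbest(single), c(1L, 1L, 0L))
  arch <- update_archive(new_archive(5), list(
    archive_entry(c(1, 1, 0, 0), c(0, 3)),
    archive_entry(c(0, 1, 1, 0), c(1, 2)),
    archive_entry(c(0, 0, 1, 1), c(2, 1)),
    archive_entry(c(1, 0, 0, 1), c(3, 0))))
  keys <- archive_masks(arch)
  draws <- mobpso:::with_seed(13, {
    vapply(1:10000, function(i) paste(select_gbest(arch), collapse = ""), "")
  })
  expect_true(all(draws %in% keys))
  freqs <- table(draws) / 10000
  expect_true(all(freqs >= 0.22 & freqs <= 0.28))
  expect_error(select_gbest(new_archive(5)), "empty archive")
})

test_that("a full run is reproducible and satisfies the archive contract", {
  g <- make_small_graph(seed = 31)
  p <- pso_params(swarm_size = 10, iterations = 30, seed = 5)
  a <- run_mobpso(g, p)
  b <- run_mobpso(g, p)
  expect_identical(lapply(a$entries, unclass), lapply(b$entries, unclass))
  expect_identical(attr(a, "log"), attr(b, "log"))
  expect_true(all(vapply(a$entries, function(e) sum(e$mask) >= 2, logical(1))))
  fit <- do.call(rbind, lapply(a$entries, `[[`, "fitness"))
  for (i in seq_len(nrow(fit))) {
    for (j in seq_len(nrow(fit))) {
      if (i != j) expect_false(dominates(fit[i, ], fit[j, ]))
    }
  }
  log <- attr(a, "log")
  expect_equal(log$iteration, 0:30)
  # elitism: archive extremes never regress
  expect_true(all(diff(log$best_f1) <= 1e-12))
  expect_true(all(diff(log$best_f2) <= 1e-12))
})

test_that("the fixed-threshold discretization variant runs and is reproducible", {
  g <- make_small_graph(seed = 31)
  p <- pso_params(swarm_size = 8, iterations = 10, seed = 3, delta = 0.5)
  a <- run_mobpso(g, p)
  b <- run_mobpso(g, p)
  expect_identical(lapply(a$entries, unclass), lapply(b$entries, unclass))
  expect_gte(length(a$entries), 1)
})

test_that("the archive converges toward the exhaustive Pareto front with budget", {
  masks <- all_masks(12)
  attained <- vapply(1:10, function(s) {
    g <- make_small_graph(seed = s)
    true_front <- oracle_pareto_pairs(enumerate_fitness(g, masks))
    arch <- run_mobpso(g, pso_params(swarm_size = 10, iterations = 100, seed = s))
    fit <- do.call(rbind, lapply(arch$entries, `[[`, "fitness"))
    hits <- apply(true_front, 1, function(tf) {
      any(abs(fit[, 1] - tf[1]) < 1e-9 & abs(fit[, 2] - tf[2]) < 1e-9)
    })
    # nothing in the archive may beat the exhaustive front
    consistent <- apply(fit, 1, function(f) {
      any(true_front[, 1] <= f[1] + 1e-9 & true_front[, 2] <= f[2] + 1e-9)
    })
    expect_true(all(consistent))
    mean(hits)
  }, numeric(1))
  expect_gte(sum(attained >= 0.5), 8)
  expect_gte(mean(attained), 0.6)
})

test_that("any strictly decreasing transform yields the same Pareto-optimal masks", {
  g <- make_small_graph(seed = 17)
  keep <- 1:8
  g8 <- feature_graph(g$node_weights[keep], g$edge_weights[keep, keep],
                      g$gene_ids[keep])
  masks <- all_masks(8)
  fit_neg <- enumerate_fitness(g8, masks)
  raw <- cbind(-fit_neg[, 1], -fit_neg[, 2])  # the maximized averages
  fit_exp <- cbind(exp(-raw[, 1]), exp(-raw[, 2]))  # another decreasing transform
  pareto_idx <- function(fit) sort(oracle_fronts(fit)[[1]])
  expect_equal(pareto_idx(fit_neg), pareto_idx(fit_exp))
})
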
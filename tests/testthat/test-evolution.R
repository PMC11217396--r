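test_that("single-link mutation changes exactly one entry by the drawn factor", {
  set.seed(1)
  net <- init_network(6, 4, 1)
  forced <- mutate_link(net, xi = 1)
  expect_identical(forced$matrices, net$matrices)
  for (i in 1:50) {
    mut <- mutate_link(net)
    diffs <- mapply(function(a, b) sum(a != b), mut$matrices, net$matrices)
    expect_equal(sum(diffs), 1)
  }
})

test_that("mutation multipliers match the configured gaussian and stay positive", {
  set.seed(2)
  net <- all_ones_net(1, 1)
  xi <- replicate(1e5, mutate_link(net)$matrices[[1]][1, 1])
  expect_equal(mean(xi), 1, tolerance = 0.01)
  expect_equal(var(xi), 0.1, tolerance = 0.02)
  expect_true(all(xi > 0))
})

test_that("regularized fitness adds the configured link cost", {
  net <- all_ones_net(2, 2)
  G <- compose_network(net)
  expect_equal(regularized_fitness(net, G, "none", 5),
               network_fitness(net, G))
  expect_equal(regularized_fitness(net, G, "L1", 1), -8) # 8 unit links
  expect_equal(regularized_fitness(net, G, "L2", 1), -8)
  expect_equal(regularized_fitness(net, G, "L1", 0.5), -4)
  expect_error(regularized_fitness(net, G, "L1", -1), "nonnegative")
})

test_that("tournament selection favors fitter individuals", {
  set.seed(3)
  pool <- as.list(seq_len(40))
  fit <- rep(0, 40)
  fit[17] <- 10
  # dominant individual with group covering the pool fills every slot
  sel <- tournament_select(pool, fit, 20, group_size = 40)
  expect_true(all(unlist(sel$individuals) == 17))
  # selection pressure: mean fitness of winners >= pool mean (Monte Carlo)
  fit2 <- rnorm(40)
  gains <- replicate(1000, {
    s <- tournament_select(pool, fit2, 20, group_size = 4)
    mean(fit2[s$indices])
  })
  expect_gt(mean(gains), mean(fit2))
  expect_error(tournament_select(pool, fit2, 5, group_size = 1), "group_size")
})

test_that("a no-mutation elite generation preserves the population's genotypes", {
  set.seed(4)
  cfg <- evolution_config(N = 10, selection = "elite", max_generations = 5)
  cfg$mutate_fraction <- 0 # config override below the constructor floor
  pop <- replicate(10, init_network(4, 3, 1), simplify = FALSE)
  g <- generate_goal(4, 2, 10)
  out <- generation_step(pop, g, cfg)
  # every survivor is a verbatim copy of some parent, and the distinct set
  # of survivor fitnesses comes from the parents' upper half (duplication
  # means each selected parent can appear twice)
  parent_fit <- sort(sapply(pop, function(n) network_fitness(n, g)),
                     decreasing = TRUE)
  surv_fit <- sapply(out$population, function(n) network_fitness(n, g))
  expect_true(all(surv_fit %in% parent_fit))
  expect_equal(sort(unique(surv_fit), decreasing = TRUE),
               parent_fit[1:5], tolerance = 1e-15)
  expect_equal(out$best_fitness, parent_fit[1])
})

test_that("elite selection gives non-decreasing mean fitness across generations", {
  set.seed(5)
  cfg <- evolution_config(N = 12, selection = "elite")
  pop <- replicate(12, init_network(4, 2, 0.5), simplify = FALSE)
  g <- generate_goal(4, 1, 5)
  means <- numeric(100)
  for (t in 1:100) {
    out <- generation_step(pop, g, cfg)
    means[t] <- out$mean_fitness
    pop <- out$population
  }
  expect_true(all(diff(means) >= -1e-12))
  expect_true(all(means <= 0))
})

test_that("population size drift is caught", {
  cfg <- evolution_config(N = 10)
  pop <- replicate(9, init_network(3, 2, 1), simplify = FALSE)
  expect_error(generation_step(pop, generate_goal(3, 1, 5), cfg), "drift")
})

test_that("compiled runs are seed-deterministic", {
  cfg <- quick_config()
  run <- function() {
    set.seed(99)
    g <- generate_goal(6, 1, 60)
    run_evolution(cfg, g, M = 6, L = 4, A0 = 0.5)
  }
  a <- run()
  b <- run()
  expect_identical(a$records, b$records)
  expect_identical(a$final_network$matrices, b$final_network$matrices)
})

test_that("a population pre-seeded at the goal converges immediately", {
  set.seed(6)
  g <- generate_goal(6, 1, 60)
  # build a network composing exactly to G from its rank-1 factors
  f <- attr(g, "factors")
  A1 <- matrix(0, 6, 6); A1[1, ] <- f$v[, 1]
  A4 <- matrix(0, 6, 6); A4[, 1] <- f$u[, 1]
  perfect <- layered_network(list(A1, diag(6), diag(6), A4))
  expect_equal(network_fitness(perfect, g), 0, tolerance = 1e-18)
  cfg <- quick_config(N = 10)
  tr <- run_evolution(cfg, g, init_pop = replicate(10, perfect,
                                                   simplify = FALSE))
  expect_equal(tr$converged_at, 0L)
  expect_identical(tr$status, "converged")
})

test_that("best fitness never exceeds zero and convergence matches the flag", {
  set.seed(7)
  g <- generate_goal(6, 1, 60)
  tr <- run_evolution(evolution_config(record_stride = 100), g, A0 = 30)
  expect_true(all(tr$records$best_fitness <= 0))
  expect_true(all(tr$records$best_fitness >= tr$records$mean_fitness - 1e-9))
  expect_false(is.na(tr$converged_at))
  expect_gte(tail(tr$records$mean_fitness, 1), -0.01)
})

test_that("non-convergence returns a trajectory, not an error", {
  set.seed(8)
  g <- generate_goal(6, 6, 60)
  cfg <- quick_config(max_generations = 50)
  tr <- run_evolution(cfg, g, A0 = 0.01)
  expect_true(is.na(tr$converged_at))
  expect_identical(tr$status, "max_generations")
})

test_that("network expansion embeds the original block with near-zero padding", {
  set.seed(9)
  net <- init_network(10, 4, 10)
  big <- expand_network(net, 20, pad_scale = 0.01)
  for (l in 1:4) {
    expect_identical(big$matrices[[l]][1:10, 1:10], net$matrices[[l]])
    pad <- big$matrices[[l]][11:20, ]
    expect_true(all(pad >= 0 & pad <= 0.01))
  }
  expect_error(expand_network(net, 10), "new_M")
  expect_error(expand_network(net, 20, pad_scale = 0), "pad_scale")
})

test_that("instantaneous minimum waist scans the recorded trajectory", {
  rec <- data.frame(waist = c(6, 3, 1, 6))
  expect_equal(instantaneous_min_waist(rec), 1L)
  expect_equal(instantaneous_min_waist(data.frame(waist = rep(6, 4))), 6L)
  expect_error(instantaneous_min_waist(data.frame(waist = numeric())), "empty")
})

test_that("mid-run goal switches are applied and logged by epoch", {
  set.seed(10)
  sched <- goal_schedule(3, period = 100, ranks = 1, M = 6, norm = 60,
                         seed = 17)
  cfg <- quick_config(N = 20, max_generations = 300,
                      stop_at_convergence = FALSE, record_stride = 50)
  tr <- run_evolution(cfg, sched, A0 = 0.5)
  expect_setequal(unique(tr$records$epoch), c(0, 1, 2))
  expect_equal(max(tr$records$generation), 300)
})
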
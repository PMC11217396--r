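#' Genetic algorithm over layered networks
#'
#' Each generation the population of N networks is duplicated to 2N, a
#' fraction of the pool receives a single multiplicative link mutation
#' (`A_ij -> A_ij * xi`, `xi ~ N(1, 0.1)`), all 2N are evaluated against the
#' goal, and N survivors are chosen by tournament (default, group size 4) or
#' elite selection.
#'
#' @name evolution_engine
NULL

#' Genetic-algorithm configuration
#'
#' @param N population size (default 100).
#' @param mutate_fraction fraction of the 2N post-duplication pool that
#'   receives exactly one single-link mutation (default 0.2, i.e. 40
#'   individuals at N = 100).
#' @param xi_mean,xi_var mean and variance of the Gaussian mutation
#'   multiplier (defaults 1 and 0.1).
#' @param xi_positive resample nonpositive multipliers (default `TRUE`;
#'   the linear model keeps links nonnegative).
#' @param selection `"tournament"` or `"elite"`.
#' @param tournament_size group size for tournament selection (default 4).
#' @param convergence_fitness mean-fitness threshold declaring the
#'   population fully evolved (default -0.01).
#' @param max_generations generation cap (default 150000, the per-epoch
#'   budget of the adapt-then-perturb protocols).
#' @param reg_kind `"none"`, `"L1"` or `"L2"` link-cost regularization.
#' @param reg_lambda nonnegative regularization weight (default 0).
#' @param record_stride record trajectory rows every this many generations.
#' @param active_def active-node definition used for trajectory recording
#'   (1 = fitness drop, 2 = in-out drop, 3 = max link).
#' @param active_threshold activity cutoff for recording.
#' @param mutate_copies_only restrict mutation to the duplicated copies
#'   (default `FALSE`: the whole 2N pool is eligible).
#' @param stop_at_convergence stop once mean fitness reaches the threshold
#'   (default `TRUE`; fluctuation protocols set `FALSE`).
#' @param pad_scale upper bound of the uniform near-zero entries used to pad
#'   networks when the goal expands mid-run.
#' @return object of class `evolution_config`.
#' @export
evolution_config <- function(N = 100, mutate_fraction = 0.2, xi_mean = 1,
                             xi_var = 0.1, xi_positive = TRUE,
                             selection = c("tournament", "elite"),
                             tournament_size = 4,
                             convergence_fitness = -0.01,
                             max_generations = 150000,
                             reg_kind = c("none", "L1", "L2"),
                             reg_lambda = 0, record_stride = 10,
                             active_def = 1, active_threshold = 0.001,
                             mutate_copies_only = FALSE,
                             stop_at_convergence = TRUE,
                             pad_scale = 0.01) {
  selection <- match.arg(selection)
  reg_kind <- match.arg(reg_kind)
  if (N < 2) stop("N must be >= 2")
  if (mutate_fraction <= 0 || mutate_fraction > 1) {
    stop("mutate_fraction must be in (0, 1]")
  }
  if (xi_var <= 0) stop("xi_var must be positive")
  if (tournament_size < 2) stop("tournament_size must be >= 2")
  if (reg_lambda < 0) stop("reg_lambda must be nonnegative")
  structure(as.list(environment()), class = "evolution_config")
}

#' Apply one multiplicative single-link mutation
#'
#' Multiplies one uniformly chosen link by `xi ~ N(xi_mean, xi_var)`; with
#' `xi_positive` the multiplier is resampled until positive.  All other
#' links are untouched.
#'
#' @param net a [layered_network].
#' @param xi_mean,xi_var multiplier distribution parameters.
#' @param xi_positive resample nonpositive draws.
#' @param xi test hook: force the multiplier to this value.
#' @return mutated copy of `net`.
#' @export
mutate_link <- function(net, xi_mean = 1, xi_var = 0.1, xi_positive = TRUE,
                        xi = NULL) {
  stopifnot(inherits(net, "layered_network"))
  l <- sample.int(net$L, 1)
  i <- sample.int(net$M, 1)
  j <- sample.int(net$M, 1)
  if (is.null(xi)) {
    repeat {
      xi <- stats::rnorm(1, xi_mean, sqrt(xi_var))
      if (!xi_positive || xi > 0) break
    }
  }
  net$matrices[[l]][i, j] <- net$matrices[[l]][i, j] * xi
  net
}

#' Fitness with an optional link-cost regularization term
#'
#' `F - lambda * sum |A_ij^(l)|` (L1) or `F - lambda * sum (A_ij^(l))^2`
#' (L2); `reg_kind = "none"` returns the plain fitness.
#'
#' @inheritParams network_fitness
#' @param reg_kind `"none"`, `"L1"` or `"L2"`.
#' @param reg_lambda nonnegative weight.
#' @export
regularized_fitness <- function(net, G, reg_kind = c("none", "L1", "L2"),
                                reg_lambda = 0) {
  reg_kind <- match.arg(reg_kind)
  if (reg_lambda < 0) stop("reg_lambda must be nonnegative")
  F <- network_fitness(net, G)
  if (reg_kind == "L1") {
    F <- F - reg_lambda * sum(vapply(net$matrices,
                                     function(A) sum(abs(A)), 0))
  } else if (reg_kind == "L2") {
    F <- F - reg_lambda * sum(vapply(net$matrices,
                                     function(A) sum(A^2), 0))
  }
  F
}

#' Tournament selection of N survivors from a 2N pool
#'
#' Repeats N times: sample `group_size` individuals without replacement
#' from the pool, the highest fitness in the group advances.  Groups are
#' drawn with replacement across repetitions.
#'
#' @param pool list of individuals (any type).
#' @param fitnesses numeric vector aligned with `pool`.
#' @param n number of survivors.
#' @param group_size tournament group size (`>= 2`).
#' @return list with `individuals` (length n) and `indices` into the pool.
#' @export
tournament_select <- function(pool, fitnesses, n, group_size = 4) {
  if (group_size < 2) stop("group_size must be >= 2")
  group_size <- min(group_size, length(pool))
  idx <- vapply(seq_len(n), function(s) {
    g <- sample.int(length(pool), group_size)
    g[which.max(fitnesses[g])]
  }, 0L)
  list(individuals = pool[idx], indices = idx)
}

#' One generation of the genetic algorithm (reference implementation)
#'
#' Duplication to 2N, single-link mutation of a fraction of the pool,
#' evaluation (with regularization if configured) and selection back to N.
#' This plain-R stepper mirrors the compiled loop used by [run_evolution]
#' and is convenient for inspecting single generations.
#'
#' @param population list of [layered_network] of length `config$N`.
#' @param G a [goal_matrix].
#' @param config an [evolution_config].
#' @return list with `population` (length N), `mean_fitness`,
#'   `best_fitness`, `best` (index of the best survivor).
#' @export
generation_step <- function(population, G, config) {
  N <- length(population)
  if (N != config$N) stop("population size drifted from config$N")
  pool <- c(population, population)
  n_mut <- floor(config$mutate_fraction * 2 * N)
  eligible <- if (config$mutate_copies_only) N + seq_len(N) else seq_len(2 * N)
  if (n_mut > 0) {
    for (idx in sample(eligible, min(n_mut, length(eligible)))) {
      pool[[idx]] <- mutate_link(pool[[idx]], config$xi_mean, config$xi_var,
                                 config$xi_positive)
    }
  }
  fit <- vapply(pool, regularized_fitness, 0, G = G,
                reg_kind = config$reg_kind, reg_lambda = config$reg_lambda)
  if (config$selection == "elite") {
    keep <- order(fit, decreasing = TRUE)[seq_len(N)]
    sel <- list(individuals = pool[keep], indices = keep)
  } else {
    sel <- tournament_select(pool, fit, N, config$tournament_size)
  }
  f <- fit[sel$indices]
  list(population = sel$individuals, mean_fitness = mean(f),
       best_fitness = max(f), best = which.max(f))
}

normalize_schedule <- function(schedule) {
  if (inherits(schedule, "goal_matrix")) {
    schedule <- list(list(generation = 0L, goal = schedule))
  }
  gens <- vapply(schedule, function(s) as.integer(s$generation), 0L)
  if (is.unsorted(gens, strictly = TRUE)) {
    stop("schedule generations must be strictly increasing")
  }
  if (gens[1] != 0) stop("the first goal must apply from generation 0")
  schedule
}

#' Run the evolutionary simulation
#'
#' Iterates the generation step (compiled core), applying scheduled goal
#' switches; when a scheduled goal has a larger dimension than the current
#' networks, every individual is padded with near-zero random entries
#' (goal-expansion protocol).  Per-generation statistics of the selected
#' population and active-node counts of the best individual are recorded
#' every `record_stride` generations.
#'
#' @param config an [evolution_config].
#' @param schedule a [goal_matrix] or a list of `list(generation =, goal =)`
#'   as produced by [goal_schedule].
#' @param M,L network dimensions (ignored when `init_pop` is given).
#' @param A0 initial Frobenius norm of each individual's composed matrix.
#' @param init_pop optional list of `config$N` [layered_network] used as the
#'   initial population (e.g. pre-adapted networks); otherwise `N`
#'   independent random networks scaled to `A0` are drawn.
#' @return object of class `evo_trajectory`: list with `records`
#'   (data.frame: generation, mean_fitness, best_fitness, active counts per
#'   middle node layer, waist, epoch), `final_network` (best individual),
#'   `converged_at` (generation or `NA`), `status`, `config`.
#' @export
run_evolution <- function(config, schedule, M = 6, L = 4, A0 = 0.01,
                          init_pop = NULL) {
  stopifnot(inherits(config, "evolution_config"))
  schedule <- normalize_schedule(schedule)
  if (is.null(init_pop)) {
    init_pop <- replicate(config$N, init_network(M, L, A0), simplify = FALSE)
  } else {
    if (length(init_pop) != config$N) stop("init_pop must have N individuals")
    M <- init_pop[[1]]$M
    L <- init_pop[[1]]$L
  }
  res <- cpp_evolve(
    lapply(init_pop, as_link_array),
    vapply(schedule, function(s) as.integer(s$generation), 0L),
    lapply(schedule, function(s) s$goal$entries),
    as.integer(floor(config$mutate_fraction * 2 * config$N)),
    config$xi_mean, sqrt(config$xi_var), config$xi_positive,
    if (config$selection == "elite") 1L else 0L,
    as.integer(config$tournament_size), config$convergence_fitness,
    as.integer(config$max_generations),
    match(config$reg_kind, c("none", "L1", "L2")) - 1L,
    config$reg_lambda, as.integer(config$record_stride),
    as.integer(config$active_def), config$active_threshold,
    config$mutate_copies_only, config$stop_at_convergence,
    config$pad_scale)
  rec <- as.data.frame(res$records)
  names(rec) <- c("generation", "mean_fitness", "best_fitness",
                  paste0("active_", seq_len(L - 1) + 1), "waist", "epoch")
  structure(list(records = rec,
                 final_network = array_to_network(res$best),
                 final_fitness = res$best_fitness,
                 converged_at = if (res$converged_at < 0) NA_integer_
                                else as.integer(res$converged_at),
                 status = res$status, M = res$M, L = L, config = config),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf(paste0("evolution trajectory: %d recorded generations, ",
                     "status %s\n  converged at: %s; final best fitness ",
                     "%.4g; final waist %d\n"),
              nrow(x$records), x$status,
              ifelse(is.na(x$converged_at), "never", x$converged_at),
              last$best_fitness, as.integer(last$waist)))
  invisible(x)
}

#' Smallest waist size reached at any recorded generation
#'
#' @param traj an `evo_trajectory` (or ODE trajectory with a waist column).
#' @return integer minimum of the per-generation waist sizes.
#' @export
instantaneous_min_waist <- function(traj) {
  rec <- if (is.data.frame(traj)) traj else traj$records
  if (!nrow(rec)) stop("trajectory is empty")
  as.integer(min(rec$waist))
}

#' Embed a network in a larger layer dimension with near-zero padding
#'
#' Each layer matrix becomes the top-left block of a `new_M x new_M` matrix
#' whose remaining entries are i.i.d. uniform(0, pad_scale).
#'
#' @param net a [layered_network].
#' @param new_M new dimension, `> net$M`.
#' @param pad_scale upper bound of the padding entries (`> 0`).
#' @return a [layered_network] of dimension `new_M`.
#' @export
expand_network <- function(net, new_M, pad_scale = 0.01) {
  stopifnot(inherits(net, "layered_network"))
  if (new_M <= net$M) stop("new_M must exceed the current dimension")
  if (pad_scale <= 0) stop("pad_scale must be positive")
  layered_network(lapply(net$matrices, function(A) {
    B <- matrix(stats::runif(new_M * new_M, 0, pad_scale), new_M, new_M)
    B[seq_len(net$M), seq_len(net$M)] <- A
    B
  }))
}

#' Write a trajectory's records as CSV
#'
#' @param traj an `evo_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$records, path, row.names = FALSE)
  invisible(path)
}
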
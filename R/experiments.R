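#' Figure-level experiment drivers
#'
#' Reproducible protocols over grids of goal rank and initial link
#' intensity, with per-replicate child seeds, per-run trajectory export and
#' aggregate summaries (mode/mean/sd of the waist per condition).
#'
#' @name experiments
NULL

#' Describe an experiment
#'
#' @param experiment one of `"waist_vs_rank"`, `"waist_vs_A0"`,
#'   `"trajectories"`, `"min_waist_dist"`, `"fluctuation"`, `"expansion"`,
#'   `"nonlinear"`, `"ode_phase"`.
#' @param replicates runs per grid condition (default 20; the full-scale
#'   protocols use 100).
#' @param ranks goal ranks in the grid.
#' @param A0 initial link intensities in the grid.
#' @param M,L network dimensions.
#' @param norm goal Frobenius norm (the figure protocols use 60).
#' @param normalize_D if non-`NULL`, goals are variance-and-norm normalized
#'   with this squared-norm target after generation.
#' @param config base [evolution_config].
#' @param seed master seed; replicate r of condition c runs under a child
#'   seed derived from `(seed, c, r)`.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param ... protocol-specific options: `periods`/`epochs`/`rank_switch`/
#'   `start_generation` (fluctuation), `expand_M`/`expand_generation`
#'   (expansion), `eta`/`dt`/`t_end` (ode_phase), `n_images`
#'   (nonlinear).
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("waist_vs_rank", "waist_vs_A0",
                                           "trajectories", "min_waist_dist",
                                           "fluctuation", "expansion",
                                           "nonlinear", "ode_phase"),
                            replicates = 20, ranks = 1:6, A0 = 0.01,
                            M = 6, L = 4, norm = 60, normalize_D = NULL,
                            config = evolution_config(), seed = 1,
                            out_dir = NULL, ...) {
  experiment <- match.arg(experiment)
  if (replicates < 1) stop("replicates must be >= 1")
  if (!length(ranks) || !length(A0)) stop("parameter grids must be nonempty")
  structure(c(list(experiment = experiment, replicates = replicates,
                   ranks = ranks, A0 = A0, M = M, L = L, norm = norm,
                   normalize_D = normalize_D, config = config, seed = seed,
                   out_dir = out_dir), list(...)),
            class = "experiment_spec")
}

child_seed <- function(seed, cond, rep) {
  as.integer(((seed %% 1e5) * 7919 + cond * 104729 + rep * 131) %% 2147483647)
}

spec_goal <- function(spec, rank) {
  g <- generate_goal(spec$M, rank, spec$norm)
  if (!is.null(spec$normalize_D)) g <- normalize_variance_norm(g, spec$normalize_D)
  g
}

#' Run an experiment protocol
#'
#' Executes the protocol named in the spec over its (rank, A0) grid with
#' `replicates` child-seeded runs per condition.  Per-run rows record the
#' condition, seed, convergence generation, final fitness, final waist and
#' instantaneous minimum waist; aggregates (mode/mean/sd of the final
#' waist, converged-run counts) are computed per condition.  When
#' `out_dir` is set, per-run rows, the summary and a manifest are written
#' as CSV/JSON.
#'
#' @param spec an [experiment_spec].
#' @param keep_trajectories return the trajectory objects as well (memory
#'   permitting).
#' @return list with `runs` (data.frame), `summary` (data.frame), and
#'   optionally `trajectories`.
#' @export
run_experiment <- function(spec, keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- expand.grid(rank = spec$ranks, A0 = spec$A0)
  rows <- list()
  trajs <- list()
  for (ci in seq_len(nrow(grid))) {
    for (r in seq_len(spec$replicates)) {
      sd_ <- child_seed(spec$seed, ci, r)
      run <- with_child_seed(sd_, run_protocol(spec, grid$rank[ci],
                                               grid$A0[ci]))
      rows[[length(rows) + 1]] <- data.frame(
        rank = grid$rank[ci], A0 = grid$A0[ci], seed = sd_,
        converged_at = ifelse(is.na(run$converged_at), NA_integer_,
                              run$converged_at),
        converged = !is.na(run$converged_at),
        final_fitness = utils::tail(run$records$best_fitness, 1),
        final_waist = utils::tail(run$records$waist, 1),
        min_waist = instantaneous_min_waist(run))
      if (keep_trajectories) trajs[[length(trajs) + 1]] <- run
    }
  }
  runs <- do.call(rbind, rows)
  summary <- summarize_runs(runs)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(spec$out_dir, "runs.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(spec$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(experiment = spec$experiment, replicates = spec$replicates,
           ranks = spec$ranks, A0 = spec$A0, M = spec$M, L = spec$L,
           norm = spec$norm, seed = spec$seed,
           package_version = as.character(utils::packageVersion("bowtieevo"))),
      file.path(spec$out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  out <- list(runs = runs, summary = summary)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

# dispatch one replicate of the protocol at a grid condition
run_protocol <- function(spec, rank, A0) {
  cfg <- spec$config
  switch(spec$experiment,
    waist_vs_rank = ,
    waist_vs_A0 = ,
    min_waist_dist = ,
    trajectories = run_evolution(cfg, spec_goal(spec, rank),
                                 M = spec$M, L = spec$L, A0 = A0),
    fluctuation = {
      epochs <- spec$epochs %||% 10
      period <- spec$period %||% 1000
      start_gen <- spec$start_generation %||% 0
      ranks_seq <- if (!is.null(spec$rank_switch)) {
        c(rank, rep(spec$rank_switch, epochs - 1))
      } else rank
      sched <- goal_schedule(epochs, period = period, ranks = ranks_seq,
                             M = spec$M, norm = spec$norm,
                             seed = stats::runif(1, 1, 1e6),
                             start_generation = start_gen)
      cfg$stop_at_convergence <- FALSE
      run_evolution(cfg, sched, M = spec$M, L = spec$L, A0 = A0)
    },
    expansion = {
      g1 <- spec_goal(spec, rank)
      new_M <- spec$expand_M %||% (2 * spec$M)
      sched <- list(
        list(generation = 0L, goal = g1),
        list(generation = as.integer(spec$expand_generation %||% 1000),
             goal = expand_goal(g1, new_M)))
      run_evolution(cfg, sched, M = spec$M, L = spec$L, A0 = A0)
    },
    nonlinear = {
      data <- make_digit_dataset(spec$n_images %||% 300)
      evolve_nonlinear(cfg, A0, data)
    },
    ode_phase = {
      g <- spec_goal(spec, rank)
      net <- init_network(spec$M, spec$L, A0)
      tr <- integrate_ode(net, g, eta = spec$eta %||% 1e-4,
                          dt = spec$dt %||% 0.1,
                          t_end = spec$t_end %||% 1e5,
                          record_stride = spec$ode_stride %||% 200)
      # present ODE output with the fields the summaries expect
      tr$records$best_fitness <- tr$records$fitness
      tr$converged_at <- if (tr$status == "converged") {
        as.integer(utils::tail(tr$records$t, 1))
      } else NA_integer_
      tr
    },
    stop("unknown experiment id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-run records by condition
#'
#' Mode (ties toward the smaller value), mean and standard deviation of the
#' final waist per (rank, A0) condition, plus run and converged-run counts
#' and the same statistics restricted to converged runs.
#'
#' @param runs per-run data.frame as returned in `run_experiment()$runs`.
#' @return one row per condition.
#' @export
summarize_runs <- function(runs) {
  if (!nrow(runs)) stop("no runs to summarize")
  conds <- unique(runs[, c("rank", "A0")])
  do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    sub <- runs[runs$rank == conds$rank[i] & runs$A0 == conds$A0[i], ]
    conv <- sub[sub$converged, ]
    data.frame(
      rank = conds$rank[i], A0 = conds$A0[i], n = nrow(sub),
      n_converged = nrow(conv),
      waist_mode = stat_mode(sub$final_waist),
      waist_mean = mean(sub$final_waist),
      waist_sd = stats::sd(sub$final_waist),
      waist_mode_converged = if (nrow(conv)) stat_mode(conv$final_waist)
                             else NA_integer_,
      min_waist_mean = mean(sub$min_waist))
  }))
}

#' Mode of an integer sample, ties toward the smaller value
#'
#' @param x numeric/integer vector.
#' @export
stat_mode <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1]
}
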
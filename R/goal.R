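#' Goal matrices: construction, normalization, expansion and schedules
#'
#' A goal matrix is the target in-out relation toward which the composed
#' network matrix evolves.  Goals are generated as sums of outer products of
#' positive random vectors, which gives exact control of the rank, and then
#' rescaled to a prescribed Frobenius norm.
#'
#' @name goal_synthesis
NULL

#' Construct a goal matrix object
#'
#' Wraps a square numeric matrix together with its dimension, measured
#' numerical rank and Frobenius norm.  Rank is measured from the singular
#' values (threshold `1e-9` relative to the largest).
#'
#' @param entries square numeric matrix.
#' @param rank intended rank; if `NULL` the numerical rank is measured.
#' @return object of class `goal_matrix` with fields `entries`, `M`, `rank`,
#'   `frob_norm`.
#' @export
goal_matrix <- function(entries, rank = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) {
    stop("goal matrix must be square")
  }
  meas <- numerical_rank(entries)
  if (is.null(rank)) rank <- meas
  structure(
    list(entries = entries, M = nrow(entries), rank = as.integer(rank),
         frob_norm = frob_norm(entries)),
    class = "goal_matrix"
  )
}

#' @export
print.goal_matrix <- function(x, ...) {
  cat(sprintf("goal matrix: %d x %d, rank %d, ||G||_F = %.6g\n",
              x$M, x$M, x$rank, x$frob_norm))
  invisible(x)
}

frob_norm <- function(x) sqrt(sum(x^2))

numerical_rank <- function(x, tol = 1e-9) {
  s <- svd(x, nu = 0, nv = 0)$d
  sum(s > tol * s[1])
}

#' Generate a random goal matrix of given dimension, rank and norm
#'
#' The matrix is built as a sum of `rank` outer products of positive random
#' vectors (uniform(0, 1) components shifted away from zero), then rescaled
#' so its Frobenius norm equals `norm`.  Entries are therefore nonnegative,
#' which keeps a zero-distance fit reachable by networks with nonnegative
#' links.  On the (measure-zero) event that the numerical rank collapses
#' below the declared rank, the construction is redrawn.
#'
#' @param M matrix dimension.
#' @param rank intended rank, `1 <= rank <= M`.
#' @param norm target Frobenius norm (`> 0`); the figure-level protocols use
#'   `norm = 60`.
#' @param vec_shift positive offset added to the uniform components so
#'   generating vectors are bounded away from zero.
#' @return a [goal_matrix] whose generating vectors are kept in the
#'   `"factors"` attribute (used by [expand_goal]).
#' @export
generate_goal <- function(M, rank, norm = 60, vec_shift = 0.05) {
  if (rank < 1 || rank > M) stop("rank must satisfy 1 <= rank <= M")
  if (norm <= 0) stop("norm must be positive")
  for (attempt in 1:100) {
    u <- matrix(stats::runif(M * rank) + vec_shift, M, rank)
    v <- matrix(stats::runif(M * rank) + vec_shift, M, rank)
    G <- u %*% t(v)
    if (numerical_rank(G) == rank) {
      sc <- norm / frob_norm(G)
      g <- goal_matrix(G * sc, rank = rank)
      attr(g, "factors") <- list(u = u * sqrt(sc), v = v * sqrt(sc))
      return(g)
    }
  }
  stop("failed to generate a goal of the requested rank") # nocov
}

#' Normalize element variance and squared norm of a goal matrix
#'
#' Applies the affine normalization
#' `Z_ij = (G_ij - <G>) / sd(G) + sqrt(D / N^2 - 1)`,
#' where `<G>` and the variance are taken over all `N^2` elements
#' (population variance).  The result has element variance exactly 1 and
#' squared Frobenius norm exactly `D`.  The shift adds a rank-one component,
#' so the rank is re-measured on the output rather than carried over.
#'
#' @param G a [goal_matrix].
#' @param D target squared Frobenius norm; must satisfy `D >= N^2`.
#' @return a [goal_matrix] with variance-1 elements and `||Z||_F^2 = D`.
#' @export
normalize_variance_norm <- function(G, D) {
  stopifnot(inherits(G, "goal_matrix"))
  N <- G$M
  if (D < N^2) stop("D must be at least N^2")
  mu <- mean(G$entries)
  v <- mean((G$entries - mu)^2)
  if (v == 0) stop("degenerate goal: element variance is zero")
  Z <- (G$entries - mu) / sqrt(v) + sqrt(D / N^2 - 1)
  goal_matrix(Z)
}

#' Expand a rank-1 goal matrix to a larger dimension
#'
#' Keeps the original matrix as the upper-left block and extends the rank-1
#' generating vectors with positive random components, so the numerical rank
#' stays 1 while the Frobenius norm grows.  New components are uniform(0, 1)
#' scaled by the mean magnitude of the existing components, making the new
#' rows/columns statistically similar to the old ones.
#'
#' @param G a rank-1 [goal_matrix].
#' @param new_M new dimension, `> G$M`.
#' @param pad_zero if `TRUE` extend with zero components (block embedding,
#'   norm unchanged); used for exactness checks.
#' @return a [goal_matrix] of dimension `new_M`, rank 1.
#' @export
expand_goal <- function(G, new_M, pad_zero = FALSE) {
  stopifnot(inherits(G, "goal_matrix"))
  if (new_M <= G$M) stop("new_M must exceed the current dimension")
  if (G$rank != 1) stop("expansion is defined for rank-1 goals")
  f <- attr(G, "factors")
  if (is.null(f)) {
    s <- svd(G$entries, nu = 1, nv = 1)
    u <- abs(s$u[, 1, drop = FALSE]) * sqrt(s$d[1])
    v <- abs(s$v[, 1, drop = FALSE]) * sqrt(s$d[1])
  } else {
    u <- f$u[, 1, drop = FALSE]
    v <- f$v[, 1, drop = FALSE]
  }
  k <- new_M - G$M
  ext <- function(w) {
    add <- if (pad_zero) rep(0, k) else stats::runif(k) * mean(abs(w))
    matrix(c(w, add), ncol = 1)
  }
  u2 <- ext(u)
  v2 <- ext(v)
  Z <- u2 %*% t(v2)
  Z[seq_len(G$M), seq_len(G$M)] <- G$entries
  g <- goal_matrix(Z, rank = 1)
  attr(g, "factors") <- list(u = u2, v = v2)
  g
}

#' Build a schedule of goal-matrix switches
#'
#' Generates the ordered list of `(generation, goal)` pairs used by
#' [run_evolution] for goal-fluctuation protocols: a fresh random goal every
#' `period` generations, with per-epoch rank taken from `ranks` (recycled).
#' Each epoch's goal is drawn from a child seed derived from
#' `(seed, epoch)`, so epochs are individually reproducible.
#'
#' @param epochs number of goal epochs (`>= 1`).
#' @param period generations between switches (first goal at generation 0).
#' @param ranks integer vector of per-epoch ranks, recycled to `epochs`.
#' @param M goal dimension.
#' @param norm Frobenius norm of every goal.
#' @param seed master seed for the child-seed derivation.
#' @param start_generation generation of the first switch (0 starts the
#'   fluctuation immediately; a positive value schedules the first epoch at
#'   generation 0 and subsequent switches from `start_generation` on).
#' @return list of `list(generation =, goal =)`, generations strictly
#'   increasing.
#' @export
goal_schedule <- function(epochs, period = 1000, ranks = 1, M = 6,
                          norm = 60, seed = 1, start_generation = 0) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (period <= 0) stop("period must be positive")
  ranks <- rep_len(as.integer(ranks), epochs)
  gens <- if (epochs == 1) 0 else c(0, start_generation + period * seq_len(epochs - 1) -
                                      if (start_generation > 0) period else 0)
  if (any(diff(gens) <= 0)) stop("generation indices must be increasing")
  lapply(seq_len(epochs), function(e) {
    child <- ((seed %% 1e6) * 1000003 + e) %% 2147483647
    with_child_seed(child, list(generation = as.integer(gens[e]),
                                goal = generate_goal(M, ranks[e], norm)))
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_child_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Write / read a goal matrix as tab-separated text with a JSON sidecar
#'
#' @param G a [goal_matrix].
#' @param path file path for the matrix (one row per line, tab-separated);
#'   the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly (for the writer); a [goal_matrix] (reader).
#' @export
write_goal <- function(G, path) {
  stopifnot(inherits(G, "goal_matrix"))
  utils::write.table(G$entries, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(M = G$M, rank = G$rank, frob_norm = G$frob_norm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_goal
#' @export
read_goal <- function(path) {
  entries <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(entries) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  goal_matrix(entries, rank = meta$rank)
}
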
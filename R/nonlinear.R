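#' Nonlinear (tanh) classification variant
#'
#' A 5-layer network with activation `f(x) = (1 + tanh(x)) / 2` after every
#' matrix stage maps a flattened 8 x 8 image (64 inputs) through three
#' 6-node middle layers to a 6-bit group code:
#' `u = f(A4 f(A3 f(A2 f(A1 v))))` with `A1` of shape 6 x 64 and `A2..A4`
#' of shape 6 x 6.  Weights are signed; training uses the same genetic
#' algorithm with a wide multiplicative mutation `xi ~ N(1, 0.5)` whose
#' sign flips are allowed.
#'
#' @name nonlinear_network
NULL

#' Construct a nonlinear network
#'
#' @param matrices list of 4 matrices: 6 x 64, then three 6 x 6.
#' @return object of class `nonlinear_network`.
#' @export
nonlinear_network <- function(matrices) {
  if (length(matrices) != 4) stop("expected 4 layer matrices")
  d <- lapply(matrices, dim)
  if (d[[1]][1] != d[[2]][1]) stop("layer widths disagree")
  for (l in 2:4) {
    if (d[[l]][2] != d[[l - 1]][1]) stop("layer shapes do not chain")
  }
  structure(list(matrices = matrices, n_in = d[[1]][2], n_mid = d[[2]][1]),
            class = "nonlinear_network")
}

#' Random nonlinear network scaled to a composed-norm target
#'
#' Entries are i.i.d. uniform(-1, 1); all four layers are rescaled by the
#' common positive factor `(A0 / ||A4 A3 A2 A1||_F)^(1/4)` so the Frobenius
#' norm of the composed (linearized) product equals `A0`.
#'
#' @param A0 target norm of the composed product (`> 0`).
#' @param n_in number of inputs (default 64).
#' @param n_mid middle/output layer width (default 6).
#' @return a [nonlinear_network].
#' @export
init_nonlinear <- function(A0, n_in = 64, n_mid = 6) {
  if (A0 <= 0) stop("A0 must be positive")
  mats <- c(list(matrix(stats::runif(n_mid * n_in, -1, 1), n_mid, n_in)),
            replicate(3, matrix(stats::runif(n_mid^2, -1, 1), n_mid, n_mid),
                      simplify = FALSE))
  comp <- Reduce(function(acc, A) A %*% acc, mats)
  s <- (A0 / frob_norm(comp))^(1 / 4)
  nonlinear_network(lapply(mats, function(A) A * s))
}

#' Forward pass of the nonlinear network
#'
#' @param net a [nonlinear_network].
#' @param v input: a length-`n_in` vector or an `n_in x n` matrix of
#'   column images.
#' @return output in (0, 1): a length-6 vector, or 6 x n matrix.
#' @export
nl_forward <- function(net, v) {
  stopifnot(inherits(net, "nonlinear_network"))
  vec <- is.null(dim(v))
  U <- if (vec) matrix(v, ncol = 1) else v
  if (nrow(U) != net$n_in) stop("input length does not match the network")
  for (A in net$matrices) U <- (1 + tanh(A %*% U)) / 2
  if (vec) drop(U) else U
}

# 8x8 glyph templates for the digits used by the classification task
digit_templates <- function() {
  g <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
    storage.mode(m) <- "double"
    m
  }
  list(
    "2" = g(c("00111100", "01100110", "00000110", "00001100",
              "00011000", "00110000", "01100000", "01111110")),
    "4" = g(c("00001100", "00011100", "00110100", "01100100",
              "01111110", "00000100", "00000100", "00000100")),
    "6" = g(c("00011100", "00110000", "01100000", "01111100",
              "01100110", "01100110", "01100110", "00111100")),
    "8" = g(c("00111100", "01100110", "01100110", "00111100",
              "01100110", "01100110", "01100110", "00111100"))
  )
}

#' Default redundant class-to-group encoding
#'
#' Maps the four digit classes onto six output groups; two classes each
#' activate two groups, so the encoding is redundant rather than one-hot.
#'
#' @return 4 x 6 binary matrix with rownames `"2", "4", "6", "8"`.
#' @export
default_group_map <- function() {
  m <- rbind("2" = c(1, 1, 0, 0, 0, 0),
             "4" = c(0, 0, 1, 1, 0, 0),
             "6" = c(0, 0, 0, 0, 1, 0),
             "8" = c(0, 0, 0, 0, 0, 1))
  m
}

#' Synthetic digit-image dataset
#'
#' Draws 8 x 8 images of the digits 2, 4, 6 and 8 from fixed glyph
#' templates with per-image intensity jitter, +/-1 pixel shifts and
#' Gaussian pixel noise, clipped to [0, 1]; classes are balanced.  Group
#' targets follow a configurable redundant class-to-group map.
#'
#' @param n number of images (default 300).
#' @param noise pixel noise standard deviation (default 0.1).
#' @param shift maximal circular shift in pixels (default 1).
#' @param group_map 4 x 6 binary class-to-group matrix
#'   (default [default_group_map]).
#' @param source `"synthetic"` (default) draws from the built-in templates;
#'   no other source is bundled.
#' @return object of class `digit_dataset`: `images` (64 x n, columns are
#'   flattened images in [0, 1]), `labels` (integer digits), `targets`
#'   (6 x n binary group codes), `group_map`.
#' @export
make_digit_dataset <- function(n = 300, noise = 0.1, shift = 1,
                               group_map = default_group_map(),
                               source = "synthetic") {
  if (n < 1) stop("n must be >= 1")
  if (!identical(source, "synthetic")) stop("unknown dataset source")
  tpl <- digit_templates()
  classes <- as.integer(names(tpl))
  labels <- rep_len(classes, n)
  roll <- function(m, k, margin) {
    if (k == 0) return(m)
    idx <- ((seq_len(8) - 1 - k) %% 8) + 1
    if (margin == 1) m[idx, ] else m[, idx]
  }
  images <- vapply(seq_len(n), function(i) {
    m <- tpl[[as.character(labels[i])]] * stats::runif(1, 0.7, 1)
    m <- roll(m, sample(-shift:shift, 1), 1)
    m <- roll(m, sample(-shift:shift, 1), 2)
    m <- m + matrix(stats::rnorm(64, 0, noise), 8, 8)
    pmin(pmax(as.vector(m), 0), 1)
  }, numeric(64))
  targets <- t(group_map[as.character(labels), , drop = FALSE])
  dimnames(targets) <- NULL
  structure(list(images = images, labels = labels, targets = targets,
                 group_map = group_map),
            class = "digit_dataset")
}

#' @export
print.digit_dataset <- function(x, ...) {
  cat(sprintf("digit dataset: %d images (8 x 8), classes %s\n",
              ncol(x$images), paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Squared-error classification fitness
#'
#' `F = -sum_images ||u - target||^2`, mirroring the Frobenius objective of
#' the linear model; 0 iff every output matches its 6-bit target exactly.
#'
#' @param net a [nonlinear_network].
#' @param data a [make_digit_dataset] object.
#' @export
classification_fitness <- function(net, data) {
  stopifnot(inherits(data, "digit_dataset"))
  if (!ncol(data$images)) stop("empty dataset")
  -sum((nl_forward(net, data$images) - data$targets)^2)
}

#' Predicted digit classes (nearest group code)
#'
#' @param net a [nonlinear_network].
#' @param data a [make_digit_dataset] object.
#' @return integer vector of predicted digit labels.
#' @export
classify_digits <- function(net, data) {
  U <- nl_forward(net, data$images)
  codes <- data$group_map
  d2 <- vapply(seq_len(nrow(codes)),
               function(k) colSums((U - codes[k, ])^2),
               numeric(ncol(U)))
  as.integer(rownames(codes))[max.col(-d2)]
}

#' Evolve a nonlinear classifier with the genetic algorithm
#'
#' Same duplication/mutation/selection loop as [run_evolution], with a wide
#' mutation multiplier `xi ~ N(1, 0.5)` that may flip signs (no
#' resampling), fitness given by [classification_fitness], and active
#' nodes judged by the deletion fitness drop (threshold 0.001) over the
#' three 6-node middle layers.
#'
#' @param config an [evolution_config]; `xi_var` defaults to 0.5 here if
#'   left at the linear default.
#' @param A0 initial composed-product norm.
#' @param data a [make_digit_dataset] object.
#' @return an `evo_trajectory` whose `final_network` is a
#'   [nonlinear_network].
#' @export
evolve_nonlinear <- function(config, A0, data) {
  stopifnot(inherits(config, "evolution_config"),
            inherits(data, "digit_dataset"))
  xi_var <- if (identical(config$xi_var, 0.1)) 0.5 else config$xi_var
  pop <- replicate(config$N, init_nonlinear(A0)$matrices, simplify = FALSE)
  res <- cpp_evolve_nl(
    pop, data$images, data$targets,
    as.integer(floor(config$mutate_fraction * 2 * config$N)),
    config$xi_mean, sqrt(xi_var),
    if (config$selection == "elite") 1L else 0L,
    as.integer(config$tournament_size), config$convergence_fitness,
    as.integer(config$max_generations), as.integer(config$record_stride),
    config$active_threshold, config$stop_at_convergence)
  rec <- as.data.frame(res$records)
  names(rec) <- c("generation", "mean_fitness", "best_fitness",
                  paste0("active_", 2:4), "waist", "epoch")
  structure(list(records = rec,
                 final_network = nonlinear_network(res$best),
                 final_fitness = res$best_fitness,
                 converged_at = if (res$converged_at < 0) NA_integer_
                                else as.integer(res$converged_at),
                 status = res$status, M = 6, L = 4, config = config),
            class = "evo_trajectory")
}
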
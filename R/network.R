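#' Layered linear networks, fitness, node deletion and waist statistics
#'
#' A layered network is an ordered stack of L nonnegative M x M link
#' matrices; the composed in-out matrix is `A = A^(L) ... A^(1)`.  Bow-tie
#' structure is read off from node-deletion importance statistics: a middle
#' layer whose number of active nodes falls below M is a waist.
#'
#' @name linear_network
NULL

#' Construct a layered network from a list of link matrices
#'
#' @param matrices list of L square M x M matrices, `A^(1)` first.
#' @return object of class `layered_network` with fields `matrices`, `M`,
#'   `L`.
#' @export
layered_network <- function(matrices) {
  if (!length(matrices)) stop("network needs at least one layer matrix")
  M <- nrow(matrices[[1]])
  for (A in matrices) {
    if (!is.matrix(A) || nrow(A) != M || ncol(A) != M) {
      stop("all layer matrices must be square with a common dimension")
    }
  }
  structure(list(matrices = matrices, M = M, L = length(matrices)),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("layered network: %d nodes/layer, %d link stages (%d node layers)\n",
              x$M, x$L, x$L + 1))
  invisible(x)
}

as_link_array <- function(net) {
  array(unlist(net$matrices), dim = c(net$M, net$M, net$L))
}

array_to_network <- function(a) {
  layered_network(lapply(seq_len(dim(a)[3]), function(l) a[, , l]))
}

#' Compose the in-out matrix of a layered network
#'
#' @param net a [layered_network].
#' @return the M x M product `A^(L) %*% ... %*% A^(1)`.
#' @export
compose_network <- function(net) {
  stopifnot(inherits(net, "layered_network"))
  Reduce(function(acc, A) A %*% acc, net$matrices)
}

#' Fitness of a network against a goal matrix
#'
#' `F = -||A - G||_F^2`, the negative squared Frobenius distance between the
#' composed in-out matrix and the goal.  Zero iff the goal is matched
#' exactly.
#'
#' @param net a [layered_network].
#' @param G a [goal_matrix] (or plain matrix) of matching dimension.
#' @return nonpositive scalar.
#' @export
network_fitness <- function(net, G) {
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  if (nrow(Gm) != net$M) stop("goal and network dimensions disagree")
  -sum((compose_network(net) - Gm)^2)
}

#' Random initial network scaled to a prescribed composed norm
#'
#' Entries are i.i.d. uniform(0, 1); every layer is then rescaled by the
#' common factor `(A0 / ||compose||_F)^(1/L)` so the Frobenius norm of the
#' composed in-out matrix equals `A0` exactly.
#'
#' @param M nodes per layer.
#' @param L number of link stages (the network has L + 1 node layers).
#' @param A0 target Frobenius norm of the composed matrix (`> 0`).
#' @return a [layered_network] with strictly positive entries.
#' @export
init_network <- function(M, L, A0) {
  if (A0 <= 0) stop("A0 must be positive")
  mats <- replicate(L, matrix(stats::runif(M * M), M, M), simplify = FALSE)
  raw <- frob_norm(Reduce(function(acc, A) A %*% acc, mats))
  s <- (A0 / raw)^(1 / L)
  layered_network(lapply(mats, function(A) A * s))
}

#' Delete a middle-layer node
#'
#' Removal of node `i` in node layer `l` zeroes row `i` of `A^(l-1)`
#' (incoming links) and column `i` of `A^(l)` (outgoing links).  Only middle
#' node layers `2 .. L` can be deleted.
#'
#' @param net a [layered_network].
#' @param layer node-layer index, `2 <= layer <= L`.
#' @param node node index within the layer.
#' @return a modified copy of `net`; the input is untouched.
#' @export
delete_node <- function(net, layer, node) {
  stopifnot(inherits(net, "layered_network"))
  if (layer < 2 || layer > net$L) {
    stop("only middle node layers 2..L can be deleted")
  }
  if (node < 1 || node > net$M) stop("node index out of range")
  m <- net$matrices
  m[[layer - 1]][node, ] <- 0
  m[[layer]][, node] <- 0
  layered_network(m)
}

#' Node importance profile of the middle layers
#'
#' For each node in middle node layers `2 .. L`, computes the relative
#' importance `P_i^l` under one of three definitions:
#' \describe{
#'   \item{`fitness_drop`}{absolute fitness drop upon deletion, normalized
#'     within the layer (threshold default 0.001).}
#'   \item{`inout_drop`}{squared Frobenius norm of the change of the
#'     composed in-out matrix upon deletion, normalized (threshold 0.001).}
#'   \item{`max_link`}{largest link intensity touching the node (over its
#'     incoming row and outgoing column), normalized (threshold 0.05).}
#' }
#' Within each layer the importances sum to 1 when the denominator is
#' positive; a layer whose deletions are all neutral reports all zeros.
#'
#' @param net a [layered_network] with at least one middle layer (`L >= 2`).
#' @param G goal matrix used by the fitness-based definition.
#' @param definition one of `"fitness_drop"`, `"inout_drop"`, `"max_link"`.
#' @param threshold activity cutoff stored in the profile; defaults to the
#'   definition's conventional value.
#' @return object of class `node_importance`: list with `values`
#'   ((L-1) x M matrix, row `j` = node layer `j + 1`), `definition`,
#'   `threshold`, `M`.
#' @export
node_importance <- function(net, G,
                            definition = c("fitness_drop", "inout_drop",
                                           "max_link"),
                            threshold = NULL) {
  stopifnot(inherits(net, "layered_network"))
  if (net$L < 2) stop("need at least one middle layer (L >= 2)")
  definition <- match.arg(definition)
  def <- match(definition, c("fitness_drop", "inout_drop", "max_link"))
  if (is.null(threshold)) threshold <- if (def == 3) 0.05 else 0.001
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  P <- cpp_importance(as_link_array(net), Gm, def)
  rownames(P) <- paste0("layer", seq_len(net$L - 1) + 1)
  structure(list(values = P, definition = definition,
                 threshold = threshold, M = net$M),
            class = "node_importance")
}

#' Waist statistics from a node-importance profile
#'
#' A node is active when its importance exceeds the threshold.  The waist is
#' the middle node layer with the fewest active nodes (ties broken toward
#' the lowest layer index); the network is a bow-tie when the waist size is
#' below M.
#'
#' @param profile a [node_importance] profile.
#' @param threshold activity cutoff; defaults to the profile's own.
#' @return object of class `waist_report`: `active_counts` (named per
#'   middle node layer), `waist_layer` (node-layer index), `waist_size`,
#'   `is_bowtie`.
#' @export
waist_stats <- function(profile, threshold = profile$threshold) {
  stopifnot(inherits(profile, "node_importance"))
  if (threshold <= 0) stop("threshold must be positive")
  counts <- rowSums(profile$values > threshold)
  w <- which.min(counts) # first minimum = lowest layer index
  structure(list(active_counts = counts,
                 waist_layer = as.integer(w + 1L),
                 waist_size = as.integer(counts[w]),
                 is_bowtie = counts[w] < profile$M),
            class = "waist_report")
}

#' @export
print.waist_report <- function(x, ...) {
  cat(sprintf("waist: %d active nodes at node layer %d (%s)\n",
              x$waist_size, x$waist_layer,
              if (x$is_bowtie) "bow-tie" else "not bow-tie"))
  invisible(x)
}

#' Write / read a layered network as JSON
#'
#' @param net a [layered_network].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "layered_network"))
  jsonlite::write_json(list(M = net$M, L = net$L,
                            matrices = lapply(net$matrices, as.vector)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- x$matrices
  if (is.matrix(mats)) mats <- lapply(seq_len(nrow(mats)), function(l) mats[l, ])
  layered_network(lapply(seq_len(x$L), function(l) {
    matrix(as.numeric(mats[[l]]), x$M, x$M)
  }))
}
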
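# Small builders shared across test files.

tiny_net <- function(mats) layered_network(lapply(mats, function(m) {
  if (is.matrix(m)) m else matrix(m, sqrt(length(m)), sqrt(length(m)))
}))

all_ones_net <- function(M, L) {
  layered_network(replicate(L, matrix(1, M, M), simplify = FALSE))
}

# brute-force elementwise fitness oracle, independent of compose_network
fitness_oracle <- function(net, G) {
  A <- diag(net$M)
  for (l in seq_len(net$L)) {
    # hand matrix multiplication, loops only
    B <- net$matrices[[l]]
    C <- matrix(0, net$M, net$M)
    for (i in seq_len(net$M)) {
      for (j in seq_len(net$M)) {
        s <- 0
        for (k in seq_len(net$M)) s <- s + B[i, k] * A[k, j]
        C[i, j] <- s
      }
    }
    A <- C
  }
  Gm <- if (inherits(G, "goal_matrix")) G$entries else G
  f <- 0
  for (i in seq_len(net$M)) {
    for (j in seq_len(net$M)) f <- f - (A[i, j] - Gm[i, j])^2
  }
  f
}

quick_config <- function(...) {
  args <- list(N = 20, max_generations = 500, record_stride = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(evolution_config, args)
}
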
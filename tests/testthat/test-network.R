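test_that("composition multiplies the stack in layer order", {
  expect_equal(compose_network(all_ones_net(3, 1)), matrix(1, 3, 3))
  id <- layered_network(replicate(4, diag(5), simplify = FALSE))
  expect_equal(compose_network(id), diag(5))
  # hand-computed 2x2 case: A = A2 %*% A1
  net <- tiny_net(list(matrix(c(1, 3, 2, 4), 2, 2),
                       matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(compose_network(net), matrix(c(3, 1, 4, 2), 2, 2))
})

test_that("composition is bracketing-invariant", {
  set.seed(1)
  net <- init_network(5, 6, 3)
  left <- Reduce(function(acc, A) A %*% acc, net$matrices)
  right <- Reduce(`%*%`, rev(net$matrices))
  expect_lt(max(abs(left - right)), 1e-12)
  expect_lt(max(abs(compose_network(net) - left)), 1e-12)
})

test_that("fitness equals the negative squared Frobenius distance", {
  set.seed(2)
  g <- generate_goal(4, 2, 10)
  # brute-force loop oracle
  for (i in 1:5) {
    net <- init_network(4, 3, runif(1, 0.1, 20))
    expect_equal(network_fitness(net, g), fitness_oracle(net, g),
                 tolerance = 1e-12)
  }
  # exact match -> 0; zero network -> -||G||^2
  zero <- layered_network(replicate(2, matrix(0, 6, 6), simplify = FALSE))
  g60 <- generate_goal(6, 1, 60)
  expect_equal(network_fitness(zero, g60), -3600)
  net <- tiny_net(list(diag(2), diag(2)))
  expect_equal(network_fitness(net, matrix(c(0, 0, 0, 0), 2, 2)), -2)
  expect_equal(network_fitness(net, diag(2)), 0)
})

test_that("initial networks hit the requested composed norm with positive links", {
  set.seed(3)
  for (A0 in c(0.01, 40, 3)) {
    net <- init_network(6, 4, A0)
    expect_equal(sqrt(sum(compose_network(net)^2)), A0, tolerance = 1e-9)
    expect_true(all(unlist(net$matrices) > 0))
  }
  expect_error(init_network(6, 4, 0), "A0")
})

test_that("node deletion zeroes the incoming row and outgoing column", {
  net <- all_ones_net(2, 2)
  del <- delete_node(net, 2, 1)
  expect_equal(del$matrices[[1]][1, ], c(0, 0))
  expect_equal(del$matrices[[2]][, 1], c(0, 0))
  # remaining path through middle node 2 only
  expect_equal(compose_network(del), matrix(1, 2, 2))
  # original untouched; idempotent; boundary layers rejected
  expect_equal(net$matrices[[1]], matrix(1, 2, 2))
  expect_identical(delete_node(del, 2, 1)$matrices, del$matrices)
  expect_error(delete_node(net, 1, 1), "middle")
  expect_error(delete_node(net, 3, 1), "middle")
})

test_that("deleting an already-disconnected node leaves fitness unchanged", {
  set.seed(4)
  net <- init_network(4, 3, 5)
  net$matrices[[1]][2, ] <- 0
  net$matrices[[2]][, 2] <- 0
  g <- generate_goal(4, 2, 5)
  expect_equal(network_fitness(delete_node(net, 2, 2), g),
               network_fitness(net, g))
})

test_that("node importance is uniform for a fully symmetric network", {
  net <- all_ones_net(6, 4)
  g <- generate_goal(6, 1, 60)
  for (d in c("fitness_drop", "inout_drop", "max_link")) {
    p <- node_importance(net, g, d)
    expect_equal(unname(p$values), matrix(1 / 6, 3, 6), tolerance = 1e-12)
  }
})

test_that("a single middle node carrying all flow gets importance 1", {
  # M=2, L=2; all flow through middle node 1
  net <- tiny_net(list(matrix(c(1, 0, 1, 0), 2, 2),
                       matrix(c(1, 1, 0, 0), 2, 2)))
  g <- goal_matrix(compose_network(net))
  for (d in c("fitness_drop", "inout_drop", "max_link")) {
    p <- node_importance(net, g, d)
    expect_equal(unname(p$values[1, ]), c(1, 0), tolerance = 1e-12,
                 label = d)
  }
  # exhaustive deletion confirms node 2 is neutral
  expect_equal(network_fitness(delete_node(net, 2, 2), g), 0)
})

test_that("importance rows sum to one when the layer is not neutral", {
  set.seed(5)
  g <- generate_goal(6, 3, 60)
  net <- init_network(6, 4, 10)
  for (d in c("fitness_drop", "inout_drop", "max_link")) {
    p <- node_importance(net, g, d)
    expect_equal(unname(rowSums(p$values)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("a neutral layer reports all nodes inactive", {
  # zero goal + zero network: every deletion changes nothing
  net <- layered_network(replicate(3, matrix(0, 3, 3), simplify = FALSE))
  p <- node_importance(net, matrix(0, 3, 3))
  expect_equal(unname(p$values), matrix(0, 2, 3))
  w <- waist_stats(p)
  expect_equal(w$waist_size, 0L)
})

test_that("waist statistics threshold, tie-break and bow-tie flag", {
  p <- structure(list(values = matrix(1 / 6, 3, 6), definition = "fitness_drop",
                      threshold = 0.001, M = 6), class = "node_importance")
  w <- waist_stats(p)
  expect_equal(w$waist_size, 6L)
  expect_false(w$is_bowtie)
  expect_equal(w$waist_layer, 2L) # tie -> lowest middle layer
  v <- matrix(0, 3, 6)
  v[, 1] <- 1
  v[2, ] <- c(1, 0, 0, 0, 0, 0)
  p$values <- v
  w2 <- waist_stats(p)
  expect_equal(w2$waist_size, 1L)
  expect_true(w2$is_bowtie)
  expect_error(waist_stats(p, threshold = 0), "threshold")
})

test_that("default thresholds follow the importance definition", {
  net <- all_ones_net(4, 2)
  g <- generate_goal(4, 1, 10)
  expect_equal(node_importance(net, g, "fitness_drop")$threshold, 0.001)
  expect_equal(node_importance(net, g, "inout_drop")$threshold, 0.001)
  expect_equal(node_importance(net, g, "max_link")$threshold, 0.05)
})

test_that("networks round-trip through json", {
  set.seed(6)
  net <- init_network(4, 3, 2)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- read_network(path)
  expect_equal(net2$matrices, net$matrices, tolerance = 1e-12)
})
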
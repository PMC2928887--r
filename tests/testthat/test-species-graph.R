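test_that("mating graph thresholds similarities into edges", {
  q <- init_similarity(5)
  expect_true(all(mating_graph(q, 0.9)[upper.tri(q)]))
  expect_false(any(diag(mating_graph(q, 0.9))))
  q[2, 4] <- q[4, 2] <- 0.5
  adj <- mating_graph(q, 0.9)
  expect_false(adj[2, 4])
  expect_equal(sum(adj), 5 * 4 - 2)
  # range kind drops excessively similar pairs
  q2 <- init_similarity(3); q2[1, 2] <- q2[2, 1] <- 0.95
  adj2 <- mating_graph(q2, 0.9, kind = "range", q_max = 0.99)
  expect_true(adj2[1, 2]); expect_false(adj2[1, 3])
})

test_that("species are connected components, transitively", {
  # path graph a-b-c: one species even though q_ac is below threshold
  q <- init_similarity(3)
  q[1, 3] <- q[3, 1] <- 0.2
  part <- species_partition(q, q_min = 0.5)
  expect_equal(length(unique(part$species)), 1)
  # two clusters of 5 and 4
  q <- matrix(0.2, 9, 9)
  q[1:5, 1:5] <- 0.99; q[6:9, 6:9] <- 0.99; diag(q) <- 1
  part <- species_partition(q, q_min = 0.9)
  expect_equal(sort(as.integer(table(part$species))), c(4L, 5L))
})

test_that("union-find agrees with an independent DFS oracle", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    q <- random_similarity(n)
    adj <- mating_graph(q, q_min = stats::runif(1, 0.2, 0.8))
    mine <- species_partition(adj)$species
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ref <- igraph::components(g)$membership
    expect_equal(as.integer(factor(mine, levels = unique(mine))),
                 as.integer(factor(ref, levels = unique(ref))))
  }
})

test_that("symmetry index is the smallest-new-to-mother abundance ratio", {
  expect_equal(symmetry_index(4, 4), 1)
  expect_equal(symmetry_index(1, 9), 1 / 9)
  expect_equal(symmetry_index(1, 5), 0.2)  # multi-way split {5,3,1}
  expect_error(symmetry_index(0, 5), ">= 1")
})

test_that("relabelling keeps the mother label on the largest fragment", {
  # component {1..9} splits into {1..5} and {6..9} after a bridge death
  # (slot 10 is the dead individual: keeps its label, no component)
  comp <- c(rep(1L, 5), rep(6L, 4), NA)
  rl <- relabel_and_detect(rep(1L, 10), comp, "after_death",
                           next_label = 2L)
  ev <- rl$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "speciation")
  expect_equal(ev$mode, "fission")
  expect_equal(ev$new_size, 4L)
  expect_equal(ev$mother_size, 5L)
  expect_equal(rl$labels[1:5], rep(1L, 5))
  expect_equal(rl$labels[6:9], rep(2L, 4))

  # no topology change: labels unchanged, zero events
  comp_same <- c(rep(1L, 9), NA)
  rl2 <- relabel_and_detect(rep(1L, 10), comp_same, "after_death",
                            next_label = 2L)
  expect_equal(nrow(rl2$events), 0)
  expect_equal(rl2$labels[1:9], rep(1L, 9))

  # death of a singleton species: extinction
  prev3 <- c(rep(1L, 8), 2L, 1L)
  comp3 <- c(rep(1L, 8), NA, 1L)
  rl3 <- relabel_and_detect(prev3, comp3, "after_death", next_label = 3L)
  expect_equal(rl3$events$type, "extinction")
  expect_equal(rl3$events$label, 2L)
})

test_that("an isolated newborn founds a mutation-induced species", {
  prev <- c(rep(1L, 5), NA)
  comp <- c(rep(1L, 5), 6L)  # newborn at slot 6, disconnected
  rl <- relabel_and_detect(prev, comp, "after_birth", offspring = 6,
                           next_label = 2L, mother_label = 1L)
  expect_equal(rl$events$mode, "mutation_induced")
  expect_equal(rl$events$new_size, 1L)
  expect_equal(rl$events$mother_size, 5L)
  expect_equal(rl$labels[6], 2L)
  # a newborn bridging two species triggers a merge, not a speciation
  prev2 <- c(1L, 1L, 1L, 2L, 2L, NA)
  comp2 <- rep(1L, 6)
  rl2 <- relabel_and_detect(prev2, comp2, "after_birth", offspring = 6,
                            next_label = 3L, mother_label = 1L)
  expect_equal(rl2$events$type, "merge")
  expect_equal(rl2$events$label, 2L)   # smaller species retired
  expect_equal(rl2$labels, c(1L, 1L, 1L, 1L, 1L, 1L))
})

test_that("constructed isolation matrix yields a mutation-induced event in a run", {
  # mu far above the one-step minimum: the very first birth from the
  # identical initial population is already below threshold to everyone
  p <- sim_params(N = 10, mu = 0.06, q_min = 0.95, generations = 2,
                  seed = 1)
  ev <- suppressWarnings(simulate_radiation(p))$events
  first <- ev[ev$type == "speciation", ][1, ]
  expect_equal(first$mode, "mutation_induced")
  expect_equal(first$step, 1L)
})
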
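test_that("initial population is fully compatible", {
  q <- init_similarity(5)
  expect_equal(q, matrix(1, 5, 5))
  expect_equal(nrow(unique(species_partition(q, q_min = 0.9)["species"])), 1)
  adj <- mating_graph(init_similarity(100), q_min = 0.99)
  expect_true(all(rowSums(adj) == 99))
})

test_that("offspring similarity follows the overlap recursion", {
  q <- init_similarity(4)
  expect_equal(offspring_similarity(q, 1, 2, mu = 0), rep(1, 4))
  q2 <- init_similarity(4)
  q2[1, 3] <- q2[3, 1] <- 0.4
  q2[2, 3] <- q2[3, 2] <- 0.6
  expect_equal(offspring_similarity(q2, 1, 2, mu = 0)[3], 0.5)
  # similarity to a parent from identical parents: e^(-2 mu)
  expect_equal(offspring_similarity(init_similarity(3), 1, 2, 0.01)[1],
               exp(-0.02))
  expect_error(offspring_similarity(q, 2, 2, 0.01), "selfing")
})

test_that("recursion matches the finite-genome oracle on random configurations", {
  # smaller sibling of the acceptance block: 10 configurations, L = 2500
  set.seed(42)
  L <- 2500
  for (cfg in 1:10) {
    mu <- stats::runif(1, 0.001, 0.05)
    g <- oracle_population(6, L, mu, births = 25)
    ps <- sample(6, 2)
    q <- outer(seq_len(6), seq_len(6),
               Vectorize(function(i, j) genome_similarity(g[[i]], g[[j]])))
    child <- oracle_offspring(g, ps[1], ps[2], mu)
    pred <- offspring_similarity(q, ps[1], ps[2], mu)
    obs <- vapply(g, function(x) genome_similarity(child, x), numeric(1))
    expect_lt(max(abs(pred - obs)), 3 / sqrt(L))
  }
})

test_that("equilibrium similarity is the mean-field fixed point", {
  expect_equal(equilibrium_similarity(50, 0), 1)
  lam <- exp(-2 * 0.005)
  expect_equal(equilibrium_similarity(50, 0.005),
               lam / (49 - lam * 48))
  # strictly decreasing in N and in mu
  expect_lt(equilibrium_similarity(100, 0.005),
            equilibrium_similarity(50, 0.005))
  expect_lt(equilibrium_similarity(50, 0.01),
            equilibrium_similarity(50, 0.005))
  # small-mu behavior ~ 1/(1 + 2 N mu)
  expect_equal(equilibrium_similarity(1000, 1e-5),
               1 / (1 + 2 * 1000 * 1e-5), tolerance = 1e-3)
})

test_that("minimum mutation rate for one-step isolation is -log(q_min)/2", {
  expect_equal(min_mutation_rate(exp(-2)), 1)
  expect_equal(min_mutation_rate(0.95), -log(0.95) / 2)
  expect_lt(min_mutation_rate(0.9999), 1e-4)  # q_min -> 1 limit
  expect_error(min_mutation_rate(0), "strictly inside")
  expect_error(min_mutation_rate(1), "strictly inside")
  # exhaustive check of the one-step definition: from identical compatible
  # parents the offspring disconnects iff mu exceeds the threshold
  q_min <- 0.9
  mm <- min_mutation_rate(q_min)
  for (mu in c(mm * 0.9, mm * 0.99, mm * 1.01, mm * 1.5)) {
    off <- exp(-2 * mu) * (1 + 1) / 2
    expect_equal(off < q_min, mu > mm)
  }
})

test_that("feasibility gate compares equilibrium similarity to the threshold", {
  expect_false(speciation_feasible(50, 0, 0.99))
  expect_true(speciation_feasible(50, 0.005, 0.9))   # q_hat ~ 0.67 < 0.9
  expect_false(speciation_feasible(50, 1e-4, 0.2))   # q_hat ~ 0.99 > 0.2
})
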
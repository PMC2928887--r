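test_that("viability kinds honor thresholds and boundaries", {
  expect_equal(viability(c(0.94, 0.95, 1), q_min = 0.95), c(0, 1, 1))
  expect_equal(viability(1, q_min = 0.9, kind = "range", q_max = 0.99), 0)
  expect_equal(viability(0.95, q_min = 0.9, kind = "range", q_max = 0.99), 1)
  expect_equal(viability(1, q_min = 0.5, kind = "linear"), 1)
  expect_equal(viability(0.75, q_min = 0.5, kind = "linear"), 0.5)
  expect_equal(viability(1, q_min = 0.5, kind = "exponential", shape = 3), 1)
  expect_equal(viability(0.5, q_min = 0.5, kind = "exponential"), 0)
  # monotone nondecreasing on [q_min, 1]
  for (kind in c("step", "linear", "exponential")) {
    v <- viability(seq(0.5, 1, by = 0.01), q_min = 0.5, kind = kind)
    expect_true(all(diff(v) >= 0))
  }
  expect_error(viability(1.4, q_min = 0.5), "\\[0, 1\\]")
})

test_that("compatible partners respect thresholds and spatial restriction", {
  q <- init_similarity(4)
  q[1, 2:4] <- q[2:4, 1] <- c(0.97, 0.94, 0.96)
  expect_equal(compatible_partners(q, 1, q_min = 0.95), c(2L, 4L))
  expect_equal(compatible_partners(init_similarity(6), 3, q_min = 0.5),
               c(1L, 2L, 4L, 5L, 6L))
  # spatial restriction only removes candidates
  nb <- radsim:::neighbor_list(spatial_grid(4, 4), 16)
  qs <- init_similarity(16)
  for (i in c(1, 6, 16)) {
    sp <- compatible_partners(qs, i, q_min = 0.5, neighbors = nb[[i]])
    expect_true(all(sp %in% compatible_partners(qs, i, q_min = 0.5)))
    expect_lte(length(sp), 8)
  }
})

test_that("compatibility is symmetric", {
  set.seed(1)
  q <- random_similarity(12)
  for (i in 1:12) {
    for (j in compatible_partners(q, i, q_min = 0.5))
      expect_true(i %in% compatible_partners(q, j, q_min = 0.5))
  }
})

test_that("parent weights implement the rare-type advantage", {
  expect_equal(parent_weights(c(3, 3, 3), "frequency_dependent"),
               rep(1 / 3, 3))
  expect_equal(parent_weights(c(3, 3, 3), "neutral"), rep(1 / 3, 3))
  w <- parent_weights(c(9, 1), "frequency_dependent")
  expect_gt(w[2], w[1])
  expect_equal(sum(w), 1)
  expect_equal(parent_weights(c(1, 0), "neutral")[2], 0)
  # strictly decreasing in degree, both families
  for (form in c("inverse_degree", "linear_deficit")) {
    w <- parent_weights(c(1, 2, 3, 0), "frequency_dependent", form)
    expect_true(all(diff(w[1:3]) < 0))
    expect_equal(w[4], 0)
  }
  expect_error(parent_weights(c(0, 0), "neutral"), "sterile")
})

test_that("mate choice is uniform over the first parent's compatible set", {
  q <- init_similarity(5)
  q[1, 2:5] <- q[2:5, 1] <- c(0.99, 0.99, 0.99, 0.2)
  q[2:5, 2:5][q[2:5, 2:5] != 1] <- 0.2  # only 1 has partners 2,3,4
  params <- sim_params(N = 5, mu = 0, q_min = 0.9)
  set.seed(99)
  draws <- replicate(6000, choose_parents(q, params)[2])
  tab <- table(factor(draws, levels = 2:4))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("frequency dependence prefers the low-degree individual as parent", {
  # ring-of-9 all mutually compatible, plus one individual compatible with
  # exactly one of them: degrees (9,...,9,1)
  n <- 10
  q <- matrix(0.99, n, n); diag(q) <- 1
  q[n, ] <- q[, n] <- 0.2; q[n, n] <- 1
  q[n, 1] <- q[1, n] <- 0.99
  params <- sim_params(N = n, mu = 0, q_min = 0.9,
                       regime = "frequency_dependent")
  set.seed(7)
  p1 <- replicate(4000, choose_parents(q, params)[1])
  counts <- tabulate(p1, n)
  expect_gt(counts[n], max(counts[2:(n - 1)]))
  # two mutually compatible survivors -> that pair deterministically
  q2 <- matrix(0.2, 4, 4); diag(q2) <- 1
  q2[1, 2] <- q2[2, 1] <- 0.99
  pr <- choose_parents(q2, sim_params(N = 4, mu = 0, q_min = 0.9))
  expect_setequal(pr, c(1, 2))
})

test_that("neutral and frequency-dependent regimes coincide at equal degrees", {
  p_n <- sim_params(N = 24, mu = 0.004, q_min = 0.5, generations = 30,
                    seed = 3, regime = "neutral")
  p_f <- sim_params(N = 24, mu = 0.004, q_min = 0.5, generations = 30,
                    seed = 3, regime = "frequency_dependent")
  # q_min far below equilibrium: the graph stays complete, degrees equal,
  # so the two regimes draw identical trajectories from the same seed
  a <- simulate_radiation(p_n)
  b <- simulate_radiation(p_f)
  expect_equal(a$final_q, b$final_q)
  expect_identical(a$final_labels, b$final_labels)
})
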
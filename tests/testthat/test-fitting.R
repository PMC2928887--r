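test_that("time normalization maps first event to 0 and present to 1", {
  s <- normalize_times(event_series(c(10, 20), present = 30))
  expect_equal(s$time, c(0, 0.5))
  expect_equal(attr(s, "present"), 1)
  expect_equal(normalize_times(s)$time, s$time)  # idempotent
  set.seed(2)
  r <- event_series(sort(stats::runif(8, 0, 90)), present = 100)
  n <- normalize_times(r)
  expect_equal(n$time[1], 0)
  expect_true(all(n$time <= 1))
  expect_equal(n$cumulative, r$cumulative)
  expect_error(normalize_times(event_series(numeric(0), present = 1)),
               "no events")
})

test_that("misfit identities and the worked two-event example", {
  obs <- event_series(c(0, 1), cumulative = c(2, 3), present = 1)
  expect_equal(as.numeric(align_misfit(obs, obs)), 0)
  sim <- event_series(c(0, 0.8), cumulative = c(2, 3), present = 1)
  expect_equal(as.numeric(align_misfit(obs, sim)), 0.2)
  # invariance to the original time units
  sim_gen <- event_series(c(100, 180), cumulative = c(2, 3), present = 200)
  expect_equal(as.numeric(align_misfit(obs, sim_gen)), 0.2)
  obs_gen <- event_series(c(5, 25), cumulative = c(2, 3), present = 25)
  expect_equal(as.numeric(align_misfit(obs_gen, sim)), 0.2)
  expect_error(align_misfit(event_series(c(1, 2, 3), present = 4),
                            event_series(c(1, 2), present = 4)),
               "insufficient")
})

test_that("self-alignment is exact and extra events never hurt", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    times <- sort(stats::runif(k, 0, 0.9))
    s <- event_series(times, present = 1)
    expect_equal(as.numeric(align_misfit(s, s)), 0)
    # appending later events can only add candidate windows
    extra <- event_series(c(times, sort(stats::runif(3, max(times), 1))),
                          present = 1)
    expect_lte(as.numeric(align_misfit(s, extra)),
               as.numeric(align_misfit(s, s)) + 1e-12)
    e1 <- as.numeric(align_misfit(s, extra))
    expect_gte(e1, 0)
  }
})

test_that("misfit is positive whenever counts or times disagree", {
  obs <- event_series(c(0, 0.5), cumulative = c(2, 3), present = 1)
  sim <- event_series(c(0, 0.5), cumulative = c(2, 4), present = 1)
  expect_gt(as.numeric(align_misfit(obs, sim)), 0)
})

test_that("grid search returns the scored surface and enforces feasibility", {
  obs <- event_series(c(5, 20, 60, 90), present = 200)
  grid1 <- data.frame(q_min = 0.95, mu = 0.01, N = 32)
  fit <- fit_radiation(obs, grid1, reps = 3, generations = 200, seed = 42)
  expect_equal(nrow(fit$surface), 1)
  expect_equal(fit$E_min, fit$surface$mean_E[1])
  expect_equal(fit$nll, fit$E_min)
  expect_gte(fit$E_min, 0)
  expect_error(
    fit_radiation(obs, data.frame(q_min = 0.2, mu = 1e-4, N = 32),
                  reps = 2, generations = 50),
    "infeasible")
  # ranking by mean E is ranking by negative log-likelihood
  expect_equal(order(fit$surface$mean_E), order(fit$surface$nll))
})

test_that("confidence bands bracket the pointwise median", {
  obs <- event_series(c(5, 20, 60, 90), present = 200)
  grid <- data.frame(q_min = c(0.94, 0.96), mu = 0.01, N = 32)
  fit <- fit_radiation(obs, grid, reps = 4, generations = 200, seed = 9)
  band <- confidence_band(fit, reps = 4)
  expect_true(all(band$lower <= band$median & band$median <= band$upper))
  expect_true(all(diff(band$median) >= 0))
  cov <- band_coverage(band, obs)
  expect_true(cov >= 0 && cov <= 1)
})

test_that("fit accessors expose the surface and the best triple", {
  obs <- event_series(c(5, 20, 60), present = 150)
  grid <- data.frame(q_min = c(0.94, 0.96), mu = 0.01, N = 32)
  fit <- fit_radiation(obs, grid, reps = 2, generations = 150, seed = 3)
  expect_equal(nrow(tidy(fit)), 2)
  g <- glance(fit)
  expect_equal(g$E_min, min(fit$surface$mean_E, na.rm = TRUE))
  expect_gte(g$n_within_2, 1)
})
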
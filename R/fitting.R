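#' Speciation-event series
#'
#' A species-through-time event series: the (nondecreasing) times of
#' speciation events together with the cumulative species count at each
#' event, plus the end-of-observation time (`present`). This is both the
#' simulator output consumed by the fitting routines and the format of
#' observed data.
#'
#' @param x A `radsim_sim`, an `events` tibble, or a numeric vector of
#'   event times.
#' @param cumulative Cumulative species counts (defaults to
#'   `1 + seq_along(times)`: one new species per event on top of the
#'   single founding species).
#' @param present End of observation (defaults to the run length or
#'   `max(times)`).
#' @return A `radsim_series` tibble with columns `time`, `cumulative` and
#'   attribute `present`.
#' @examples
#' event_series(c(3, 7, 9), present = 10)
#' @export
event_series <- function(x, cumulative = NULL, present = NULL) {
  if (inherits(x, "radsim_sim")) {
    times <- x$events$generation[x$events$type == "speciation"]
    present <- present %||% x$generations_done
  } else if (is.data.frame(x)) {
    times <- x$generation[x$type == "speciation"]
    present <- present %||% max(0, times)
  } else {
    times <- as.numeric(x)
    present <- present %||% max(times)
  }
  if (is.unsorted(times)) stop("event times must be nondecreasing",
                               call. = FALSE)
  cumulative <- cumulative %||% (1 + seq_along(times))
  if (length(cumulative) != length(times))
    stop("times and cumulative counts differ in length", call. = FALSE)
  if (length(cumulative) > 1 && any(diff(cumulative) < 1))
    stop("cumulative counts must increase by at least 1 per event",
         call. = FALSE)
  if (length(times) && max(times) > present)
    stop("event times must not exceed `present`", call. = FALSE)
  out <- tibble::tibble(time = times, cumulative = as.numeric(cumulative))
  attr(out, "present") <- as.numeric(present)
  class(out) <- c("radsim_series", class(out))
  out
}

#' Normalize an event series to the unit interval
#'
#' Affine map sending the first speciation event to 0 and the present time
#' to 1; cumulative counts are unchanged. Idempotent on an already
#' normalized series.
#'
#' @param series A [event_series()].
#' @return A normalized `radsim_series` (`present` attribute = 1).
#' @examples
#' normalize_times(event_series(c(10, 20), present = 30))
#' @export
normalize_times <- function(series) {
  stopifnot(inherits(series, "radsim_series"))
  if (nrow(series) == 0)
    stop("cannot normalize a series with no events", call. = FALSE)
  t0 <- series$time[1]
  present <- attr(series, "present")
  if (present <= t0)
    stop("present time must exceed the first event time", call. = FALSE)
  event_series((series$time - t0) / (present - t0),
               cumulative = series$cumulative, present = 1)
}

#' Quasi-likelihood misfit between observed and simulated series
#'
#' Both series are normalized to `[0, 1]` (first event to 0, present to
#' 1). For each admissible window of the simulated series -- every
#' starting event under `"sliding"` (the default), or every truncation
#' time treated as the present under `"prefix"` -- the window is
#' renormalized, its cumulative counts rebased to a one-species baseline,
#' its first `k` events paired in order with the `k` observed events, and
#' the misfit
#' \deqn{E = \sum_{i=1}^{k} \big(|\Delta S_i| + |\Delta\tau_i|\big)}
#' accumulated from the species-count and normalized-time differences.
#' The minimum over windows is returned (ties: earliest window). Under
#' exponentially distributed errors `E` is the model negative
#' log-likelihood, so parameter sets within 2 units of the minimum form
#' the usual quasi-likelihood confidence family.
#'
#' @param obs Observed [event_series()] (`k` events).
#' @param sim Simulated [event_series()] (needs at least `k` events).
#' @param window `"sliding"` or `"prefix"`.
#' @return The minimal misfit `E >= 0`, with attributes `window_start`
#'   (index of the best window's first event) and `k`.
#' @examples
#' obs <- event_series(c(0, 1), cumulative = c(2, 3), present = 1)
#' sim <- event_series(c(0, 0.8), cumulative = c(2, 3), present = 1)
#' align_misfit(obs, sim)  # 0.2
#' @export
align_misfit <- function(obs, sim, window = c("sliding", "prefix")) {
  window <- match.arg(window)
  obs <- normalize_times(obs)
  k <- nrow(obs)
  m <- nrow(sim)
  if (m < k)
    stop("insufficient events: simulation has fewer events than the data",
         call. = FALSE)
  sim <- normalize_times(sim)
  o_t <- obs$time
  o_c <- obs$cumulative
  best <- Inf
  best_start <- 1L
  if (window == "sliding") {
    for (s in seq_len(m - k + 1)) {
      t0 <- sim$time[s]
      tt <- (sim$time[s:(s + k - 1)] - t0) / (1 - t0)
      cc <- sim$cumulative[s:(s + k - 1)] -
        (if (s > 1) sim$cumulative[s - 1] else 1) + 1
      E <- sum(abs(o_c - cc) + abs(o_t - tt))
      if (E < best - 1e-12) { best <- E; best_start <- s }
    }
  } else {
    # vary the truncation time (treated as the present) over event times
    # of the k-th and later events, plus the full present
    ends <- unique(c(sim$time[k:m], 1))
    for (Tend in ends) {
      tt <- sim$time[1:k] / max(Tend, .Machine$double.eps)
      cc <- sim$cumulative[1:k] - sim$cumulative[1] + 2
      E <- sum(abs(o_c - cc) + abs(o_t - tt))
      if (E < best - 1e-12) { best <- E; best_start <- 1L }
    }
  }
  structure(best, window_start = best_start, k = k)
}

#' Grid-search quasi-likelihood fit
#'
#' For every parameter triple `(q_min, mu, N)` in the grid, runs `reps`
#' simulator replicates (replicate `r` uses seed `seed + r`), scores each
#' replicate's speciation-event series against the observed series with
#' [align_misfit()], and averages over replicates with at least as many
#' events as the data (the rest are reported missing). The best fit
#' minimizes the mean misfit; because `E` is a negative log-likelihood up
#' to the exponential error scale, the surface doubles as a
#' quasi-likelihood surface. Triples that cannot fragment the
#' compatibility graph ([speciation_feasible()] is `FALSE`) are rejected.
#'
#' @param obs Observed [event_series()].
#' @param grid A data frame with columns `q_min`, `mu`, `N` (one row per
#'   triple).
#' @param reps Replicates per triple.
#' @param generations Run length per replicate (generations).
#' @param seed Base seed.
#' @param regime,... Passed to [sim_params()].
#' @param window Passed to [align_misfit()].
#' @return A `radsim_fit` object: `best` (one-row tibble), `surface`
#'   (tibble `q_min`, `mu`, `N`, `mean_E`, `n_missing`, `nll`), `E_min`,
#'   `nll` and the call settings needed by [confidence_band()].
#' @examples
#' \donttest{
#' obs <- event_series(c(10, 30, 60), present = 100)
#' grid <- expand.grid(q_min = c(0.9, 0.95), mu = c(0.005, 0.01), N = 40)
#' fit <- fit_radiation(obs, grid, reps = 3, generations = 100)
#' glance(fit)
#' }
#' @export
fit_radiation <- function(obs, grid, reps = 20, generations = 500,
                          seed = 1, regime = "neutral",
                          window = c("sliding", "prefix"), ...) {
  window <- match.arg(window)
  stopifnot(is.data.frame(grid), nrow(grid) > 0,
            all(c("q_min", "mu", "N") %in% names(grid)), reps >= 1)
  feas <- mapply(speciation_feasible, grid$N, grid$mu, grid$q_min)
  if (!all(feas))
    stop("grid contains infeasible triples (equilibrium similarity above ",
         "q_min); pre-filter with speciation_feasible()", call. = FALSE)
  obs <- normalize_times(obs)

  score_triple <- function(q_min, mu, N) {
    Es <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      p <- sim_params(N = N, mu = mu, q_min = q_min, regime = regime,
                      generations = generations, seed = seed + r, ...)
      sim <- simulate_radiation(p, snapshot_every = generations)
      ser <- event_series(sim)
      if (nrow(ser) >= nrow(obs))
        Es[r] <- as.numeric(align_misfit(obs, ser, window = window))
    }
    c(mean_E = mean(Es, na.rm = TRUE), n_missing = sum(is.na(Es)))
  }

  sc <- mapply(score_triple, grid$q_min, grid$mu, grid$N)
  surface <- tibble::tibble(
    q_min = grid$q_min, mu = grid$mu, N = as.integer(grid$N),
    mean_E = sc["mean_E", ], n_missing = as.integer(sc["n_missing", ]))
  if (all(!is.finite(surface$mean_E)))
    stop("fit failure: every replicate of every triple had fewer events ",
         "than the data", call. = FALSE)
  surface$nll <- surface$mean_E
  best_i <- which.min(surface$mean_E)
  structure(
    list(best = surface[best_i, ], surface = surface,
         E_min = surface$mean_E[best_i], nll = surface$mean_E[best_i],
         obs = obs, reps = reps, generations = generations, seed = seed,
         regime = regime, window = window, extra = list(...)),
    class = "radsim_fit")
}

#' @export
print.radsim_fit <- function(x, ...) {
  cat("<radsim_fit> grid of", nrow(x$surface), "feasible triples,",
      x$reps, "replicates each\n")
  cat(sprintf("  best: q_min = %g, mu = %g, N = %d  (mean E = %.3f)\n",
              x$best$q_min, x$best$mu, x$best$N, x$E_min))
  n2 <- sum(x$surface$mean_E <= x$E_min + 2, na.rm = TRUE)
  cat(" ", n2, "triple(s) within 2 log-likelihood units of the minimum\n")
  invisible(x)
}

#' @export
tidy.radsim_fit <- function(x, ...) x$surface

#' @export
glance.radsim_fit <- function(x, ...) {
  tibble::tibble(q_min = x$best$q_min, mu = x$best$mu, N = x$best$N,
                 E_min = x$E_min, nll = x$nll,
                 n_within_2 = sum(x$surface$mean_E <= x$E_min + 2,
                                  na.rm = TRUE),
                 n_triples = nrow(x$surface))
}

#' Percentile confidence band for species-through-time
#'
#' Pools species-through-time curves from fresh replicates at the best
#' triple and at every grid triple within 2 log-likelihood units of the
#' minimum, and takes pointwise 2.5% and 97.5% percentiles (plus the
#' median) on the normalized time axis. Each replicate contributes the
#' best-matching window of its event series -- the same alignment
#' [align_misfit()] scores -- renormalized and rebased exactly as in the
#' misfit, so the pooled curves are commensurable with the observed
#' series; replicates with fewer events than the data are skipped.
#'
#' @param fit A [fit_radiation()] result.
#' @param reps Replicates per contributing triple.
#' @param times Normalized time grid.
#' @param probs Lower/upper percentile probabilities.
#' @return A tibble with columns `time`, `lower`, `median`, `upper`.
#' @export
confidence_band <- function(fit, reps = fit$reps,
                            times = seq(0, 1, by = 0.02),
                            probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "radsim_fit"))
  fam <- fit$surface[is.finite(fit$surface$mean_E) &
                     fit$surface$mean_E <= fit$E_min + 2, ]
  obs <- fit$obs
  k <- nrow(obs)
  curves <- list()
  for (i in seq_len(nrow(fam))) {
    for (r in seq_len(reps)) {
      p <- do.call(sim_params,
                   c(list(N = fam$N[i], mu = fam$mu[i], q_min = fam$q_min[i],
                          regime = fit$regime,
                          generations = fit$generations,
                          seed = fit$seed + 1000 * i + r),
                     fit$extra))
      sim <- simulate_radiation(p, snapshot_every = fit$generations)
      ser <- event_series(sim)
      if (nrow(ser) < k) next
      E <- align_misfit(obs, ser, window = fit$window)
      s <- attr(E, "window_start")
      ser <- normalize_times(ser)
      t0 <- ser$time[s]
      tt <- (ser$time[s:(s + k - 1)] - t0) / (1 - t0)
      curves[[length(curves) + 1]] <-
        vapply(times, function(x) 1 + sum(tt <= x), numeric(1))
    }
  }
  if (!length(curves))
    stop("no replicate produced enough speciation events", call. = FALSE)
  mat <- do.call(rbind, curves)
  tibble::tibble(
    time = times,
    lower = apply(mat, 2, stats::quantile, probs = probs[1]),
    median = apply(mat, 2, stats::median),
    upper = apply(mat, 2, stats::quantile, probs = probs[2]))
}

#' Coverage of an observed series by a confidence band
#'
#' Fraction of the band's sampled time points at which the observed
#' species-through-time step curve (count = 1 + events so far, on the
#' normalized axis) lies inside the band.
#'
#' @param band A [confidence_band()] tibble.
#' @param obs Observed [event_series()].
#' @return Fraction in `[0, 1]`.
#' @export
band_coverage <- function(band, obs) {
  obs <- normalize_times(obs)
  oc <- vapply(band$time, function(tt) 1 + sum(obs$time <= tt), numeric(1))
  mean(oc >= band$lower & oc <= band$upper)
}
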
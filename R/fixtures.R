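#' Synthetic observed event series
#'
#' Generates small observed species-through-time series with known
#' generating parameters, standing in for empirical radiation data (which
#' exist only as published figure points). Three kinds:
#' \describe{
#'   \item{`constant_rate`}{events equally spaced in normalized time --
#'     the steady, niche-independent radiation shape.}
#'   \item{`burst_plateau`}{at least 70% of events in the first 30% of
#'     normalized time -- the declining-rate radiation shape produced by
#'     negative frequency-dependent selection.}
#'   \item{`self_recovery`}{a full simulator run at stated parameters; the
#'     truth sidecar carries the generating triple, so fitting can be
#'     checked for parameter recovery.}
#' }
#'
#' @param kind Fixture kind.
#' @param seed Integer seed.
#' @param n_events Number of events (ignored for `self_recovery`).
#' @param params [sim_params()] used by `self_recovery` (default: a
#'   feasible neutral triple).
#' @return A list with `series` (a [event_series()], normalized for the
#'   analytic kinds) and `truth` (generating parameters / shape).
#' @examples
#' fx <- fixture_event_series("burst_plateau", seed = 1)
#' fx$series
#' @export
fixture_event_series <- function(kind = c("constant_rate", "burst_plateau",
                                          "self_recovery"),
                                 seed = 1, n_events = 10, params = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "constant_rate") {
    k <- n_events
    times <- (seq_len(k) - 1) / k
    list(series = event_series(times, present = 1),
         truth = list(kind = kind, n_events = k, rate = k))
  } else if (kind == "burst_plateau") {
    k <- n_events
    k_early <- ceiling(0.75 * k)
    early <- sort(stats::runif(k_early, 0, 0.28))
    late <- sort(stats::runif(k - k_early, 0.35, 0.95))
    times <- c(0, early[-1], late)
    list(series = event_series(times, present = 1),
         truth = list(kind = kind, n_events = k,
                      burst_fraction = k_early / k))
  } else {
    if (is.null(params))
      params <- sim_params(N = 64, mu = 0.005, q_min = 0.95,
                           generations = 500, seed = seed)
    sim <- simulate_radiation(params, snapshot_every = params$generations)
    list(series = event_series(sim),
         truth = list(kind = kind, N = params$N, mu = params$mu,
                      q_min = params$q_min, regime = params$regime,
                      generations = params$generations, seed = params$seed))
  }
}

#' Write a fixture to disk
#'
#' Writes the observed series as TSV (via [write_series_tsv()]) and the
#' truth sidecar as YAML next to it (`<stem>_truth.yaml`).
#'
#' @param fixture A [fixture_event_series()] result.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fixture, path) {
  write_series_tsv(fixture$series, path)
  yaml::write_yaml(fixture$truth,
                   sub("\\.tsv$", "_truth.yaml", path))
  invisible(path)
}
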
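#' Species-through-time curves
#'
#' The total number of species ever created (extant plus extinct; a
#' nondecreasing step function starting at 1) and the number of extant
#' species (total minus cumulative extinctions; merged labels are treated
#' as losses of extant labels but are not extinctions), both sampled once
#' per generation.
#'
#' @param x A `radsim_sim` object or its `events` tibble.
#' @param present End of observation in generations (defaults to the run
#'   length).
#' @param by Sampling interval in generations.
#' @return A tibble with columns `generation`, `total`, `extant`.
#' @examples
#' p <- sim_params(N = 30, mu = 0.01, q_min = 0.95, generations = 50)
#' species_through_time(simulate_radiation(p))
#' @export
species_through_time <- function(x, present = NULL, by = 1) {
  ev <- if (inherits(x, "radsim_sim")) x$events else x
  if (is.null(present)) {
    present <- if (inherits(x, "radsim_sim")) x$generations_done
               else max(0, ev$generation)
  }
  grid <- seq(0, present, by = by)
  sp <- ev$generation[ev$type == "speciation"]
  ex <- ev$generation[ev$type == "extinction"]
  mg <- ev$generation[ev$type == "merge"]
  total <- 1 + vapply(grid, function(g) sum(sp <= g), numeric(1))
  lost <- vapply(grid, function(g) sum(ex <= g) + sum(mg <= g), numeric(1))
  tibble::tibble(generation = grid, total = total, extant = total - lost)
}

#' Speciation rate in sliding windows and its temporal trend
#'
#' Events per generation in consecutive windows after the transient (the
#' transient ends at the first speciation event), with the least-squares
#' slope of rate against window midpoint. The trend tag is `"constant"`
#' when the fitted linear trend changes the rate by less than half its
#' mean level over the observed span (overridable via `tol`), otherwise
#' `"declining"` or `"increasing"` by the slope sign.
#'
#' @param x A `radsim_sim`, an `events` tibble, or a [event_series()].
#' @param window Window width in generations.
#' @param present End of observation in generations.
#' @param tol Absolute slope below which the trend counts as constant;
#'   `NULL` uses `0.5 * mean(rate) / span` (the fitted change over the
#'   whole span must exceed half the mean rate to count as a trend).
#' @return A `radsim_trend` object: list with `rates` (tibble `midpoint`,
#'   `rate`), `slope`, `slope_se`, `tag`, `transient`.
#' @examples
#' p <- sim_params(N = 40, mu = 0.01, q_min = 0.95, generations = 100)
#' speciation_rate(simulate_radiation(p), window = 10)
#' @export
speciation_rate <- function(x, window = 10, present = NULL, tol = NULL) {
  if (inherits(x, "radsim_series")) {
    times <- x$time
    if (is.null(present)) present <- attr(x, "present")
  } else {
    ev <- if (inherits(x, "radsim_sim")) x$events else x
    times <- ev$generation[ev$type == "speciation"]
    if (is.null(present)) {
      present <- if (inherits(x, "radsim_sim")) x$generations_done
                 else max(0, times)
    }
  }
  stopifnot(window > 0)
  if (length(times) < 3) {
    out <- list(rates = tibble::tibble(midpoint = numeric(0),
                                       rate = numeric(0)),
                slope = NA_real_, slope_se = NA_real_, tag = "undefined",
                transient = if (length(times)) min(times) else NA_real_)
    return(structure(out, class = "radsim_trend"))
  }
  transient <- min(times)
  breaks <- seq(transient, present, by = window)
  if (utils::tail(breaks, 1) < present) breaks <- c(breaks, present)
  if (length(breaks) < 2) breaks <- c(transient, present)
  counts <- graphics::hist(times[times >= transient & times <= present],
                           breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  widths <- diff(breaks)
  rates <- tibble::tibble(midpoint = breaks[-length(breaks)] + widths / 2,
                          rate = counts / widths)
  if (nrow(rates) >= 3 && stats::sd(rates$rate) > 0) {
    fit <- stats::lm(rate ~ midpoint, data = rates)
    slope <- unname(stats::coef(fit)[2])
    slope_se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  } else {
    slope <- 0
    slope_se <- NA_real_
  }
  span <- diff(range(rates$midpoint))
  thr <- if (!is.null(tol)) tol
         else if (span > 0) 0.5 * mean(rates$rate) / span
         else Inf
  tag <- if (abs(slope) <= thr) "constant"
         else if (slope < 0) "declining" else "increasing"
  structure(list(rates = rates, slope = slope, slope_se = slope_se,
                 tag = tag, transient = transient),
            class = "radsim_trend")
}

#' @export
print.radsim_trend <- function(x, ...) {
  cat("<radsim_trend> tag:", x$tag, "\n")
  cat(sprintf("  slope = %.4g (SE %.4g) over %d windows; transient ends at %.4g\n",
              x$slope, x$slope_se, nrow(x$rates), x$transient))
  invisible(x)
}

#' @export
tidy.radsim_trend <- function(x, ...) x$rates

#' @export
glance.radsim_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se, tag = x$tag,
                 transient = x$transient,
                 mean_rate = mean(x$rates$rate))
}

#' Ranked relative species abundances
#'
#' Species sizes divided by the population size, sorted from the most
#' common to the most rare (the rank-abundance curve).
#'
#' @param sizes Integer vector of species abundances, or a `radsim_sim`
#'   (final partition used).
#' @return A tibble with columns `rank`, `relative_abundance`.
#' @examples
#' abundance_distribution(c(5, 4))
#' @export
abundance_distribution <- function(sizes) {
  if (inherits(sizes, "radsim_sim"))
    sizes <- as.integer(table(sizes$final_labels))
  stopifnot(length(sizes) > 0, all(sizes > 0))
  p <- sort(sizes, decreasing = TRUE) / sum(sizes)
  tibble::tibble(rank = seq_along(p), relative_abundance = p)
}

#' Shannon diversity
#'
#' `H = -sum(p log p)` in nats over relative abundances: 0 for a single
#' species, `log(k)` for `k` equally abundant species.
#'
#' @param p Relative abundances summing to 1, or a `radsim_sim`.
#' @return Shannon entropy (nats).
#' @examples
#' shannon_diversity(c(0.5, 0.25, 0.25))
#' @export
shannon_diversity <- function(p) {
  if (inherits(p, "radsim_sim"))
    p <- abundance_distribution(p)$relative_abundance
  if (abs(sum(p) - 1) > 1e-8)
    stop("relative abundances must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Abundance symmetry after each speciation event
#'
#' The per-event symmetry `s = new_size / mother_size` (see
#' [symmetry_index()]) with the event time.
#'
#' @param x A `radsim_sim` or its `events` tibble.
#' @return A tibble with columns `generation`, `mode`, `s`.
#' @export
symmetry_series <- function(x) {
  ev <- if (inherits(x, "radsim_sim")) x$events else x
  sp <- ev[ev$type == "speciation", ]
  tibble::tibble(generation = sp$generation, mode = sp$mode,
                 s = if (nrow(sp)) symmetry_index(sp$new_size,
                                                  sp$mother_size)
                     else numeric(0))
}

#' One-row summary of a run
#'
#' Extant and total species counts, Shannon diversity of the stationary
#' abundances, mean abundance symmetry over speciation events,
#' post-transient speciation rate and its trend tag. Stationarity
#' quantities use the final snapshot; `stationary_frac` controls the tail
#' of the run over which the extant count is averaged.
#'
#' @param sim A `radsim_sim`.
#' @param window Window width (generations) for the rate trend; defaults
#'   to 1/20 of the run length.
#' @param stationary_frac Final fraction of the run treated as stationary.
#' @return A one-row tibble.
#' @export
summarize_radiation <- function(sim, window = NULL, stationary_frac = 0.1) {
  stopifnot(inherits(sim, "radsim_sim"))
  if (is.null(window)) window <- max(1, sim$generations_done / 20)
  stt <- species_through_time(sim)
  tail_from <- (1 - stationary_frac) * sim$generations_done
  extant_stat <- mean(stt$extant[stt$generation >= tail_from])
  tr <- speciation_rate(sim, window = window)
  ss <- symmetry_series(sim)
  h <- if (any(sim$final_labels > 0)) shannon_diversity(sim) else NA_real_
  tibble::tibble(
    extant = utils::tail(stt$extant, 1),
    extant_stationary = extant_stat,
    total = utils::tail(stt$total, 1),
    shannon = h,
    mean_symmetry = if (nrow(ss)) mean(ss$s) else NA_real_,
    post_transient_rate = if (nrow(tr$rates)) mean(tr$rates$rate)
                          else NA_real_,
    rate_slope = tr$slope,
    trend = tr$tag)
}
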
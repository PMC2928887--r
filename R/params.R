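#' Simulation parameters
#'
#' Builds and validates the full parameterization of one simulation run:
#' population size, mutation rate, the assortative-mating thresholds, the
#' selection regime, the offspring-viability function, optional spatial
#' (lattice) mating restriction, run length and seed.
#'
#' The population holds exactly one haploid, hermaphroditic individual per
#' site; density is kept constant by zero-sum dynamics (every death is
#' immediately matched by a birth). One generation is `N` elementary
#' death--birth steps (Moran convention).
#'
#' @param N Population size (number of sites/individuals), at least 2.
#' @param mu Mutation rate per genome-similarity unit per birth
#'   (dimensionless, `>= 0`): a newborn's similarity to any survivor is
#'   multiplied by `exp(-2 * mu)`.
#' @param q_min Minimum genetic similarity (proportion of identical
#'   nucleotides, in `[0, 1]`) required for fertile offspring.
#' @param q_max Optional maximum similarity for mating (in `(q_min, 1]`);
#'   `NULL` disables self-incompatibility.
#' @param regime `"neutral"` (parents drawn uniformly among individuals with
#'   at least one compatible partner) or `"frequency_dependent"` (rare
#'   individuals -- those with few compatible partners -- mate more often).
#' @param viability Shape of the offspring-viability (mate-choice) function:
#'   `"step"` (the default and the headline case), `"range"` (requires
#'   `q_max`), `"linear"` or `"exponential"`. See [viability()].
#' @param shape Decay parameter for the graded (`linear`/`exponential`)
#'   viability kinds; ignored otherwise.
#' @param fds_weight Functional form of the rare-type mating advantage:
#'   `"inverse_degree"` gives weight proportional to `1/(1 + degree)`,
#'   `"linear_deficit"` gives weight proportional to `(N - degree)/N`.
#' @param spatial Optional lattice specification from [spatial_grid()];
#'   restricts mating to the Moore-8 neighborhood.
#' @param generations Run length in generations (1 generation = `N` steps).
#' @param seed Integer seed for the random stream.
#'
#' @return An object of class `radsim_params` (a validated list).
#' @examples
#' p <- sim_params(N = 50, mu = 0.005, q_min = 0.95, generations = 100)
#' p
#' @export
sim_params <- function(N, mu, q_min,
                       q_max = NULL,
                       regime = c("neutral", "frequency_dependent"),
                       viability = c("step", "range", "linear", "exponential"),
                       shape = 10,
                       fds_weight = c("inverse_degree", "linear_deficit"),
                       spatial = NULL,
                       generations = 100,
                       seed = 1L) {
  regime <- match.arg(regime)
  viability <- match.arg(viability)
  fds_weight <- match.arg(fds_weight)

  stop_cfg <- function(msg) stop("invalid simulation parameters: ", msg,
                                 call. = FALSE)
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N != round(N))
    stop_cfg("N must be an integer >= 2")
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0)
    stop_cfg("mu must be a single number >= 0")
  if (!is.numeric(q_min) || length(q_min) != 1 || q_min < 0 || q_min > 1)
    stop_cfg("q_min must lie in [0, 1]")
  if (!is.null(q_max)) {
    if (!is.numeric(q_max) || length(q_max) != 1 ||
        q_max <= q_min || q_max > 1)
      stop_cfg("q_max must lie in (q_min, 1]")
  }
  if (viability == "range" && is.null(q_max))
    stop_cfg("viability kind 'range' requires q_max")
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0)
    stop_cfg("shape must be a single number > 0")
  if (!is.null(spatial)) {
    if (!inherits(spatial, "radsim_spatial"))
      stop_cfg("spatial must come from spatial_grid()")
    if (spatial$width * spatial$height != N)
      stop_cfg("spatial width * height must equal N")
  }
  if (!is.numeric(generations) || length(generations) != 1 || generations < 1)
    stop_cfg("generations must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop_cfg("seed must be an integer")

  structure(
    list(N = as.integer(N), mu = as.numeric(mu),
         q_min = as.numeric(q_min),
         q_max = if (is.null(q_max)) NULL else as.numeric(q_max),
         regime = regime, viability = viability,
         shape = as.numeric(shape), fds_weight = fds_weight,
         spatial = spatial,
         generations = as.integer(generations), seed = as.integer(seed)),
    class = "radsim_params"
  )
}

#' Lattice specification for spatially restricted mating
#'
#' Individuals sit on a `width` x `height` grid (row-major site order) and
#' may only mate within their Moore-8 neighborhood; the offspring always
#' takes the site freed by the death.
#'
#' @param width,height Grid dimensions; `width * height` must equal `N`.
#' @param torus Wrap edges around (torus topology)?
#' @return An object of class `radsim_spatial`.
#' @examples
#' spatial_grid(8, 8, torus = TRUE)
#' @export
spatial_grid <- function(width, height, torus = TRUE) {
  stopifnot(width >= 1, height >= 1, width * height >= 2)
  structure(list(width = as.integer(width), height = as.integer(height),
                 torus = isTRUE(torus)),
            class = "radsim_spatial")
}

#' @export
print.radsim_params <- function(x, ...) {
  cat("<radsim_params>\n")
  cat(sprintf("  N = %d, mu = %g, q_min = %g%s\n", x$N, x$mu, x$q_min,
              if (!is.null(x$q_max)) sprintf(", q_max = %g", x$q_max) else ""))
  cat(sprintf("  regime = %s, viability = %s", x$regime, x$viability))
  if (x$viability %in% c("linear", "exponential"))
    cat(sprintf(" (shape = %g)", x$shape))
  cat("\n")
  if (!is.null(x$spatial))
    cat(sprintf("  spatial: %d x %d Moore-8%s\n", x$spatial$width,
                x$spatial$height, if (x$spatial$torus) " (torus)" else ""))
  cat(sprintf("  generations = %d (%d elementary steps), seed = %d\n",
              x$generations, x$generations * x$N, x$seed))
  invisible(x)
}

# Moore-8 neighbor list (1-based site indices, row-major), or NULL if
# spatial mating is disabled.
neighbor_list <- function(spatial, N) {
  if (is.null(spatial)) return(NULL)
  w <- spatial$width; h <- spatial$height
  lapply(seq_len(N), function(i) {
    r <- (i - 1L) %/% w; c <- (i - 1L) %% w
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (spatial$torus) {
        rr <- rr %% h; cc <- cc %% w
      } else if (rr < 0 || rr >= h || cc < 0 || cc >= w) next
      out <- c(out, rr * w + cc + 1L)
    }
    sort(unique(out))
  })
}
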
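#' Offspring viability as a function of parental similarity
#'
#' The mate-choice function: the probability that a mating between two
#' individuals of genetic similarity `q` yields fertile offspring. The
#' `step` kind (the default throughout) is the simplest representation of
#' Dobzhansky--Muller incompatibility: fully viable at `q >= q_min`
#' (threshold inclusive), inviable below. The `range` kind additionally
#' blocks excessively similar pairs (`q > q_max`, self-incompatibility).
#' The graded kinds rise from 0 at `q_min` to 1 at `q = 1`: `linear` as
#' `(q - q_min)/(1 - q_min)`, `exponential` as
#' `(1 - exp(-shape (q - q_min))) / (1 - exp(-shape (1 - q_min)))`.
#'
#' @param q Similarity value(s) in `[0, 1]`; vectorized.
#' @param q_min Lower compatibility threshold.
#' @param kind One of `"step"`, `"range"`, `"linear"`, `"exponential"`.
#' @param q_max Upper threshold (required for `"range"`).
#' @param shape Decay parameter for the `exponential` kind.
#' @return Viability probabilities in `[0, 1]`, same length as `q`.
#' @examples
#' viability(c(0.94, 0.95, 1), q_min = 0.95)          # 0 1 1
#' viability(1, q_min = 0.9, kind = "range", q_max = 0.99)  # 0
#' @export
viability <- function(q, q_min, kind = c("step", "range", "linear",
                                         "exponential"),
                      q_max = NULL, shape = 10) {
  kind <- match.arg(kind)
  if (any(q < 0 | q > 1)) stop("similarity must lie in [0, 1]", call. = FALSE)
  switch(kind,
    step = as.numeric(q >= q_min),
    range = {
      if (is.null(q_max))
        stop("viability kind 'range' requires q_max", call. = FALSE)
      as.numeric(q >= q_min & q <= q_max)
    },
    linear = pmax(0, pmin(1, (q - q_min) / (1 - q_min))),
    exponential = {
      v <- 1 - exp(-shape * pmax(0, q - q_min))
      v / (1 - exp(-shape * (1 - q_min)))
    })
}

# Support of the viability function: can a pair (i, j) with similarity q
# ever produce fertile offspring? Step is threshold-inclusive; the graded
# kinds have positive viability only strictly above q_min.
viability_support <- function(q, q_min, kind = "step", q_max = NULL) {
  if (kind == "step") q >= q_min
  else if (kind == "range") q >= q_min & q <= q_max
  else q > q_min
}

#' Compatible partners of an individual
#'
#' The set of individuals with which `i` can produce fertile offspring:
#' positive viability support (for the step/range kinds, `q_ij` within the
#' thresholds) and, if spatial mating is enabled, membership of `i`'s
#' Moore-8 neighborhood. For the graded viability kinds an optional
#' acceptance draw per candidate (`rng = TRUE`) thins the set with
#' probability equal to each candidate's viability.
#'
#' @param q Similarity matrix.
#' @param i Focal individual index.
#' @param q_min,kind,q_max,shape As in [viability()].
#' @param neighbors Optional integer vector of lattice neighbors of `i`.
#' @param rng If `TRUE` and the kind is graded, apply acceptance draws.
#' @return Integer vector of partner indices (possibly empty).
#' @examples
#' q <- init_similarity(4); q[1, 3] <- q[3, 1] <- 0.5
#' compatible_partners(q, 1, q_min = 0.9) # 2 and 4
#' @export
compatible_partners <- function(q, i, q_min, kind = "step", q_max = NULL,
                                shape = 10, neighbors = NULL, rng = FALSE) {
  ok <- viability_support(q[i, ], q_min, kind, q_max)
  ok[i] <- FALSE
  cand <- which(ok)
  if (!is.null(neighbors)) cand <- intersect(cand, neighbors)
  if (rng && kind %in% c("linear", "exponential") && length(cand)) {
    v <- viability(q[i, cand], q_min, kind, q_max, shape)
    cand <- cand[stats::runif(length(cand)) < v]
  }
  cand
}

#' Parent-selection weights under the two regimes
#'
#' Normalized probabilities with which each individual is drawn as the
#' first parent. Only individuals with at least one compatible partner
#' (degree >= 1) can reproduce. Under the neutral regime eligible
#' individuals are equally likely; under negative frequency-dependent
#' selection individuals with few connections -- carriers of rare alleles --
#' get more weight: `1/(1 + degree)` (default) or `(N - degree)/N`.
#'
#' @param degrees Non-negative integer vector of compatible-partner counts.
#' @param regime `"neutral"` or `"frequency_dependent"`.
#' @param form Weight family for the frequency-dependent regime.
#' @return Numeric weight vector summing to 1 (zeros for degree-0
#'   individuals).
#' @examples
#' parent_weights(c(3, 3, 3), "frequency_dependent") # uniform
#' parent_weights(c(9, 1), "frequency_dependent")    # rare one favored
#' @export
parent_weights <- function(degrees,
                           regime = c("neutral", "frequency_dependent"),
                           form = c("inverse_degree", "linear_deficit")) {
  regime <- match.arg(regime)
  form <- match.arg(form)
  stopifnot(all(degrees >= 0))
  w <- if (regime == "neutral") rep(1, length(degrees))
       else if (form == "inverse_degree") 1 / (1 + degrees)
       else (length(degrees) - degrees) / length(degrees)
  w[degrees == 0] <- 0
  tot <- sum(w)
  if (tot == 0)
    stop("population sterile: no individual has a compatible partner",
         call. = FALSE)
  w / tot
}

#' Draw a parent pair
#'
#' The first parent is drawn by [parent_weights()] over all individuals
#' with a nonempty compatible set (the current step's dead individual, if
#' any, excluded); the mate is then drawn uniformly from the first parent's
#' compatible partners. Uses inverse-CDF draws on `runif()` so the R and
#' compiled engines consume the random stream identically.
#'
#' @param q Similarity matrix.
#' @param params A [sim_params()] object.
#' @param exclude Optional index excluded from both draws (the dead slot).
#' @param neighbors Optional neighbor list from a lattice.
#' @return Integer vector `c(p1, p2)`.
#' @export
choose_parents <- function(q, params, exclude = NULL, neighbors = NULL) {
  N <- nrow(q)
  alive <- setdiff(seq_len(N), exclude)
  partner_sets <- lapply(seq_len(N), function(i) {
    if (!(i %in% alive)) return(integer(0))
    setdiff(compatible_partners(q, i, params$q_min, params$viability,
                                params$q_max, params$shape,
                                neighbors = if (is.null(neighbors)) NULL
                                            else neighbors[[i]]),
            exclude)
  })
  degrees <- lengths(partner_sets)
  w <- parent_weights(degrees, params$regime, params$fds_weight)
  repeat {
    p1 <- draw_weighted(w)
    cand <- partner_sets[[p1]]
    if (params$viability %in% c("linear", "exponential") && length(cand)) {
      v <- viability(q[p1, cand], params$q_min, params$viability,
                     params$q_max, params$shape)
      cand <- cand[stats::runif(length(cand)) < v]
    }
    if (length(cand)) break
    # graded kinds can reject every candidate; redraw the first parent
  }
  p2 <- cand[floor(stats::runif(1) * length(cand)) + 1]
  c(p1, p2)
}

# Inverse-CDF categorical draw; mirrors the compiled engine exactly.
draw_weighted <- function(w) {
  u <- stats::runif(1) * sum(w)
  cum <- 0
  for (i in seq_along(w)) {
    cum <- cum + w[i]
    if (u < cum) return(i)
  }
  length(w)
}
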
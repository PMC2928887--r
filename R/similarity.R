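#' Initial similarity matrix
#'
#' At the start of a run all individuals carry identical genomes, so every
#' pairwise genetic similarity is 1 and the compatibility graph is complete.
#'
#' @param N Population size.
#' @return An `N` x `N` matrix of ones.
#' @examples
#' init_similarity(5)
#' @export
init_similarity <- function(N) {
  stopifnot(N >= 2)
  matrix(1, N, N)
}

#' Similarity row of a newborn
#'
#' Computes the newborn's genetic similarity to every current individual
#' under free recombination and mutation in the infinite-genome limit:
#' each nucleotide is inherited from either parent with probability 1/2 and
#' then mutates, giving the overlap recursion
#' \deqn{q_{o,j} = e^{-2\mu}\,(q_{p_1,j} + q_{p_2,j})/2.}
#' Similarity to a parent follows from the unit diagonal:
#' `exp(-2 mu) * (1 + q_p1p2) / 2`. The newborn's similarity to itself is 1.
#'
#' @param q Similarity matrix (symmetric, unit diagonal).
#' @param p1,p2 Parent indices (distinct).
#' @param mu Mutation rate per birth (`>= 0`).
#' @return Numeric vector of length `nrow(q)`: the newborn's similarity to
#'   each individual, with the entry at the newborn's own slot left at
#'   whichever index it will occupy (callers overwrite the dead slot; the
#'   returned vector has `1` nowhere -- assign `1` at the newborn's index).
#' @examples
#' q <- init_similarity(4)
#' offspring_similarity(q, 1, 2, mu = 0.01) # exp(-0.02) everywhere
#' @export
offspring_similarity <- function(q, p1, p2, mu) {
  if (p1 == p2) stop("selfing is disabled: parents must be distinct",
                     call. = FALSE)
  stopifnot(mu >= 0)
  lam <- exp(-2 * mu)
  lam * (q[p1, ] + q[p2, ]) / 2
}

#' Expected mean similarity at mutation--drift equilibrium
#'
#' Mean-field fixed point of the overlap recursion under the asynchronous
#' (Moran) update used by the simulator. One elementary step replaces one
#' uniformly chosen individual with an offspring of two uniformly chosen
#' survivors, so the expected mean off-diagonal similarity obeys
#' \deqn{\bar q \;=\; \lambda\,\frac{(N-2)\,\bar q + 1}{N-1},\qquad
#'       \lambda = e^{-2\mu},}
#' whose fixed point is
#' \deqn{\hat q = \frac{\lambda}{\,N-1-\lambda(N-2)\,}.}
#' For `mu = 0` this is 1; it is strictly decreasing in both `N` and `mu`,
#' and for small `mu` behaves as `1/(1 + 2 N mu)` (the synchronous-
#' generations analogue is `1/(1 + 4 N mu)`; the factor 2 reflects the
#' shorter pair-coalescence time of the Moran update).
#'
#' @param N Population size (`>= 2`).
#' @param mu Mutation rate per birth (`>= 0`).
#' @return Expected mean off-diagonal similarity, in `(0, 1]`.
#' @examples
#' equilibrium_similarity(50, 0)      # 1
#' equilibrium_similarity(50, 0.005)  # ~0.66
#' @export
equilibrium_similarity <- function(N, mu) {
  stopifnot(N >= 2, mu >= 0)
  lam <- exp(-2 * mu)
  lam / (N - 1 - lam * (N - 2))
}

#' Minimum mutation rate for mutation-induced speciation
#'
#' A newborn can found a new species in a single birth only if its
#' similarity to its parents can fall below `q_min`. From two identical,
#' mutually compatible parents (`q_p1p2 = 1`, the one-step extreme), the
#' newborn's similarity to each parent is `exp(-2 mu)`, so the smallest
#' mutation rate at which a single birth can disconnect the newborn is
#' \deqn{\mu_{min} = -\ln(q_{min}) / 2.}
#' Below this rate a newborn of identical parents is always compatible with
#' them, and mutation-induced speciation cannot start a radiation; fission
#' is then the only mode of speciation available from an initially
#' homogeneous population.
#'
#' @param q_min Compatibility threshold, strictly inside `(0, 1)`.
#' @return The minimum mutation rate.
#' @examples
#' min_mutation_rate(0.95)     # ~0.02565
#' min_mutation_rate(exp(-2))  # 1
#' @export
min_mutation_rate <- function(q_min) {
  if (!is.numeric(q_min) || any(q_min <= 0) || any(q_min >= 1))
    stop("q_min must lie strictly inside (0, 1)", call. = FALSE)
  -log(q_min) / 2
}

#' Can these parameters fragment the compatibility graph?
#'
#' Speciation requires the compatibility graph to lose edges at equilibrium,
#' i.e. the expected mean similarity must fall below the mating threshold:
#' `equilibrium_similarity(N, mu) < q_min`. Used to vet parameter grids
#' before fitting.
#'
#' @param N Population size.
#' @param mu Mutation rate per birth.
#' @param q_min Compatibility threshold.
#' @return `TRUE` if the expected equilibrium similarity is below `q_min`.
#' @examples
#' speciation_feasible(50, 0.005, 0.95) # TRUE
#' speciation_feasible(50, 0,     0.95) # FALSE
#' @export
speciation_feasible <- function(N, mu, q_min) {
  equilibrium_similarity(N, mu) < q_min
}
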
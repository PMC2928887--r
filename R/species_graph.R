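#' Compatibility (mating) graph
#'
#' Builds the undirected graph whose nodes are individuals and whose edges
#' connect pairs with positive viability support (step kind:
#' `q_ij >= q_min`; range kind additionally `q_ij <= q_max`), optionally
#' intersected with Moore-8 lattice adjacency. No self-edges.
#'
#' @param q Similarity matrix.
#' @param q_min Compatibility threshold.
#' @param kind Viability kind (see [viability()]).
#' @param q_max Optional upper threshold.
#' @param spatial Optional [spatial_grid()] object.
#' @return Logical adjacency matrix.
#' @examples
#' mating_graph(init_similarity(4), q_min = 0.9) # complete graph
#' @export
mating_graph <- function(q, q_min, kind = "step", q_max = NULL,
                         spatial = NULL) {
  adj <- viability_support(q, q_min, kind, q_max)
  diag(adj) <- FALSE
  if (!is.null(spatial)) {
    nb <- neighbor_list(spatial, nrow(q))
    sp <- matrix(FALSE, nrow(q), nrow(q))
    for (i in seq_len(nrow(q))) sp[i, nb[[i]]] <- TRUE
    adj <- adj & sp
  }
  adj & t(adj)  # enforce symmetry (thresholds are shared, Q symmetric)
}

# Union-find over 1..n. Returns component id per node (smallest member
# index as representative id).
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n - 1)) {
    js <- which(adj[i, (i + 1):n]) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Species partition of the population
#'
#' Species are maximal connected components of the compatibility graph: two
#' individuals are conspecific if any path of compatible pairs links them,
#' even when they are themselves reproductively incompatible. Components
#' are found by union--find.
#'
#' @param adj Logical adjacency matrix (from [mating_graph()]), or a
#'   similarity matrix if `q_min` is supplied.
#' @param q_min,kind,q_max,spatial Passed to [mating_graph()] when `adj`
#'   is a similarity matrix.
#' @return A tibble with columns `individual` and `species` (component id =
#'   smallest member index), one row per individual.
#' @examples
#' q <- init_similarity(3); q[1, 3] <- q[3, 1] <- 0   # path 1-2-3
#' species_partition(q, q_min = 0.5)                  # one species
#' @export
species_partition <- function(adj, q_min = NULL, kind = "step",
                              q_max = NULL, spatial = NULL) {
  if (!is.logical(adj)) {
    if (is.null(q_min))
      stop("supply q_min when passing a similarity matrix", call. = FALSE)
    adj <- mating_graph(adj, q_min, kind, q_max, spatial)
  }
  comp <- uf_components(adj)
  tibble::tibble(individual = seq_len(nrow(adj)), species = comp)
}

#' Abundance symmetry of a speciation event
#'
#' Degree of symmetry of a split: the ratio of the smallest new species'
#' abundance to the mother species' abundance,
#' `s = new_size / mother_size`. `s = 1` means the new species is exactly
#' as abundant as the mother (perfect symmetry); small `s` means the new
#' species split off as a sliver. Because the mother label stays with the
#' largest fragment, `s <= 1`.
#'
#' @param new_size Abundance of the smallest new species (`>= 1`).
#' @param mother_size Abundance of the mother species (`>= 1`).
#' @return Symmetry value in `(0, 1]`.
#' @examples
#' symmetry_index(4, 4) # 1
#' symmetry_index(1, 9) # 0.111...
#' @export
symmetry_index <- function(new_size, mother_size) {
  if (any(new_size < 1) || any(mother_size < 1))
    stop("species sizes must be >= 1", call. = FALSE)
  new_size / mother_size
}

#' Relabel a partition across one sub-step and detect events
#'
#' Maps each old species onto the new component(s) holding its surviving
#' members. The largest fragment keeps the mother label (ties broken by
#' smallest member index); every other fragment becomes a new species. At
#' the `after_death` sub-step new fragments are fission events; at
#' `after_birth`, a newborn disconnected from everyone founds a
#' mutation-induced species, and a newborn bridging several old species
#' triggers bookkeeping merges (largest component keeps its label; merges
#' are not speciations). Old labels with no surviving members go extinct.
#'
#' @param prev Integer vector: species label per individual before the
#'   sub-step (at `after_death` the dead slot keeps its old label so that
#'   extinctions of singletons are visible).
#' @param comp Integer vector: component id per individual after the
#'   sub-step (`NA` for the empty slot), e.g. from [species_partition()].
#' @param sub_step `"after_death"` or `"after_birth"`.
#' @param offspring Index of the newborn (required for `after_birth`).
#' @param next_label Smallest unused species label.
#' @param mother_label Species label of the newborn's parents (used when
#'   the newborn is disconnected from everyone).
#' @return A list with `labels` (updated label per individual) and `events`
#'   (tibble: `type`, `mode`, `label`, `other`, `new_size`, `mother_size`).
#' @export
relabel_and_detect <- function(prev, comp, sub_step = c("after_death",
                                                        "after_birth"),
                               offspring = NULL, next_label = NULL,
                               mother_label = NULL) {
  sub_step <- match.arg(sub_step)
  if (length(prev) != length(comp))
    stop("partitions cover different individual sets", call. = FALSE)
  if (is.null(next_label)) next_label <- max(prev, na.rm = TRUE) + 1L
  labels <- rep(NA_integer_, length(prev))
  ev <- list()
  add_ev <- function(type, mode, label, other, new_size, mother_size) {
    ev[[length(ev) + 1]] <<- tibble::tibble(
      type = type, mode = mode, label = as.integer(label),
      other = as.integer(other), new_size = as.integer(new_size),
      mother_size = as.integer(mother_size))
  }

  if (sub_step == "after_death") {
    for (L in sort(unique(prev[!is.na(prev)]))) {
      members <- which(!is.na(prev) & prev == L & !is.na(comp))
      if (!length(members)) {
        add_ev("extinction", NA_character_, L, NA, NA, NA)
        next
      }
      frags <- split(members, comp[members])
      sizes <- lengths(frags)
      mins <- vapply(frags, min, integer(1))
      mother <- order(-sizes, mins)[1]
      labels[frags[[mother]]] <- L
      for (k in seq_along(frags)[-mother]) {
        labels[frags[[k]]] <- next_label
        add_ev("speciation", "fission", next_label, L,
               sizes[k], sizes[mother])
        next_label <- next_label + 1L
      }
    }
  } else {
    if (is.null(offspring)) stop("after_birth requires the offspring index",
                                 call. = FALSE)
    labels <- prev
    mates <- which(comp == comp[offspring])
    mates <- setdiff(mates, offspring)
    joined <- unique(prev[mates])
    if (!length(joined)) {
      labels[offspring] <- next_label
      msize <- if (!is.null(mother_label))
        sum(prev == mother_label, na.rm = TRUE) else NA_integer_
      add_ev("speciation", "mutation_induced", next_label,
             mother_label %||% NA, 1L, msize)
      next_label <- next_label + 1L
    } else if (length(joined) == 1) {
      labels[offspring] <- joined
    } else {
      sizes <- vapply(joined, function(L) sum(prev == L, na.rm = TRUE),
                      integer(1))
      keep <- joined[order(-sizes, joined)][1]
      for (L in sort(setdiff(joined, keep))) {
        add_ev("merge", NA_character_, L, keep,
               sum(prev == L, na.rm = TRUE), sum(prev == keep, na.rm = TRUE))
        labels[labels == L & !is.na(labels)] <- keep
      }
      labels[offspring] <- keep
    }
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(type = character(), mode = character(),
                   label = integer(), other = integer(),
                   new_size = integer(), mother_size = integer())
  list(labels = labels, events = events, next_label = next_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
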
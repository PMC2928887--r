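# Pure-R reference engine. Slow (quadratic per step) but built directly on
# the exported building blocks, with the same random-draw sequence as the
# compiled engine: trajectories from the same seed are identical. Used for
# cross-validation and small illustrative runs.

run_engine_r <- function(params, n_steps, snapshot_steps) {
  N <- params$N
  lam <- exp(-2 * params$mu)
  nb <- neighbor_list(params$spatial, N)

  q <- init_similarity(N)
  # initial species = components of the initial graph (one species unless
  # q_max or a disconnected lattice fragments the identical founders)
  init_adj <- mating_graph(q, params$q_min, params$viability, params$q_max,
                           params$spatial)
  comp0 <- uf_components(init_adj)
  labels <- match(comp0, unique(comp0))
  next_label <- max(labels) + 1L
  nroots <- max(labels)
  lineage <- list(parent = rep(0L, nroots), origin_step = rep(0L, nroots),
                  end_step = rep(NA_integer_, nroots),
                  end_type = rep(0L, nroots),
                  merged_into = rep(0L, nroots))
  events <- list()
  snap <- list(gen = integer(0), label = list(), size = list(),
               qbar = numeric(0))
  halted <- 0L

  adjacency <- function(mat, alive_mask) {
    adj <- mating_graph(mat, params$q_min, params$viability, params$q_max,
                        params$spatial)
    adj[!alive_mask, ] <- FALSE
    adj[, !alive_mask] <- FALSE
    adj
  }

  add_event <- function(step, type, mode, label, other, new_size,
                        mother_size, died, p1, p2) {
    events[[length(events) + 1]] <<- data.frame(
      step = step, type = type, mode = mode, label = label, other = other,
      new_size = new_size, mother_size = mother_size, died = died,
      p1 = p1, p2 = p2)
  }

  for (step in seq_len(n_steps)) {
    ## death sub-step
    u <- stats::runif(1)
    die <- min(floor(u * N) + 1L, N)
    L <- labels[die]
    prev <- labels  # dead slot keeps its label so extinctions are visible
    alive <- rep(TRUE, N); alive[die] <- FALSE
    adj <- adjacency(q, alive)

    comp <- uf_components(adj)
    comp[die] <- NA_integer_
    rl <- relabel_and_detect(prev, comp, "after_death",
                             next_label = next_label)
    labels <- rl$labels
    labels[die] <- NA_integer_
    next_label <- rl$next_label
    if (nrow(rl$events)) {
      for (k in seq_len(nrow(rl$events))) {
        e <- rl$events[k, ]
        if (e$type == "extinction") {
          lineage$end_step[e$label] <- step
          lineage$end_type[e$label] <- 1L
        } else {
          lineage$parent[e$label] <- e$other
          lineage$origin_step[e$label] <- step
          lineage$end_step[e$label] <- NA_integer_
          lineage$end_type[e$label] <- 0L
          lineage$merged_into[e$label] <- 0L
        }
        add_event(step, e$type, e$mode, e$label, e$other, e$new_size,
                  e$mother_size, die, NA_integer_, NA_integer_)
      }
    }

    ## parent selection (sterile check mirrors the compiled engine)
    deg <- rowSums(adj)
    if (all(deg[alive] == 0)) { halted <- step; break }
    pr <- choose_parents(q, params, exclude = die, neighbors = nb)
    p1 <- pr[1]; p2 <- pr[2]

    ## birth sub-step
    newrow <- offspring_similarity(q, p1, p2, params$mu)
    newrow[die] <- 1
    q[die, ] <- newrow
    q[, die] <- newrow

    adj <- adjacency(q, rep(TRUE, N))
    comp <- uf_components(adj)
    rl <- relabel_and_detect(labels, comp, "after_birth", offspring = die,
                             next_label = next_label,
                             mother_label = labels[p1])
    labels <- rl$labels
    next_label <- rl$next_label
    if (nrow(rl$events)) {
      for (k in seq_len(nrow(rl$events))) {
        e <- rl$events[k, ]
        if (e$type == "speciation") {
          lineage$parent[e$label] <- e$other
          lineage$origin_step[e$label] <- step
          lineage$end_step[e$label] <- NA_integer_
          lineage$end_type[e$label] <- 0L
          lineage$merged_into[e$label] <- 0L
        } else if (e$type == "merge") {
          lineage$end_step[e$label] <- step
          lineage$end_type[e$label] <- 2L
          lineage$merged_into[e$label] <- e$other
        }
        add_event(step, e$type, e$mode, e$label, e$other, e$new_size,
                  e$mother_size, die, p1, p2)
      }
    }

    if (snapshot_steps > 0 && step %% snapshot_steps == 0) {
      tab <- table(labels)
      snap$gen <- c(snap$gen, step %/% snapshot_steps)
      snap$label <- c(snap$label, list(as.integer(names(tab))))
      snap$size <- c(snap$size, list(as.integer(tab)))
      snap$qbar <- c(snap$qbar, (sum(q) - N) / (N * (N - 1)))
    }
  }

  nlab <- next_label - 1L
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), type = character(0), mode = character(0),
               label = integer(0), other = integer(0),
               new_size = integer(0), mother_size = integer(0),
               died = integer(0), p1 = integer(0), p2 = integer(0))
  list(events = ev,
       labels = labels, q = q,
       lineage = data.frame(label = seq_len(nlab),
                            parent = lineage$parent[seq_len(nlab)],
                            origin_step = lineage$origin_step[seq_len(nlab)],
                            end_step = lineage$end_step[seq_len(nlab)],
                            end_type = lineage$end_type[seq_len(nlab)],
                            merged_into = lineage$merged_into[seq_len(nlab)]),
       snapshots = snap,
       halted = halted,
       steps_done = if (halted > 0) halted else n_steps)
}
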
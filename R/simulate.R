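#' Run the speciation simulator
#'
#' Executes `generations * N` elementary steps of the zero-sum
#' death--birth cycle. In each step one uniformly chosen individual dies
#' (fissions and extinctions are detected immediately after the death);
#' parents are then selected -- the first by the regime's mating-success
#' weights, the mate uniformly among the first parent's compatible
#' partners -- and the dead slot is filled by their offspring, whose
#' similarity row follows the overlap recursion (see
#' [offspring_similarity()]); mutation-induced speciations (a newborn
#' incompatible with everyone) are detected after the birth. Species labels
#' are genealogical: the largest fragment keeps the mother's label.
#'
#' @param params A [sim_params()] object.
#' @param snapshot_every Snapshot cadence in generations (species sizes are
#'   recorded at each snapshot).
#' @param engine `"cpp"` (compiled, the default) or `"r"` (pure-R reference
#'   implementation; identical trajectories for the same seed).
#' @return A `radsim_sim` object with elements
#'   \describe{
#'     \item{events}{tibble of events: `step`, `generation`, `type`
#'       (speciation/extinction/merge), `mode` (fission/mutation_induced),
#'       `label`, `other` (mother or absorbing label), `new_size`,
#'       `mother_size`, `died`, `p1`, `p2`.}
#'     \item{sizes}{tibble of per-snapshot species abundances
#'       (`generation`, `label`, `size`).}
#'     \item{snapshots}{tibble of per-snapshot population summaries
#'       (`generation`, `extant`, `qbar` = mean off-diagonal similarity).}
#'     \item{lineage}{tibble of species lineages (`label`, `parent`,
#'       `origin_gen`, `end_gen`, `status`).}
#'     \item{final_q, final_labels}{state at the end of the run.}
#'     \item{sterile}{`TRUE` if the run halted because no individual had a
#'       compatible partner.}
#'   }
#' @examples
#' p <- sim_params(N = 30, mu = 0.01, q_min = 0.95, generations = 50,
#'                 seed = 1)
#' sim <- simulate_radiation(p)
#' sim
#' @export
simulate_radiation <- function(params, snapshot_every = 1,
                               engine = c("cpp", "r")) {
  stopifnot(inherits(params, "radsim_params"))
  engine <- match.arg(engine)
  N <- params$N
  n_steps <- params$generations * N
  snapshot_steps <- as.integer(snapshot_every * N)

  set.seed(params$seed)
  if (engine == "cpp") {
    nb <- neighbor_list(params$spatial, N)
    raw <- .engine_run(
      N, params$mu, params$q_min,
      q_max = params$q_max %||% 2, has_qmax = !is.null(params$q_max),
      regime = match(params$regime, c("neutral", "frequency_dependent")) - 1L,
      vkind = match(params$viability,
                    c("step", "range", "linear", "exponential")) - 1L,
      shape = params$shape,
      fds_form = match(params$fds_weight,
                       c("inverse_degree", "linear_deficit")) - 1L,
      n_steps = n_steps, snapshot_steps = snapshot_steps,
      neighbors = nb %||% list())
    events <- tibble::as_tibble(raw$events)
    events$type <- c("speciation", "extinction", "merge")[events$type]
    events$mode <- c(NA, "fission", "mutation_induced")[events$mode + 1]
    sizes <- tibble::tibble(
      generation = rep(raw$snap_gen * snapshot_every,
                       diff(raw$snap_off)),
      label = raw$snap_label, size = raw$snap_size)
    snapshots <- tibble::tibble(
      generation = raw$snap_gen * snapshot_every,
      extant = diff(raw$snap_off), qbar = raw$snap_qbar)
    lineage_raw <- tibble::as_tibble(raw$lineage)
    labels <- raw$labels
    q <- raw$q
    halted <- raw$halted
    steps_done <- raw$steps_done
  } else {
    raw <- run_engine_r(params, n_steps, snapshot_steps)
    events <- tibble::as_tibble(raw$events)
    sizes <- tibble::tibble(
      generation = rep(raw$snapshots$gen * snapshot_every,
                       lengths(raw$snapshots$label)),
      label = unlist(raw$snapshots$label) %||% integer(0),
      size = unlist(raw$snapshots$size) %||% integer(0))
    snapshots <- tibble::tibble(
      generation = raw$snapshots$gen * snapshot_every,
      extant = lengths(raw$snapshots$label),
      qbar = raw$snapshots$qbar)
    lineage_raw <- tibble::as_tibble(raw$lineage)
    labels <- raw$labels
    q <- raw$q
    halted <- raw$halted
    steps_done <- raw$steps_done
  }
  events$generation <- events$step / N
  labels <- as.integer(labels)
  labels[!is.na(labels) & labels < 0] <- NA_integer_  # sterile dead slot

  lineage <- tibble::tibble(
    label = lineage_raw$label,
    parent = ifelse(lineage_raw$parent == 0, NA_integer_,
                    lineage_raw$parent),
    origin_gen = lineage_raw$origin_step / N,
    end_gen = lineage_raw$end_step / N,
    status = c("extant", "extinct", "merged")[lineage_raw$end_type + 1],
    merged_into = ifelse(lineage_raw$merged_into == 0, NA_integer_,
                         lineage_raw$merged_into))

  out <- structure(
    list(params = params, events = events, sizes = sizes,
         snapshots = snapshots,
         lineage = lineage, final_q = q,
         final_labels = as.integer(labels),
         sterile = halted > 0,
         steps_done = steps_done,
         generations_done = steps_done / N,
         snapshot_every = snapshot_every,
         engine = engine),
    class = "radsim_sim")
  if (out$sterile)
    warning("population became sterile at step ", halted,
            "; returning partial results", call. = FALSE)
  out
}

#' @export
print.radsim_sim <- function(x, ...) {
  sp <- x$events[x$events$type == "speciation", ]
  cat("<radsim_sim> ", x$params$regime, " regime, N = ", x$params$N,
      ", mu = ", x$params$mu, ", q_min = ", x$params$q_min, "\n", sep = "")
  cat(sprintf("  %g generations run (%d elementary steps)%s\n",
              x$generations_done, x$steps_done,
              if (x$sterile) " [halted: sterile]" else ""))
  cat(sprintf("  %d speciation events (%d fission, %d mutation-induced), %d extinctions\n",
              nrow(sp), sum(sp$mode == "fission"),
              sum(sp$mode == "mutation_induced"),
              sum(x$events$type == "extinction")))
  cat(sprintf("  %d extant species at the end\n",
              length(unique(x$final_labels[x$final_labels > 0]))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.radsim_sim <- function(x, ...) x$events

#' @export
glance.radsim_sim <- function(x, ...) summarize_radiation(x)
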
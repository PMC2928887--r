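#' Read a run configuration
#'
#' Loads a YAML or JSON configuration mirroring [sim_params()] field for
#' field, plus optional run-control keys (`outputs`, `snapshot_every`,
#' `replicates`). Unknown keys are rejected with the offending names;
#' invalid values fail with the violated constraint.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `radsim_config` list with elements `params`
#'   ([sim_params()]), `outputs`, `snapshot_every`, `replicates`.
#' @export
read_radsim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_radsim_config(fix_yaml_N(raw))
}

# YAML 1.1 reads a bare `N` key as the boolean FALSE; restore it.
fix_yaml_N <- function(raw) {
  names(raw)[names(raw) == "FALSE"] <- "N"
  raw
}

as_radsim_config <- function(raw) {
  param_keys <- c("N", "mu", "q_min", "q_max", "regime", "viability",
                  "shape", "fds_weight", "spatial", "generations", "seed")
  run_keys <- c("outputs", "snapshot_every", "replicates")
  unknown <- setdiff(names(raw), c(param_keys, run_keys))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spatial <- NULL
  if (!is.null(raw$spatial)) {
    sk <- setdiff(names(raw$spatial), c("width", "height", "torus"))
    if (length(sk))
      stop("unknown spatial keys: ", paste(sk, collapse = ", "),
           call. = FALSE)
    spatial <- spatial_grid(raw$spatial$width, raw$spatial$height,
                            raw$spatial$torus %||% TRUE)
  }
  params <- sim_params(
    N = raw$N, mu = raw$mu, q_min = raw$q_min, q_max = raw$q_max,
    regime = raw$regime %||% "neutral",
    viability = raw$viability %||% "step",
    shape = raw$shape %||% 10,
    fds_weight = raw$fds_weight %||% "inverse_degree",
    spatial = spatial,
    generations = raw$generations %||% 100,
    seed = raw$seed %||% 1L)
  structure(list(params = params,
                 outputs = raw$outputs %||% ".",
                 snapshot_every = raw$snapshot_every %||% 1,
                 replicates = raw$replicates %||% 1L),
            class = "radsim_config")
}

#' Write a run configuration
#'
#' Inverse of [read_radsim_config()]; the write--read round trip is the
#' identity on the configuration contents.
#'
#' @param config A `radsim_config` (or a [sim_params()] object, wrapped
#'   with defaults).
#' @param path Destination `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_radsim_config <- function(config, path) {
  if (inherits(config, "radsim_params"))
    config <- structure(list(params = config, outputs = ".",
                             snapshot_every = 1, replicates = 1L),
                        class = "radsim_config")
  p <- config$params
  lst <- list(N = p$N, mu = p$mu, q_min = p$q_min, regime = p$regime,
              viability = p$viability, shape = p$shape,
              fds_weight = p$fds_weight, generations = p$generations,
              seed = p$seed, outputs = config$outputs,
              snapshot_every = config$snapshot_every,
              replicates = config$replicates)
  if (!is.null(p$q_max)) lst$q_max <- p$q_max
  if (!is.null(p$spatial))
    lst$spatial <- list(width = p$spatial$width, height = p$spatial$height,
                        torus = p$spatial$torus)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' Write simulation outputs as TSV tables
#'
#' Writes `events.tsv` (one row per event), `species_through_time.tsv`,
#' `species.tsv` (lineage table: label, parent, origin/extinction times)
#' and `similarity_final.tsv` (dense matrix) into a directory. Tables are
#' tab-separated with a header row; times are in generations.
#'
#' @param sim A `radsim_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_radsim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "radsim_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$events, file.path(dir, "events.tsv"))
  readr::write_tsv(species_through_time(sim),
                   file.path(dir, "species_through_time.tsv"))
  readr::write_tsv(sim$lineage, file.path(dir, "species.tsv"))
  qdf <- as.data.frame(sim$final_q)
  names(qdf) <- paste0("ind", seq_len(ncol(qdf)))
  readr::write_tsv(qdf, file.path(dir, "similarity_final.tsv"))
  invisible(dir)
}

#' Read/write an observed event series as TSV
#'
#' Two tab-separated columns, `time` and `cumulative_species`.
#'
#' @param path File path.
#' @param present End-of-observation time; defaults to the last event
#'   time when reading (a `# present: <t>` comment line, if present, takes
#'   precedence).
#' @return [read_series_tsv()]: a `radsim_series`.
#' @export
read_series_tsv <- function(path, present = NULL) {
  header <- readLines(path, n = 1)
  if (is.null(present)) {
    cm <- grep("^#\\s*present:", readLines(path), value = TRUE)
    if (length(cm)) present <- as.numeric(sub("^#\\s*present:\\s*", "",
                                              cm[1]))
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  event_series(df$time, cumulative = df$cumulative_species,
               present = present %||% max(df$time))
}

#' @param series A `radsim_series` to write.
#' @rdname read_series_tsv
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "radsim_series"))
  writeLines(sprintf("# present: %.10g", attr(series, "present")), path)
  readr::write_tsv(
    tibble::tibble(time = series$time,
                   cumulative_species = series$cumulative),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Export the species lineage forest as Newick
#'
#' Serializes the genealogical species labels as a Newick tree with branch
#' lengths in generations: each speciation event is a bifurcation of the
#' mother lineage, extinct (and merged) tips terminate at their end time,
#' extant tips run to the present. Species labels become tip/node names
#' (`s<label>`).
#'
#' @param sim A `radsim_sim`, or a lineage tibble with columns `label`,
#'   `parent`, `origin_gen`, `end_gen`, `status`.
#' @param present Present time in generations.
#' @return A Newick string (terminated by `;`).
#' @examples
#' p <- sim_params(N = 30, mu = 0.02, q_min = 0.97, generations = 60)
#' nwk <- export_lineage_newick(simulate_radiation(p))
#' @export
export_lineage_newick <- function(sim, present = NULL) {
  if (inherits(sim, "radsim_sim")) {
    lineage <- sim$lineage
    present <- present %||% sim$generations_done
  } else {
    lineage <- sim
    if (is.null(present)) stop("supply `present` with a lineage table",
                               call. = FALSE)
  }
  kids <- split(lineage$label[!is.na(lineage$parent)],
                lineage$parent[!is.na(lineage$parent)])
  origin <- stats::setNames(lineage$origin_gen, lineage$label)
  endt <- stats::setNames(
    ifelse(is.na(lineage$end_gen), present, lineage$end_gen),
    lineage$label)

  seen <- integer(0)
  children_of <- function(L) {
    ch <- kids[[as.character(L)]]
    if (is.null(ch)) integer(0) else ch[order(origin[as.character(ch)])]
  }
  # Subtree whose stem starts at time t_start on lineage L, with the given
  # children (sorted by origin time) still ahead; returns "str:len".
  descend <- function(L, t_start, ch) {
    if (!length(ch))
      return(sprintf("s%d:%.10g", L, endt[[as.character(L)]] - t_start))
    c1 <- ch[1]
    if (c1 %in% seen) stop("cyclic lineage", call. = FALSE)
    seen <<- c(seen, c1)
    t1 <- origin[[as.character(c1)]]
    sprintf("(%s,%s):%.10g",
            descend(c1, t1, children_of(c1)),
            descend(L, t1, ch[-1]),
            t1 - t_start)
  }
  roots <- lineage$label[is.na(lineage$parent)]
  if (length(roots) != 1) stop("lineage must have exactly one root",
                               call. = FALSE)
  L <- roots[1]
  paste0(descend(L, origin[[as.character(L)]], children_of(L)), ";")
}
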
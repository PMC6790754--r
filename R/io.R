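config_keys <- c("V", "m", "d", "delta_mut", "k_max", "n_tot", "init_cells",
                 "density_collisions",
                 "t_max", "record_every", "snapshot_every", "seed",
                 "out_dir", "log_events_from", "log_events_to",
                 "log_cell_events", "ancestor_at", "analysis_window")

#' Load a run configuration from a YAML file
#'
#' Applies the model defaults (`d = 0.02`, `delta_mut = 0.05`,
#' `k_max = 1`, `n_tot = 50 V`, `init_cells = 50`) to any field not
#' present, validates the result through [sim_params()], and rejects
#' unknown keys with a field-level message.
#'
#' @param path YAML file with at least `V` and `m`.
#' @return A `run_config`: list with `params` (a `sim_params`) and the
#'   remaining run-control fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(raw$V) || is.null(raw$m))
    stop("config must provide V and m")
  par_names <- intersect(names(raw), names(formals(sim_params)))
  params <- do.call(sim_params, raw[par_names])
  extra <- raw[setdiff(names(raw), par_names)]
  structure(list(params = params, control = extra), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` yields
#' an identical configuration.
#'
#' @param config A `run_config` (or a bare `sim_params`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "sim_params"))
    config <- structure(list(params = config, control = list()),
                        class = "run_config")
  flat <- c(unclass(config$params), config$control)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write a trajectory as tab-separated values
#'
#' One header line, fixed column order as produced by the engine.
#'
#' @param trajectory Trajectory data frame from [run_simulation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  write.table(trajectory, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Write a replicator genealogy event log as TSV
#'
#' Merges birth and death events into the on-disk format: columns `step`,
#' `event` (birth/death), `rep_id`, `rtype`, `template_id`,
#' `catalyst_id`, `cell_id`, with empty template/catalyst fields on death
#' rows, sorted by step.
#'
#' @param births,deaths Event data frames from [run_simulation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genealogy_tsv <- function(births, deaths, path) {
  b <- data.frame(step = births$step,
                  event = rep("birth", nrow(births)),
                  rep_id = births$rep_id, rtype = births$rtype,
                  template_id = births$template_id,
                  catalyst_id = births$catalyst_id,
                  cell_id = births$cell_id)
  d <- data.frame(step = deaths$step,
                  event = rep("death", nrow(deaths)),
                  rep_id = deaths$rep_id, rtype = deaths$rtype,
                  template_id = rep(NA_integer_, nrow(deaths)),
                  catalyst_id = rep(NA_integer_, nrow(deaths)),
                  cell_id = deaths$cell_id)
  ev <- rbind(b, d)
  ev <- ev[order(ev$step), ]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a genealogy event log written by [write_genealogy_tsv()]
#'
#' @param path TSV file.
#' @return List with `births` and `deaths` data frames.
#' @export
read_genealogy_tsv <- function(path) {
  ev <- read.delim(path)
  list(births = ev[ev$event == "birth",
                   c("step", "rep_id", "rtype", "template_id",
                     "catalyst_id", "cell_id")],
       deaths = ev[ev$event == "death", c("step", "rep_id", "rtype",
                                          "cell_id")])
}

#' Run a (V, m) parameter sweep and classify end states
#'
#' Runs the simulator over the grid of division thresholds and mutation
#' rates, `replicates` seeds per combination, and classifies each end
#' state with [classify_run()] -- a scaled-down phase-diagram scan.
#'
#' @param V_grid,m_grid Parameter grids.
#' @param replicates Seeds per combination (seeds `1..replicates` offset
#'   by `seed_base`).
#' @param t_max Steps per run.
#' @param seed_base Added to the replicate index to form each seed.
#' @param ... Further arguments to [sim_params()].
#' @return Data frame with one row per (V, m, seed): the label and the
#'   classifier's summary statistics.
#' @export
sweep_phase_diagram <- function(V_grid, m_grid, replicates = 1,
                                t_max = 10000, seed_base = 0, ...) {
  rows <- list()
  for (V in V_grid) for (m in m_grid) for (r in seq_len(replicates)) {
    p <- sim_params(V = V, m = m, t_max = t_max, seed = seed_base + r, ...)
    run <- run_simulation(p)
    cls <- classify_run(run)
    rows[[length(rows) + 1]] <- data.frame(
      V = V, m = m, seed = seed_base + r, label = cls$label,
      A_P = cls$A[["P"]], A_Q = cls$A[["Q"]],
      minority_median = cls$minority_median, extinct = run$extinct)
  }
  do.call(rbind, rows)
}
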
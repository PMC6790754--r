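#' Redistribute substrate among protocells
#'
#' All substrate is pooled and re-placed multinomially across cells with
#' probabilities proportional to their replicator counts, emulating
#' substrate diffusion that is fast relative to every other process. Cells
#' without replicators receive nothing (and so lose their substrate to the
#' rest of the population). If no cell holds replicators the substrate
#' stays where it is.
#'
#' @param world A `protocell_world`.
#' @return The updated world; total substrate is conserved exactly.
#' @export
diffuse_substrate <- function(world) {
  ni <- vapply(world$cells, function(c) length(c$rep_id), numeric(1))
  tot_s <- sum(vapply(world$cells, function(c) c$substrate, numeric(1)))
  if (tot_s == 0 || sum(ni) == 0) return(world)
  alloc <- as.vector(rmultinom(1, tot_s, ni))
  for (i in seq_along(world$cells))
    world$cells[[i]]$substrate <- alloc[i]
  world
}

#' Divide oversized protocells and remove empty ones
#'
#' Every cell whose particle count (replicators plus substrate) strictly
#' exceeds the threshold `V` splits into two daughters, each particle
#' independently assigned to either daughter with probability 1/2.
#' Substrate units are particles and are partitioned individually. Cells
#' left with zero particles are removed. Division and removal events are
#' accumulated in `world$cell_events`.
#'
#' @param world A `protocell_world`.
#' @return The updated world.
#' @export
divide_and_cull <- function(world) {
  V <- world$params$V
  out <- list()
  ev <- list()
  push_ev <- function(event, id, parent) {
    ev[[length(ev) + 1]] <<- data.frame(step = world$step, event = event,
                                        cell_id = id, parent_id = parent)
  }
  for (cell in world$cells) {
    particles <- length(cell$rep_id) + cell$substrate
    if (particles == 0) { push_ev("removal", cell$id, NA); next }
    if (particles <= V) { out[[length(out) + 1]] <- cell; next }
    to_a <- runif(length(cell$rep_id)) < 0.5
    sub_a <- rbinom(1, cell$substrate, 0.5)
    make_daughter <- function(keep, sub) {
      d <- cell
      d$id <- world$next_cell_id
      world$next_cell_id <<- world$next_cell_id + 1L
      d$parent <- cell$id
      d$substrate <- as.integer(sub)
      d$rep_id <- cell$rep_id[keep]
      d$rtype <- cell$rtype[keep]
      d$state <- cell$state[keep]
      d$birth_step <- cell$birth_step[keep]
      d$template_parent <- cell$template_parent[keep]
      d$k <- cell$k[keep, , drop = FALSE]
      d
    }
    a <- make_daughter(to_a, sub_a)
    b <- make_daughter(!to_a, cell$substrate - sub_a)
    push_ev("birth", a$id, cell$id)
    push_ev("birth", b$id, cell$id)
    push_ev("removal", cell$id, NA)
    for (dtr in list(a, b)) {
      if (length(dtr$rep_id) + dtr$substrate > 0) {
        out[[length(out) + 1]] <- dtr
      } else {
        push_ev("removal", dtr$id, NA)
      }
    }
  }
  world$cells <- out
  if (length(ev) > 0) {
    new_ev <- do.call(rbind, ev)
    world$cell_events <- if (is.null(world$cell_events)) new_ev
                         else rbind(world$cell_events, new_ev)
  }
  world
}

#' Advance a world by one time step (reference implementation)
#'
#' Applies, in order: per cell complex formation, product synthesis with
#' mutation, and decay; then global substrate diffusion; then cell division
#' and removal. This pure-R scheduler mirrors the compiled engine used by
#' [run_simulation()] and exists for small worlds, testing, and as readable
#' reference semantics. Total particle number is conserved exactly.
#'
#' @param world A `protocell_world`.
#' @param log_events Collect birth/death events into `world$events`.
#' @return The updated world with `step` incremented.
#' @export
step_world <- function(world, log_events = FALSE) {
  world$step <- world$step + 1L
  births <- list(); deaths <- list()
  for (i in seq_along(world$cells)) {
    fc <- form_complexes(world$cells[[i]], world$params)
    sp <- synthesize_products(fc$cell, fc$complexes, world$params,
                              step = world$step,
                              next_rep_id = world$next_rep_id)
    world$next_rep_id <- sp$next_rep_id
    dc <- decay_step(sp$cell, world$params$d, step = world$step)
    world$cells[[i]] <- dc$cell
    if (log_events) {
      births[[length(births) + 1]] <- sp$births
      deaths[[length(deaths) + 1]] <- dc$deaths
    }
  }
  world <- diffuse_substrate(world)
  world <- divide_and_cull(world)
  if (log_events) {
    world$events <- list(
      births = rbind(world$events$births, do.call(rbind, births)),
      deaths = rbind(world$events$deaths, do.call(rbind, deaths)))
  }
  if (!conservation_holds(world))
    warning("particle conservation violated at step ", world$step)
  world
}

#' Run the compiled simulation engine
#'
#' The production path for simulations of any size: a C++ implementation
#' of the same reaction/diffusion/division scheduler as [step_world()],
#' drawing from R's RNG stream so that a fixed seed gives bit-identical
#' output. Optional logging channels (replicator events, cell events,
#' completed lifetimes, mutation increments, window-ancestor tracking) feed
#' the genealogy and observables modules without storing full histories.
#'
#' @param params A [sim_params()] object; `t_max`, `record_every`,
#'   `snapshot_every` and `seed` are taken from it.
#' @param log_events_window Integer vector `c(from, to)`: log individual
#'   birth and death events for steps in this window, or `NULL` for none.
#' @param log_cell_events Log cell creations, divisions and removals
#'   (needed to build a cell genealogy).
#' @param ancestor_at Time step at which to anchor window-ancestor
#'   tracking, or `NULL`. Every replicator alive at the end of that step
#'   becomes its own ancestor marker; descendants inherit the marker, so
#'   the run's final population can be mapped onto its ancestors at that
#'   step without storing the full genealogy. Cells are marked the same
#'   way.
#' @param max_lifetimes Collect up to this many completed replicator
#'   lifetimes (in steps, geometric with success probability `d`).
#' @param max_mutations Collect up to this many realized mutation events as
#'   (pre-mutation value, drawn increment) pairs.
#' @param init_state Optional engine state (see [world_to_state()]) to
#'   start from instead of the standard initial condition.
#' @return A `replicell_run` object: list with `trajectory` (data frame),
#'   `snapshots` (list of `replicell_snapshot`), `births`, `deaths`,
#'   `cell_events` data frames, `lifetimes`, `mutations`, `ancestors`,
#'   `final_state`, `extinct`, `conservation_violations`, `steps_run` and
#'   the `params` used.
#' @examples
#' \donttest{
#' run <- run_simulation(sim_params(V = 20, m = 0.01, t_max = 200, seed = 1))
#' tail(run$trajectory$cell_count, 1)
#' }
#' @export
run_simulation <- function(params, log_events_window = NULL,
                           log_cell_events = FALSE, ancestor_at = NULL,
                           max_lifetimes = 0, max_mutations = 0,
                           init_state = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  opts <- list(t_max = params$t_max, record_every = params$record_every,
               snapshot_every = params$snapshot_every,
               log_events_from = if (is.null(log_events_window)) -1L
                                 else as.integer(log_events_window[1]),
               log_events_to = if (is.null(log_events_window)) -1L
                               else as.integer(log_events_window[2]),
               log_cell_events = isTRUE(log_cell_events),
               ancestor_at = if (is.null(ancestor_at)) -1L
                             else as.integer(ancestor_at),
               max_lifetimes = as.integer(max_lifetimes),
               max_mutations = as.integer(max_mutations))
  raw <- cpp_run(unclass(params), opts, init_state)
  res <- list(
    params = params,
    trajectory = as.data.frame(raw$trajectory),
    snapshots = lapply(raw$snapshots, engine_snapshot),
    births = raw$births, deaths = raw$deaths,
    cell_events = raw$cell_events,
    lifetimes = raw$lifetimes,
    mutations = raw$mutations,
    ancestors = raw$ancestors,
    final_state = raw$final_state,
    extinct = raw$extinct,
    conservation_violations = raw$conservation_violations,
    steps_run = raw$steps_run)
  res$births$rtype <- c("P", "Q")[res$births$rtype + 1L]
  res$deaths$rtype <- c("P", "Q")[res$deaths$rtype + 1L]
  res$cell_events$event <- c("birth", "removal")[res$cell_events$event + 1L]
  class(res) <- "replicell_run"
  res
}

engine_snapshot <- function(s) {
  k <- s$k
  colnames(k) <- k_entry_names()
  n <- length(s$rep_id)
  reps <- data.frame(cell_id = s$cell_id, rep_id = s$rep_id,
                     rtype = c("P", "Q")[s$rtype + 1L],
                     state = rep("free", n))
  new_snapshot(s$step, cbind(reps, as.data.frame(k)),
               data.frame(cell_id = s$cells_id, substrate = s$cells_substrate))
}

#' @export
print.replicell_run <- function(x, ...) {
  cat(sprintf("<replicell_run> %d steps, V = %d, m = %g\n",
              x$steps_run, x$params$V, x$params$m))
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("  final: %d cells, %d replicators; extinct: %s; conservation violations: %d\n",
              as.integer(last$cell_count), as.integer(last$n_replicators),
              x$extinct, x$conservation_violations))
  invisible(x)
}
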
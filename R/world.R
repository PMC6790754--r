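#' @useDynLib replicell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom rmultinom setNames median var ave uniroot
#' @importFrom utils read.delim write.table head
NULL

new_cell <- function(id, n, k_max, start_type = 0L, parent = NA_integer_,
                     substrate = 0L, first_step = 1L) {
  k <- matrix(k_max, nrow = n, ncol = 8,
              dimnames = list(NULL, k_entry_names()))
  list(id = as.integer(id), parent = as.integer(parent),
       substrate = as.integer(substrate),
       rep_id = integer(n), rtype = (seq_len(n) - 1L + start_type) %% 2L,
       state = integer(n), birth_step = rep(as.integer(first_step), n),
       template_parent = rep(NA_integer_, n), k = k)
}

#' Construct the initial world state
#'
#' Creates `init_cells` protocells of (as near as possible) equal size with
#' zero substrate, every catalytic value set to `k_max`, and replicator
#' types alternating within each cell so that the global P:Q split is as
#' even as parity allows. Each cell holds `n_tot / init_cells` particles,
#' which is exactly at (not above) the division threshold when
#' `n_tot = 50 V` and `init_cells = 50`, so no division fires at step 0.
#'
#' @param params A [sim_params()] object.
#' @return A `protocell_world` object: a list with elements `params`,
#'   `step`, `cells` (list of cells), and id counters.
#' @examples
#' w <- init_world(sim_params(V = 10, m = 0, t_max = 0))
#' length(w$cells) # 50
#' @export
init_world <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  nc <- params$init_cells
  base <- params$n_tot %/% nc
  extra <- params$n_tot - base * nc
  cells <- vector("list", nc)
  next_id <- 1L
  for (ci in seq_len(nc)) {
    n <- base + as.integer(ci <= extra)
    cell <- new_cell(ci, n, params$k_max, start_type = (ci - 1L) %% 2L)
    cell$rep_id <- seq.int(next_id, length.out = n)
    next_id <- next_id + n
    cells[[ci]] <- cell
  }
  w <- list(params = params, step = 0L, cells = cells,
            next_rep_id = next_id, next_cell_id = nc + 1L)
  class(w) <- "protocell_world"
  w
}

#' Total particle count of a world
#'
#' @param world A `protocell_world`.
#' @return Integer: replicators plus substrate summed over cells.
#' @export
particle_count <- function(world) {
  sum(vapply(world$cells,
             function(c) length(c$rep_id) + c$substrate, numeric(1)))
}

#' Check the global particle-conservation invariant
#'
#' @param world A `protocell_world`.
#' @return `TRUE` if the total particle count equals `n_tot` exactly.
#' @export
conservation_holds <- function(world) {
  particle_count(world) == world$params$n_tot
}

#' @export
print.protocell_world <- function(x, ...) {
  n <- sum(vapply(x$cells, function(c) length(c$rep_id), numeric(1)))
  s <- sum(vapply(x$cells, function(c) c$substrate, numeric(1)))
  cat(sprintf("<protocell_world> step %d: %d cells, %d replicators, %d substrate\n",
              x$step, length(x$cells), n, s))
  invisible(x)
}

#' Extract a population snapshot from a world
#'
#' @param world A `protocell_world`.
#' @return A `replicell_snapshot`: list with `step`, a `replicators` data
#'   frame (cell_id, rep_id, rtype, state and the eight k columns) and a
#'   `cells` data frame (cell_id, substrate).
#' @export
as_snapshot <- function(world) {
  reps <- do.call(rbind, lapply(world$cells, function(c) {
    n <- length(c$rep_id)
    if (n == 0) return(NULL)
    df <- data.frame(cell_id = rep(c$id, n), rep_id = c$rep_id,
                     rtype = c("P", "Q")[c$rtype + 1L],
                     state = c("free", "catalyst", "template")[c$state + 1L])
    cbind(df, as.data.frame(c$k))
  }))
  if (is.null(reps)) {
    reps <- data.frame(cell_id = integer(), rep_id = integer(),
                       rtype = character(), state = character())
    for (nm in k_entry_names()) reps[[nm]] <- numeric()
  }
  cells <- data.frame(
    cell_id = vapply(world$cells, function(c) c$id, integer(1)),
    substrate = vapply(world$cells, function(c) as.integer(c$substrate),
                       integer(1)))
  new_snapshot(world$step, reps, cells)
}

new_snapshot <- function(step, replicators, cells) {
  s <- list(step = as.integer(step), replicators = replicators, cells = cells)
  class(s) <- "replicell_snapshot"
  s
}

#' @export
print.replicell_snapshot <- function(x, ...) {
  cat(sprintf("<replicell_snapshot> step %d: %d replicators in %d cells, %d substrate\n",
              x$step, nrow(x$replicators), nrow(x$cells),
              sum(x$cells$substrate)))
  invisible(x)
}

snapshot_k_matrix <- function(snapshot) {
  as.matrix(snapshot$replicators[, k_entry_names(), drop = FALSE])
}

#' Write a snapshot as JSON lines
#'
#' One JSON record per replicator (`step`, `cell_id`, `rep_id`, `rtype`,
#' `k` as an array of 8 floats in the fixed storage order, `state`) followed
#' by one record per cell (`step`, `cell_id`, `substrate`). Key order is
#' fixed; appending lets several snapshots share one file.
#'
#' @param snapshot A `replicell_snapshot`.
#' @param path Output file.
#' @param append Append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_snapshot_jsonl <- function(snapshot, path, append = FALSE) {
  k <- snapshot_k_matrix(snapshot)
  reps <- snapshot$replicators
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reps))) {
    rec <- list(step = snapshot$step, cell_id = reps$cell_id[i],
                rep_id = reps$rep_id[i], rtype = reps$rtype[i],
                k = as.numeric(k[i, ]), state = reps$state[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  for (i in seq_len(nrow(snapshot$cells))) {
    rec <- list(step = snapshot$step, cell_id = snapshot$cells$cell_id[i],
                substrate = snapshot$cells$substrate[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read snapshots from a JSON-lines file
#'
#' @param path File written by [write_snapshot_jsonl()].
#' @return A list of `replicell_snapshot` objects, one per distinct `step`.
#' @export
read_snapshot_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  is_rep <- vapply(recs, function(r) "rep_id" %in% names(r), logical(1))
  steps <- sort(unique(vapply(recs, function(r) r$step, numeric(1))))
  lapply(steps, function(s) {
    rr <- recs[is_rep & vapply(recs, function(r) r$step == s, logical(1))]
    cr <- recs[!is_rep & vapply(recs, function(r) r$step == s, logical(1))]
    reps <- data.frame(
      cell_id = vapply(rr, function(r) as.integer(r$cell_id), integer(1)),
      rep_id = vapply(rr, function(r) as.integer(r$rep_id), integer(1)),
      rtype = vapply(rr, function(r) r$rtype, character(1)),
      state = vapply(rr, function(r) r$state, character(1)))
    k <- do.call(rbind, lapply(rr, function(r) as.numeric(r$k)))
    if (is.null(k)) k <- matrix(numeric(), 0, 8)
    colnames(k) <- k_entry_names()
    cells <- data.frame(
      cell_id = vapply(cr, function(r) as.integer(r$cell_id), integer(1)),
      substrate = vapply(cr, function(r) as.integer(r$substrate), integer(1)))
    new_snapshot(s, cbind(reps, as.data.frame(k)), cells)
  })
}

#' Serialize a world to the engine's state format
#'
#' The returned list can be passed to [run_simulation()] as `init_state` to
#' start the compiled engine from an arbitrary configuration (for example a
#' hand-built two-cell competition experiment).
#'
#' @param world A `protocell_world`.
#' @return A plain list (`step`, id counters, `cells`).
#' @export
world_to_state <- function(world) {
  list(step = world$step,
       next_rep_id = as.integer(world$next_rep_id),
       next_cell_id = as.integer(world$next_cell_id),
       cells = lapply(world$cells, function(c) {
         list(id = c$id, parent = if (is.na(c$parent)) -1L else c$parent,
              substrate = as.numeric(c$substrate),
              rep_id = as.integer(c$rep_id), rtype = as.integer(c$rtype),
              birth_step = as.integer(c$birth_step),
              k = unname(c$k))
       }))
}

#' Rebuild a world object from an engine state
#'
#' @param state A state list as returned in `run$final_state` or by
#'   [world_to_state()].
#' @param params The [sim_params()] the state was generated under.
#' @return A `protocell_world`.
#' @export
state_to_world <- function(state, params) {
  cells <- lapply(state$cells, function(c) {
    n <- length(c$rep_id)
    k <- matrix(c$k, ncol = 8, dimnames = list(NULL, k_entry_names()))
    list(id = as.integer(c$id),
         parent = if (is.na(c$parent) || c$parent < 0) NA_integer_
                  else as.integer(c$parent),
         substrate = as.integer(c$substrate),
         rep_id = as.integer(c$rep_id), rtype = as.integer(c$rtype),
         state = integer(n), birth_step = as.integer(c$birth_step),
         template_parent = rep(NA_integer_, n), k = k)
  })
  w <- list(params = params, step = as.integer(state$step), cells = cells,
            next_rep_id = as.integer(state$next_rep_id),
            next_cell_id = as.integer(state$next_cell_id))
  class(w) <- "protocell_world"
  w
}
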
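#' Build a protocell genealogy from a cell event log
#'
#' @param cell_events Data frame with columns `step`, `event` ("birth" or
#'   "removal"), `cell_id`, `parent_id` (NA for founding cells), as
#'   produced by [run_simulation()] with `log_cell_events = TRUE` or by
#'   [divide_and_cull()].
#' @return A `cell_tree`: list with named vectors `parent`, `birth`,
#'   `death` (NA while alive) indexed by cell id, and `alive`, the ids
#'   never removed.
#' @export
cell_tree <- function(cell_events) {
  b <- cell_events[cell_events$event == "birth", ]
  r <- cell_events[cell_events$event == "removal", ]
  ids <- as.character(b$cell_id)
  parent <- setNames(b$parent_id, ids)
  birth <- setNames(b$step, ids)
  death <- setNames(rep(NA_real_, length(ids)), ids)
  death[as.character(r$cell_id)] <- r$step
  # acyclicity: every cell must reach a root through older cells
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle detected in cell genealogy at ", cur)
      seen <- c(seen, cur)
      cur <- as.character(parent[[cur]])
      if (!cur %in% ids) stop("missing parent record for cell ", cur)
    }
  }
  structure(list(parent = parent, birth = birth, death = death,
                 alive = as.integer(names(death)[is.na(death)])),
            class = "cell_tree")
}

tree_alive_at <- function(tree, at_step) {
  as.integer(names(tree$birth)[tree$birth <= at_step &
                                 (is.na(tree$death) | tree$death > at_step)])
}

#' Common ancestors of all surviving protocells at a given step
#'
#' Walks each surviving cell's ancestry back in time and returns the cells
#' that were alive at `at_step` and are ancestral to every survivor (a
#' cell counts as its own ancestor). The set is empty when the survivors'
#' cell-level coalescence postdates `at_step`.
#'
#' @param tree A [cell_tree()].
#' @param at_step Time step at which candidate ancestors must be alive.
#' @param survivors Cell ids to trace from; defaults to all cells never
#'   removed.
#' @return Integer vector of cell ids (possibly empty).
#' @export
common_ancestor_cells <- function(tree, at_step, survivors = tree$alive) {
  if (length(survivors) == 0) stop("no surviving cells")
  anc_sets <- lapply(survivors, function(s) {
    out <- integer(0)
    cur <- as.character(s)
    repeat {
      if (tree$birth[[cur]] <= at_step &&
          (is.na(tree$death[[cur]]) || tree$death[[cur]] > at_step))
        out <- c(out, as.integer(cur))
      p <- tree$parent[[cur]]
      if (is.na(p)) break
      cur <- as.character(p)
    }
    out
  })
  Reduce(intersect, anc_sets)
}

#' Build a molecular lineage from birth and death event logs
#'
#' @param births Birth events (`step`, `rep_id`, `template_id`), e.g. the
#'   `births` component of a [run_simulation()] result.
#' @param deaths Death events (`step`, `rep_id`); replicators without a
#'   death record are taken to be alive at the end of the log.
#' @param roots Optional data frame (`rep_id`, `birth_step`) declaring
#'   founding replicators with no template parent (e.g. the initial
#'   population).
#' @return A `molecular_lineage`: named vectors `parent`, `birth`, `death`
#'   indexed by replicator id.
#' @export
molecular_lineage <- function(births, deaths = NULL, roots = NULL) {
  ids <- as.character(births$rep_id)
  parent <- setNames(births$template_id, ids)
  birth <- setNames(births$step, ids)
  if (!is.null(roots)) {
    rid <- as.character(roots$rep_id)
    parent <- c(parent, setNames(rep(NA_integer_, length(rid)), rid))
    birth <- c(birth, setNames(roots$birth_step, rid))
  }
  death <- setNames(rep(NA_real_, length(parent)), names(parent))
  if (!is.null(deaths) && nrow(deaths) > 0) {
    hit <- as.character(deaths$rep_id)
    hit <- hit[hit %in% names(death)]
    death[hit] <- deaths$step[match(hit, as.character(deaths$rep_id))]
  }
  structure(list(parent = parent, birth = birth, death = death),
            class = "molecular_lineage")
}

#' Trace focal replicators to their ancestors within a time window
#'
#' For each focal replicator, walks template-parent links back in time
#' until reaching the most recent ancestor whose lifetime intersects
#' `[t0, t1]` (a replicator born inside the window is its own ancestor).
#' Returns the ancestors as a multiset: coalescent lineages count with
#' multiplicity.
#'
#' @param lineage A [molecular_lineage()].
#' @param focal Replicator ids to trace from (typically the surviving
#'   population, or the survivors contained in common-ancestor cells).
#' @param window Numeric `c(t0, t1)`.
#' @return Named integer vector: ancestor id -> multiplicity.
#' @export
trace_replicator_ancestors <- function(lineage, focal, window) {
  t0 <- window[1]; t1 <- window[2]
  anc <- vapply(focal, function(f) {
    cur <- as.character(f)
    repeat {
      if (!cur %in% names(lineage$parent))
        stop("lineage gap: no birth record for replicator ", cur)
      b <- lineage$birth[[cur]]
      d <- lineage$death[[cur]]
      if (b <= t1 && (is.na(d) || d >= t0)) return(as.integer(cur))
      p <- lineage$parent[[cur]]
      if (is.na(p))
        stop("lineage gap: root ", cur, " does not intersect the window")
      cur <- as.character(p)
    }
  }, integer(1))
  tab <- table(anc)
  setNames(as.integer(tab), names(tab))
}

#' Role spectrum of a population and of its window ancestors
#'
#' Assigns the two replicator types to the roles "template" and "catalyst"
#' by their mean own-type activities (the type with the smaller `A_c` is
#' the template type -- after symmetry breaking, types and roles coincide)
#' and reports the role composition of the whole population and of a
#' multiset of ancestors. When the two activities are indistinguishable
#' the role assignment is labelled "undifferentiated" and frequencies are
#' reported by type (P mapped to the "template" slot).
#'
#' @param ancestor_types Character vector of ancestor types ("P"/"Q"),
#'   repeated per multiplicity, or a named multiplicity vector with an
#'   accompanying `types` lookup.
#' @param snapshot A `replicell_snapshot` of the population at the window
#'   (used both for the role assignment and the population composition).
#' @param tol Activities closer than this are considered undifferentiated.
#' @return List of class `role_spectrum`: `role_assignment`,
#'   `template_type`, `population` and `ancestors`, each a frequency pair
#'   `(template, catalyst)` summing to 1.
#' @export
ancestor_role_spectrum <- function(ancestor_types, snapshot, tol = 1e-9) {
  A <- own_activity_means(snapshot)
  undiff <- abs(A[["P"]] - A[["Q"]]) < tol
  tmpl_type <- if (undiff) "P" else names(A)[which.min(A)]
  cat_type <- setdiff(c("P", "Q"), tmpl_type)
  pop_types <- snapshot$replicators$rtype
  freqs <- function(types) {
    n <- length(types)
    if (n == 0) return(c(template = NA_real_, catalyst = NA_real_))
    c(template = sum(types == tmpl_type) / n,
      catalyst = sum(types == cat_type) / n)
  }
  structure(list(
    role_assignment = if (undiff) "undifferentiated" else "by_activity",
    template_type = tmpl_type, catalyst_type = cat_type,
    population = freqs(pop_types),
    ancestors = freqs(ancestor_types)),
    class = "role_spectrum")
}

#' @export
print.role_spectrum <- function(x, ...) {
  cat(sprintf("<role_spectrum> template type %s (%s)\n", x$template_type,
              x$role_assignment))
  cat(sprintf("  population: template %.3f / catalyst %.3f\n",
              x$population[1], x$population[2]))
  cat(sprintf("  ancestors:  template %.3f / catalyst %.3f\n",
              x$ancestors[1], x$ancestors[2]))
  invisible(x)
}

#' Two-level ancestor summary of a completed run
#'
#' Uses the engine's online window-ancestor tracking (see the
#' `ancestor_at` argument of [run_simulation()]): first finds the
#' common-ancestor cells of all surviving protocells at the anchor step,
#' then restricts the surviving replicators' window ancestors to those
#' contained in the common-ancestor cells, and reports the ancestor role
#' spectrum against the whole population at the anchor step.
#'
#' @param run A `replicell_run` produced with `ancestor_at` set.
#' @param require_common_cell Restrict ancestors to common-ancestor cells;
#'   if the surviving cells have not coalesced since the anchor step the
#'   restricted set is empty and the unrestricted spectrum is returned
#'   with a warning.
#' @return List with the anchor step, the population type counts and mean
#'   own activities at the anchor, the ancestor table, whether the cell
#'   lineages had coalesced, and the `role_spectrum`.
#' @export
ancestor_summary <- function(run, require_common_cell = TRUE) {
  anc <- run$ancestors
  if (is.null(anc)) stop("run was not produced with ancestor tracking")
  coalesced <- length(anc$surviving_cell_ancestors) == 1
  tab <- data.frame(anc_id = anc$anc_id,
                    type = c("P", "Q")[anc$anc_type + 1L],
                    cell = anc$anc_cell, count = anc$anc_count)
  use <- tab
  if (require_common_cell) {
    if (coalesced) {
      use <- tab[tab$cell == anc$surviving_cell_ancestors, ]
    } else {
      warning("surviving cells had not coalesced since the anchor step; ",
              "reporting the unrestricted ancestor spectrum")
    }
  }
  A <- c(P = anc$pop_A_P, Q = anc$pop_A_Q)
  undiff <- abs(A[["P"]] - A[["Q"]]) < 1e-9
  tmpl_type <- if (undiff) "P" else names(A)[which.min(A)]
  cat_type <- setdiff(c("P", "Q"), tmpl_type)
  pop_n <- c(P = anc$pop_nP, Q = anc$pop_nQ)
  pop <- c(template = pop_n[[tmpl_type]], catalyst = pop_n[[cat_type]]) /
    sum(pop_n)
  anc_n <- c(P = sum(use$count[use$type == "P"]),
             Q = sum(use$count[use$type == "Q"]))
  ancf <- if (sum(anc_n) > 0)
    c(template = anc_n[[tmpl_type]], catalyst = anc_n[[cat_type]]) /
      sum(anc_n)
  else c(template = NA_real_, catalyst = NA_real_)
  spectrum <- structure(list(
    role_assignment = if (undiff) "undifferentiated" else "by_activity",
    template_type = tmpl_type, catalyst_type = cat_type,
    population = pop, ancestors = ancf),
    class = "role_spectrum")
  list(at_step = anc$at_step, population_counts = pop_n,
       mean_own_activity = A, ancestors = tab, coalesced = coalesced,
       spectrum = spectrum)
}
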
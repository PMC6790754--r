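#' Simulation parameters
#'
#' Bundles and validates the parameters of the protocell model. The model
#' follows a convention in which the unit of time is the interval over which
#' one replicator decays with probability `d`, so the mean replicator
#' lifetime is `1/d` steps. The total particle number `n_tot` (replicators
#' plus substrate) is conserved and defaults to `50 * V`, which keeps the
#' quasi-stationary protocell count near 100 for any division threshold `V`.
#'
#' @param V Division threshold: a protocell containing more than `V`
#'   particles (replicators plus substrate) divides. Must be >= 2.
#' @param m Mutation probability, applied independently to each of the eight
#'   catalytic values at every replication or transcription event.
#' @param d Per-step decay probability of a replicator. Default 0.02.
#' @param delta_mut Mutation half-width: increments are drawn uniformly from
#'   `(-delta_mut, delta_mut)`. Default 0.05.
#' @param k_max Upper bound on catalytic values, enforced by a reflecting
#'   boundary. There is no lower bound, but negative values contribute zero
#'   rate (see [effective_rate()]). Default 1.
#' @param n_tot Total particle count. Default `50 * V`.
#' @param init_cells Number of initial protocells. Default 50.
#' @param t_max Number of time steps to simulate.
#' @param record_every Trajectory recording cadence (steps).
#' @param snapshot_every Snapshot cadence in steps; 0 means "final snapshot
#'   only".
#' @param density_collisions Scale each candidate pair's complex-formation
#'   probability by the replicator density `(n - 1) / V` of its cell
#'   (capped at 1), as mass-action collision kinetics in a compartment of
#'   fixed volume would. A cell filled to the division threshold reacts at
#'   full rate; dilute cells react more slowly, which lets well-filled
#'   protocells capture diffusing substrate from shrunken ones. Default
#'   `TRUE`.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(V = 100, m = 0.01, t_max = 1000, seed = 1)
#' p$n_tot # 5000
#' @export
sim_params <- function(V, m, d = 0.02, delta_mut = 0.05, k_max = 1,
                       n_tot = 50 * V, init_cells = 50, t_max = 1000,
                       record_every = 10, snapshot_every = 0,
                       density_collisions = TRUE, seed = NULL) {
  stopifnot(length(V) == 1, length(m) == 1)
  if (V < 2) stop("V must be at least 2")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (d <= 0 || d > 1) stop("d must lie in (0, 1]")
  if (delta_mut <= 0) stop("delta_mut must be positive")
  if (k_max <= 0) stop("k_max must be positive")
  if (n_tot < init_cells) stop("n_tot must be at least init_cells")
  if (record_every < 1 || snapshot_every < 0)
    stop("record_every must be >= 1 and snapshot_every >= 0")
  if (t_max < 0) stop("t_max must be nonnegative")
  p <- list(V = as.integer(V), m = m, d = d, delta_mut = delta_mut,
            k_max = k_max, n_tot = as.integer(round(n_tot)),
            init_cells = as.integer(init_cells), t_max = as.integer(t_max),
            record_every = as.integer(record_every),
            snapshot_every = as.integer(snapshot_every),
            density_collisions = isTRUE(density_collisions),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Protocell model parameters\n")
  cat(sprintf("  V = %d, m = %g, d = %g, delta_mut = %g, k_max = %g\n",
              x$V, x$m, x$d, x$delta_mut, x$k_max))
  cat(sprintf("  n_tot = %d, init_cells = %d, t_max = %d\n",
              x$n_tot, x$init_cells, x$t_max))
  cat(sprintf("  record_every = %d, snapshot_every = %d, seed = %s\n",
              x$record_every, x$snapshot_every,
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Names of the eight catalytic values in their fixed storage order
#'
#' The order is `c = P` block first, then `c = Q`, each block ordered by
#' (product, template) = PP, PQ, QP, QQ. Entry `kC.PT` is the rate constant
#' with which a catalyst of type `C` produces type `P` from a template of
#' type `T` (for the replicator itself when `C` equals its own type, for its
#' transcripts otherwise).
#'
#' @return Character vector of length 8.
#' @export
k_entry_names <- function() {
  c("kP.PP", "kP.PQ", "kP.QP", "kP.QQ", "kQ.PP", "kQ.PQ", "kQ.QP", "kQ.QQ")
}

#' Column index of a catalytic value k^c_pt
#'
#' @param c,p,t Types ("P" or "Q") of the carrier/transcript block, the
#'   product, and the template.
#' @return Integer index in 1..8.
#' @examples
#' k_index("P", "Q", "P") # 3
#' @export
k_index <- function(c, p, t) {
  code <- function(x) {
    if (is.character(x)) match(x, c("P", "Q")) - 1L else as.integer(x)
  }
  4L * code(c) + 2L * code(p) + code(t) + 1L
}

#' Effective complex-formation rate of a catalytic value
#'
#' Heritable catalytic values are unbounded below (mutation can push them
#' negative) but a negative value contributes zero rate. Values above
#' `k_max` indicate a corrupted profile and raise an error.
#'
#' @param k Numeric vector of catalytic values.
#' @param k_max Upper bound on catalytic values.
#' @return Nonnegative rates, `pmax(k, 0)`.
#' @export
effective_rate <- function(k, k_max = 1) {
  if (any(k > k_max + 1e-12))
    stop("catalytic value exceeds k_max: corrupted profile")
  pmax(k, 0)
}
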
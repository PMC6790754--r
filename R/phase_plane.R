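#' Parameters of the deterministic mean-trait model
#'
#' The reduced model follows the two mean catalytic activities
#' `(kP, kQ)` on the unit box under selection-gradient dynamics: each
#' type's mean activity changes at a rate set by the cellular-level
#' benefit (weight `beta`, scaled by the between-cell variance
#' `sigma2_cel`) and the molecular-level cost (weight `gamma`, scaled by
#' the within-cell variance `sigma2_mol`), with the two types' terms
#' weighted by their normalized reproductive values. The defaults
#' `beta = 1`, `gamma = s` are the choice under which the flow is the
#' gradient of the inclusive-fitness potential
#' `R B - (1 - R) C` (see [potential_gradient_check()]).
#'
#' @param sigma2_cel Between-cell trait variance (>= 0). Default 1.
#' @param sigma2_mol Within-cell trait variance (>= 0).
#' @param s Cost-benefit ratio (> 0). Default 1.
#' @param beta Cellular-level benefit coefficient. Default 1.
#' @param gamma Molecular-level cost coefficient. Default `s`.
#' @return A `pp_params` object.
#' @export
pp_params <- function(sigma2_mol, sigma2_cel = 1, s = 1, beta = 1,
                      gamma = s) {
  stopifnot(sigma2_mol >= 0, sigma2_cel >= 0, s > 0)
  structure(list(sigma2_cel = sigma2_cel, sigma2_mol = sigma2_mol, s = s,
                 beta = beta, gamma = gamma), class = "pp_params")
}

#' Normalized reproductive values of the two types
#'
#' `omega_c = exp(-s * k_c) / (exp(-s * kP) + exp(-s * kQ))`: the more
#' catalytic type is sequestered in complexes more often, is replicated
#' less, and so carries the smaller reproductive value. The two values
#' sum to 1.
#'
#' @param kP,kQ Mean activities in `[0, 1]` (vectorized).
#' @param s Cost-benefit ratio.
#' @return Matrix with columns `P` and `Q`.
#' @examples
#' omega_bar(1, 0)       # c(1/(1+e), e/(1+e))
#' @export
omega_bar <- function(kP, kQ, s = 1) {
  # logistic in the activity difference, numerically stable
  wP <- 1 / (1 + exp(s * (kP - kQ)))
  cbind(P = wP, Q = 1 - wP)
}

#' Mean-trait flow field
#'
#' The raw flow is
#' `dkP = omegaP * (beta * sigma2_cel - gamma * sigma2_mol) +
#'  omegaQ * beta * sigma2_cel` (and symmetrically for Q). On the box
#' boundary a component is zeroed only when it points outward
#' (one-sided clamping), so a boundary state is pinned when the flow
#' presses against the wall but may leave when the flow points inward.
#'
#' @param kP,kQ State (vectorized).
#' @param pp A [pp_params()] object.
#' @param clamp Apply the outward-one-sided boundary clamping.
#' @return Matrix with columns `dkP`, `dkQ`.
#' @export
pp_rhs <- function(kP, kQ, pp, clamp = TRUE) {
  w <- omega_bar(kP, kQ, pp$s)
  bcel <- pp$beta * pp$sigma2_cel
  gmol <- pp$gamma * pp$sigma2_mol
  dP <- w[, "P"] * (bcel - gmol) + w[, "Q"] * bcel
  dQ <- w[, "P"] * bcel + w[, "Q"] * (bcel - gmol)
  if (clamp) {
    dP[kP >= 1 & dP > 0] <- 0
    dP[kP <= 0 & dP < 0] <- 0
    dQ[kQ >= 1 & dQ > 0] <- 0
    dQ[kQ <= 0 & dQ < 0] <- 0
  }
  cbind(dkP = dP, dkQ = dQ)
}

#' Inclusive-fitness potential and its consistency with the flow
#'
#' With `beta = 1` and `gamma = s` the flow equals
#' `sigma2_tot * grad(R B - (1 - R) C)` where
#' `R = sigma2_cel / sigma2_tot`, `B = kP + kQ` and
#' `C = -log(exp(-s kP) + exp(-s kQ))`. `potential_value()` evaluates the
#' potential; `potential_gradient_check()` evaluates the gradient form at
#' interior states and returns the maximum absolute deviation from
#' [pp_rhs()], which must vanish to floating-point accuracy.
#'
#' @param kP,kQ Interior states (vectorized).
#' @param pp A [pp_params()] object (with `beta = 1`, `gamma = s`).
#' @return `potential_value()`: numeric vector.
#'   `potential_gradient_check()`: max absolute deviation.
#' @export
potential_value <- function(kP, kQ, pp) {
  s2 <- pp$sigma2_cel + pp$sigma2_mol
  R <- pp$sigma2_cel / s2
  B <- kP + kQ
  C <- -log(exp(-pp$s * kP) + exp(-pp$s * kQ))
  R * B - (1 - R) * C
}

#' @rdname potential_value
#' @export
potential_gradient_check <- function(kP, kQ, pp) {
  s2 <- pp$sigma2_cel + pp$sigma2_mol
  R <- pp$sigma2_cel / s2
  w <- omega_bar(kP, kQ, pp$s)
  gradP <- R - (1 - R) * pp$s * w[, "P"]   # d/dkP of R*B - (1-R)*C
  gradQ <- R - (1 - R) * pp$s * w[, "Q"]
  flow_pot <- s2 * cbind(gradP, gradQ)
  flow_rhs <- pp_rhs(kP, kQ, pp, clamp = FALSE)
  max(abs(flow_pot - flow_rhs))
}

# one-sided stability test for a point on the box boundary/corner:
# each clamped coordinate must press outward, each free coordinate must
# be locally attracting along its axis
stable_at <- function(kP, kQ, pp, h = 1e-7) {
  raw <- pp_rhs(kP, kQ, pp, clamp = FALSE)[1, ]
  ok <- TRUE
  for (coord in 1:2) {
    x <- c(kP, kQ)[coord]
    f <- raw[coord]
    if (x >= 1) ok <- ok && (f >= 0)
    else if (x <= 0) ok <- ok && (f <= 0)
    else {
      # derivative of the flow component along its own axis
      up <- c(kP, kQ); up[coord] <- x + h
      dn <- c(kP, kQ); dn[coord] <- x - h
      slope <- (pp_rhs(up[1], up[2], pp, clamp = FALSE)[1, coord] -
                  pp_rhs(dn[1], dn[2], pp, clamp = FALSE)[1, coord]) / (2 * h)
      ok <- ok && (abs(f) < 1e-10) && (slope < 0)
    }
  }
  ok
}

#' Equilibria of the clamped mean-trait dynamics
#'
#' Enumerates corner, edge and interior equilibria of the clamped flow.
#' Corners are equilibria when the raw flow presses outward (or vanishes)
#' in both coordinates. Edge equilibria are found by bracketing sign
#' changes of the tangential flow component on a fine grid and refining
#' with [uniroot()], keeping those whose normal component pins the state
#' to the edge. Because the raw flow depends on the state only through
#' the activity difference `kP - kQ` (its sum-direction component is
#' constant), interior equilibria exist only in the degenerate case
#' `gamma * sigma2_mol = 2 * beta * sigma2_cel`, where the whole diagonal
#' is neutrally stationary; this case is reported via the `degenerate`
#' attribute. Stability is classified from one-sided flow signs (pinned
#' coordinates) and the tangential derivative (free coordinates);
#' equilibria are deduplicated within `1e-9`.
#'
#' @param pp A [pp_params()] object.
#' @param n_grid Bracketing grid resolution per edge.
#' @return Data frame with columns `kP`, `kQ`, `kind`
#'   ("symmetric"/"asymmetric"), `stability` ("stable"/"unstable"/
#'   "saddle") and `boundary`.
#' @export
find_equilibria <- function(pp, n_grid = 201) {
  eqs <- list()
  add <- function(kP, kQ) {
    for (e in eqs) if (abs(e[1] - kP) < 1e-9 && abs(e[2] - kQ) < 1e-9)
      return(invisible(NULL))
    eqs[[length(eqs) + 1]] <<- c(kP, kQ)
  }
  # corners: equilibrium of the clamped flow iff no coordinate flows inward
  for (kP in c(0, 1)) for (kQ in c(0, 1)) {
    raw <- pp_rhs(kP, kQ, pp, clamp = FALSE)[1, ]
    inP <- if (kP == 1) raw[1] < 0 else raw[1] > 0
    inQ <- if (kQ == 1) raw[2] < 0 else raw[2] > 0
    if (!inP && !inQ) add(kP, kQ)
  }
  # edges: tangential root with pinning normal component
  grid <- seq(0, 1, length.out = n_grid)
  edge_scan <- function(fixed_coord, fixed_val) {
    tang <- function(x) {
      st <- if (fixed_coord == 1) c(fixed_val, x) else c(x, fixed_val)
      pp_rhs(st[1], st[2], pp, clamp = FALSE)[1, 3 - fixed_coord]
    }
    vals <- vapply(grid, tang, numeric(1))
    for (i in seq_len(n_grid - 1)) {
      if (vals[i] == 0 && grid[i] > 0 && grid[i] < 1) roots <- grid[i]
      else if (vals[i] * vals[i + 1] < 0)
        roots <- uniroot(tang, c(grid[i], grid[i + 1]),
                         tol = 1e-12)$root
      else next
      for (r in roots) {
        if (r <= 1e-9 || r >= 1 - 1e-9) next
        st <- if (fixed_coord == 1) c(fixed_val, r) else c(r, fixed_val)
        normal <- pp_rhs(st[1], st[2], pp, clamp = FALSE)[1, fixed_coord]
        pinned <- if (fixed_val == 1) normal >= 0 else normal <= 0
        if (pinned) add(st[1], st[2])
      }
    }
  }
  edge_scan(1, 1); edge_scan(1, 0); edge_scan(2, 1); edge_scan(2, 0)

  degenerate <- abs(pp$gamma * pp$sigma2_mol - 2 * pp$beta * pp$sigma2_cel) <
    1e-12
  out <- do.call(rbind, lapply(eqs, function(e) {
    kP <- e[1]; kQ <- e[2]
    on_boundary <- kP %in% c(0, 1) || kQ %in% c(0, 1)
    stable <- stable_at(kP, kQ, pp)
    # distinguish saddles from fully unstable points: a boundary point is
    # a saddle when it attracts along one axis and repels along the other
    stab <- if (stable) "stable" else {
      raw <- pp_rhs(kP, kQ, pp, clamp = FALSE)[1, ]
      axis_ok <- logical(2)
      for (coord in 1:2) {
        x <- c(kP, kQ)[coord]
        if (x >= 1) axis_ok[coord] <- raw[coord] >= 0
        else if (x <= 0) axis_ok[coord] <- raw[coord] <= 0
        else {
          h <- 1e-6
          up <- c(kP, kQ); up[coord] <- x + h
          dn <- c(kP, kQ); dn[coord] <- x - h
          axis_ok[coord] <-
            (pp_rhs(up[1], up[2], pp, clamp = FALSE)[1, coord] -
               pp_rhs(dn[1], dn[2], pp, clamp = FALSE)[1, coord]) < 0
        }
      }
      if (any(axis_ok)) "saddle" else "unstable"
    }
    data.frame(kP = kP, kQ = kQ,
               kind = if (abs(kP - kQ) < 1e-9) "symmetric" else "asymmetric",
               stability = stab, boundary = on_boundary)
  }))
  if (is.null(out))
    out <- data.frame(kP = numeric(), kQ = numeric(), kind = character(),
                      stability = character(), boundary = logical())
  attr(out, "degenerate") <- degenerate
  out
}

#' Integrate the clamped flow from one state
#'
#' Explicit Euler steps of size `dt`, projected onto the unit box.
#'
#' @param kP,kQ Initial state.
#' @param pp A [pp_params()] object.
#' @param dt Step size (default 0.15, matching short-duration flow
#'   arrows; use a smaller value for accurate basin boundaries).
#' @param horizon Maximum number of steps.
#' @param tol Convergence threshold on the step displacement.
#' @return Final state `c(kP, kQ)`.
#' @export
integrate_flow <- function(kP, kQ, pp, dt = 0.15, horizon = 5000,
                           tol = 1e-10) {
  for (i in seq_len(horizon)) {
    f <- pp_rhs(kP, kQ, pp, clamp = TRUE)[1, ]
    kP2 <- min(1, max(0, kP + dt * f[1]))
    kQ2 <- min(1, max(0, kQ + dt * f[2]))
    if (abs(kP2 - kP) < tol && abs(kQ2 - kQ) < tol) break
    kP <- kP2; kQ <- kQ2
  }
  c(kP = unname(kP), kQ = unname(kQ))
}

#' Basins of attraction on a grid
#'
#' Integrates the clamped flow from every point of a regular grid and
#' labels each point by the stable equilibrium it reaches (within
#' `1e-6`), or `"undetermined"` if none is reached within the horizon.
#'
#' @param pp A [pp_params()] object.
#' @param n Grid resolution per axis.
#' @param dt,horizon Passed to [integrate_flow()].
#' @return Data frame with `kP`, `kQ` (grid point) and `basin` (label
#'   `"kP*,kQ*"` of the attracting equilibrium or `"undetermined"`).
#' @export
basins <- function(pp, n = 21, dt = 0.15, horizon = 5000) {
  eq <- find_equilibria(pp)
  stab <- eq[eq$stability == "stable", , drop = FALSE]
  grid <- seq(0, 1, length.out = n)
  pts <- expand.grid(kP = grid, kQ = grid)
  lab <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    fin <- integrate_flow(pts$kP[i], pts$kQ[i], pp, dt = dt,
                          horizon = horizon)
    hit <- which(abs(stab$kP - fin[1]) < 1e-6 & abs(stab$kQ - fin[2]) < 1e-6)
    lab[i] <- if (length(hit) == 1)
      sprintf("%g,%g", stab$kP[hit], stab$kQ[hit]) else "undetermined"
  }
  pts$basin <- lab
  pts
}
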
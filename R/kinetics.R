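#' Complex-formation channel rates for a pair of replicators
#'
#' Two replicators can form four distinct complexes: either may serve as
#' the catalyst, and the product may be of type P or Q. The rate constant
#' of each channel is the catalyst's own-type catalytic value k^x_{p,y},
#' where `x` is the catalyst's type, `y` the template's type and `p` the
#' product type; negative heritable values contribute zero rate.
#'
#' @param X,Y Replicators: lists with `rtype` ("P"/"Q" or 0/1) and `k`
#'   (numeric vector of 8 in the fixed storage order).
#' @param k_max Upper bound on catalytic values.
#' @return A list with `rates` (2 x 2 matrix, rows X/Y = catalyst, columns
#'   P/Q = product) and `total` (their sum, at most `4 * k_max`).
#' @examples
#' r <- channel_rates(list(rtype = "P", k = rep(1, 8)),
#'                    list(rtype = "Q", k = rep(1, 8)))
#' r$total # 4
#' @export
channel_rates <- function(X, Y, k_max = 1) {
  tx <- if (is.character(X$rtype)) match(X$rtype, c("P", "Q")) - 1L else X$rtype
  ty <- if (is.character(Y$rtype)) match(Y$rtype, c("P", "Q")) - 1L else Y$rtype
  rates <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("P", "Q")))
  for (p in 0:1) {
    rates["X", p + 1L] <- effective_rate(X$k[k_index(tx, p, ty)], k_max)
    rates["Y", p + 1L] <- effective_rate(Y$k[k_index(ty, p, tx)], k_max)
  }
  list(rates = rates, total = sum(rates))
}

#' Mutate a catalytic profile
#'
#' Each of the eight values independently receives, with probability `m`,
#' an additive perturbation drawn uniformly from `(-delta_mut, delta_mut)`.
#' Values exceeding `k_max` are reflected (`k -> 2 k_max - k`); there is no
#' lower bound, so values may drift below zero (where they contribute zero
#' rate but remain heritable).
#'
#' @param k Numeric vector of 8 catalytic values (all `<= k_max`).
#' @param m Per-value mutation probability.
#' @param delta_mut Half-width of the uniform increment distribution.
#' @param k_max Reflecting upper bound.
#' @return The mutated profile.
#' @export
mutate_profile <- function(k, m, delta_mut, k_max = 1) {
  stopifnot(length(k) == 8)
  if (any(k > k_max + 1e-12)) stop("profile entries must not exceed k_max")
  hit <- runif(8) < m
  if (any(hit)) {
    k[hit] <- k[hit] + (2 * runif(sum(hit)) - 1) * delta_mut
    over <- k > k_max
    k[over] <- 2 * k_max - k[over]
  }
  k
}

#' Form catalyst-template complexes within one protocell
#'
#' Free replicators are paired at random into disjoint candidate pairs
#' (`floor(n_free / 2)` of them). Each pair forms a complex with
#' probability `total / (4 k_max)` -- proportional to the summed rates of
#' its four channels -- times, when `params$density_collisions` is set, the
#' mass-action collision factor `min(1, (n_free - 1) / V)`, so that a pair
#' of all-`k_max` replicators in a cell filled to the division threshold
#' always reacts. The realized channel (which member catalyses, which
#' product type) is drawn with probability proportional to the channel
#' rates. Members of a
#' complex are marked bound; complexes live only until the synthesis
#' substep of the same time step.
#'
#' @param cell A cell (as stored in a `protocell_world`).
#' @param params A [sim_params()] object.
#' @return A list with the updated `cell` (states set) and `complexes`, a
#'   data frame with columns `catalyst`, `template` (row indices into the
#'   cell) and `product` ("P"/"Q").
#' @export
form_complexes <- function(cell, params) {
  free <- which(cell$state == 0L)
  n <- length(free)
  cx <- data.frame(catalyst = integer(), template = integer(),
                   product = character())
  cfac <- if (isTRUE(params$density_collisions))
    min(1, (n - 1) / params$V) else 1
  if (n >= 2) {
    perm <- free[sample.int(n)]
    for (i in seq_len(n %/% 2)) {
      a <- perm[2 * i - 1]; b <- perm[2 * i]
      ra <- list(rtype = cell$rtype[a], k = cell$k[a, ])
      rb <- list(rtype = cell$rtype[b], k = cell$k[b, ])
      ch <- channel_rates(ra, rb, params$k_max)
      if (ch$total <= 0) next
      if (runif(1) * 4 * params$k_max < ch$total * cfac) {
        r <- c(ch$rates["X", "P"], ch$rates["X", "Q"],
               ch$rates["Y", "P"], ch$rates["Y", "Q"])
        pick <- sample.int(4, 1, prob = r)
        cat_i <- if (pick <= 2) a else b
        tmp_i <- if (pick <= 2) b else a
        prod <- c("P", "Q")[(pick - 1) %% 2 + 1]
        cell$state[cat_i] <- 1L
        cell$state[tmp_i] <- 2L
        cx <- rbind(cx, data.frame(catalyst = cat_i, template = tmp_i,
                                   product = prod))
      }
    }
  }
  list(cell = cell, complexes = cx)
}

#' Synthesize products from complexes, consuming substrate
#'
#' Complexes are visited in uniformly random order. While the cell still
#' holds substrate, each complex consumes one unit and produces a new
#' replicator of its product type whose eight catalytic values are copied
#' from the template and passed through [mutate_profile()]; once substrate
#' is exhausted the remaining complexes produce nothing. All complexes then
#' dissociate (both members return to the free state).
#'
#' @param cell A cell with states set by [form_complexes()].
#' @param complexes The complex table from [form_complexes()].
#' @param params A [sim_params()] object.
#' @param step Current time step (stamped on birth events).
#' @param next_rep_id First id to assign to newborns.
#' @return List with updated `cell`, a `births` data frame (step, child_id,
#'   child_type, template_id, catalyst_id, cell_id) and the advanced
#'   `next_rep_id`.
#' @export
synthesize_products <- function(cell, complexes, params, step = 0L,
                                next_rep_id = 1L) {
  births <- data.frame(step = integer(), child_id = integer(),
                       child_type = character(), template_id = integer(),
                       catalyst_id = integer(), cell_id = integer())
  ncx <- nrow(complexes)
  if (ncx > 0) {
    ord <- sample.int(ncx)
    for (i in ord) {
      if (cell$substrate <= 0) break
      cell$substrate <- cell$substrate - 1L
      tmpl <- complexes$template[i]
      child_k <- mutate_profile(cell$k[tmpl, ], params$m, params$delta_mut,
                                params$k_max)
      cell$rep_id <- c(cell$rep_id, next_rep_id)
      cell$rtype <- c(cell$rtype,
                      match(complexes$product[i], c("P", "Q")) - 1L)
      cell$state <- c(cell$state, 0L)
      cell$birth_step <- c(cell$birth_step, as.integer(step))
      cell$template_parent <- c(cell$template_parent, cell$rep_id[tmpl])
      cell$k <- rbind(cell$k, child_k)
      births <- rbind(births, data.frame(
        step = as.integer(step), child_id = next_rep_id,
        child_type = complexes$product[i],
        template_id = cell$rep_id[tmpl],
        catalyst_id = cell$rep_id[complexes$catalyst[i]],
        cell_id = cell$id))
      next_rep_id <- next_rep_id + 1L
    }
  }
  cell$state[] <- 0L
  list(cell = cell, births = births, next_rep_id = next_rep_id)
}

#' Decay substep for one protocell
#'
#' Every replicator independently dies with probability `d`; each death
#' returns one unit of substrate to the cell, so the cell's particle count
#' is unchanged.
#'
#' @param cell A cell (all replicators free).
#' @param d Per-step decay probability.
#' @param step Current time step (stamped on death events).
#' @return List with updated `cell` and a `deaths` data frame (step,
#'   rep_id, cell_id).
#' @export
decay_step <- function(cell, d, step = 0L) {
  n <- length(cell$rep_id)
  dies <- runif(n) < d
  deaths <- data.frame(step = rep(as.integer(step), sum(dies)),
                       rep_id = cell$rep_id[dies],
                       cell_id = rep(cell$id, sum(dies)))
  if (any(dies)) {
    keep <- !dies
    cell$substrate <- cell$substrate + sum(dies)
    cell$rep_id <- cell$rep_id[keep]
    cell$rtype <- cell$rtype[keep]
    cell$state <- cell$state[keep]
    cell$birth_step <- cell$birth_step[keep]
    cell$template_parent <- cell$template_parent[keep]
    cell$k <- cell$k[keep, , drop = FALSE]
  }
  list(cell = cell, deaths = deaths)
}
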
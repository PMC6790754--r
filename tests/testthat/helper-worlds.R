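# small hand-built cells and worlds for unit tests

make_cell <- function(id = 1L, n = 4, k = 1, substrate = 0L, types = NULL,
                      k_max = 1) {
  km <- matrix(k, nrow = n, ncol = 8,
               dimnames = list(NULL, k_entry_names()))
  if (is.null(types)) types <- (seq_len(n) - 1L) %% 2L
  list(id = id, parent = NA_integer_, substrate = as.integer(substrate),
       rep_id = seq_len(n), rtype = as.integer(types), state = integer(n),
       birth_step = rep(1L, n), template_parent = rep(NA_integer_, n),
       k = km)
}

# a world with explicitly given cells (sizes, uniform k per cell)
make_world <- function(params, sizes, ks = rep(1, length(sizes)),
                       substrates = rep(0L, length(sizes))) {
  cells <- lapply(seq_along(sizes), function(i)
    make_cell(id = i, n = sizes[i], k = ks[i], substrate = substrates[i],
              k_max = params$k_max))
  nid <- 1L
  for (i in seq_along(cells)) {
    cells[[i]]$rep_id <- seq.int(nid, length.out = sizes[i])
    nid <- nid + sizes[i]
  }
  w <- list(params = params, step = 0L, cells = cells,
            next_rep_id = nid, next_cell_id = length(cells) + 1L)
  class(w) <- "protocell_world"
  w
}

# snapshot from explicit per-cell trait vectors (all 8 entries = trait)
snapshot_from_traits <- function(traits_by_cell, types = NULL) {
  rows <- list()
  rid <- 1L
  for (ci in seq_along(traits_by_cell)) {
    v <- traits_by_cell[[ci]]
    for (x in v) {
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = ci, rep_id = rid,
        rtype = if (is.null(types)) c("P", "Q")[rid %% 2 + 1] else types[rid],
        state = "free", t(setNames(rep(x, 8), k_entry_names())))
      rid <- rid + 1L
    }
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps)) {
    reps <- data.frame(cell_id = integer(), rep_id = integer(),
                       rtype = character(), state = character())
    for (nm in k_entry_names()) reps[[nm]] <- numeric()
  }
  replicell:::new_snapshot(0L, reps,
    data.frame(cell_id = seq_along(traits_by_cell), substrate = 0L))
}
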
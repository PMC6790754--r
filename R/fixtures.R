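#' Specification for a synthetic population snapshot
#'
#' Describes a snapshot whose trait projection has prescribed between-cell
#' and within-cell variance -- the parameter-recovery fixture for the
#' variance-decomposition and Price machinery, usable without running long
#' simulations. The construction is a balanced two-point design: half of
#' the cells sit at `mean_trait + sqrt(sigma2_cel)`, half at
#' `mean_trait - sqrt(sigma2_cel)`, and within every cell half of the
#' replicators sit at the cell mean plus `sqrt(sigma2_mol)`, half at minus
#' it. With even counts the population moments match the targets exactly.
#'
#' @param n_cells Number of cells (even).
#' @param cell_size Replicators per cell (even).
#' @param sigma2_cel,sigma2_mol Target between-cell and within-cell
#'   variances of the trait projection.
#' @param mean_trait Target population mean trait.
#' @param type_composition Fraction of type-P replicators.
#' @param k_max Upper bound the trait values must respect.
#' @param seed Seed controlling the type assignment shuffle.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_cells, cell_size, sigma2_cel, sigma2_mol,
                         mean_trait = 0.5, type_composition = 0.5,
                         k_max = 1, seed = 1) {
  stopifnot(n_cells >= 2, cell_size >= 2, sigma2_cel >= 0, sigma2_mol >= 0)
  if (n_cells %% 2 != 0 || cell_size %% 2 != 0)
    stop("n_cells and cell_size must be even for exact variance targets")
  a <- sqrt(sigma2_cel); b <- sqrt(sigma2_mol)
  if (mean_trait - a - b < 0 || mean_trait + a + b > k_max)
    stop("targets unattainable: trait values would leave [0, k_max]")
  structure(list(n_cells = as.integer(n_cells),
                 cell_size = as.integer(cell_size),
                 sigma2_cel = sigma2_cel, sigma2_mol = sigma2_mol,
                 mean_trait = mean_trait,
                 type_composition = type_composition,
                 k_max = k_max, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic snapshot with prescribed variance structure
#'
#' All eight catalytic values of a replicator are set to its trait value,
#' so the trait projection of either block recovers the design exactly.
#'
#' @param spec A [fixture_spec()].
#' @return A `replicell_snapshot` (substrate 0 in every cell).
#' @examples
#' fx <- generate_fixture(fixture_spec(10, 10, 0.04, 0.01))
#' variance_decomposition(fx)$sigma2_cel # 0.04
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  a <- sqrt(spec$sigma2_cel); b <- sqrt(spec$sigma2_mol)
  cell_dev <- rep(c(a, -a), spec$n_cells / 2)
  rep_dev <- rep(c(b, -b), spec$cell_size / 2)
  n <- spec$n_cells * spec$cell_size
  nP <- round(spec$type_composition * n)
  types <- sample(c(rep("P", nP), rep("Q", n - nP)))
  reps <- do.call(rbind, lapply(seq_len(spec$n_cells), function(ci) {
    vals <- spec$mean_trait + cell_dev[ci] + rep_dev
    idx <- (ci - 1) * spec$cell_size + seq_len(spec$cell_size)
    df <- data.frame(cell_id = ci, rep_id = idx, rtype = types[idx],
                     state = "free")
    k <- matrix(vals, nrow = spec$cell_size, ncol = 8,
                dimnames = list(NULL, k_entry_names()))
    cbind(df, as.data.frame(k))
  }))
  cells <- data.frame(cell_id = seq_len(spec$n_cells), substrate = 0L)
  new_snapshot(0L, reps, cells)
}
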
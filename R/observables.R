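#' Population means of the eight catalytic values
#'
#' Unweighted mean over replicators (one replicator, one sample) of each of
#' the eight heritable values.
#'
#' @param snapshot A `replicell_snapshot`.
#' @return Named numeric vector of length 8 (see [k_entry_names()]).
#' @export
mean_activities <- function(snapshot) {
  if (nrow(snapshot$replicators) == 0) stop("empty snapshot: no replicators")
  k <- snapshot_k_matrix(snapshot)
  colMeans(k)
}

#' Mean own-type activity of each replicator type
#'
#' For each type `c`, the population mean (over all replicators) of the
#' four `k^c` entries -- the catalytic activity that molecules of type `c`
#' (whether extant or produced as transcripts) would express.
#'
#' @param snapshot A `replicell_snapshot`.
#' @return Named vector `c(P = A_P, Q = A_Q)`.
#' @export
own_activity_means <- function(snapshot) {
  mk <- mean_activities(snapshot)
  c(P = mean(mk[1:4]), Q = mean(mk[5:8]))
}

#' Per-cell minority-type frequencies
#'
#' For every protocell holding at least `V / 2` particles (replicators plus
#' substrate) and at least one replicator, the frequency of the rarer
#' replicator type, `min(nP, nQ) / (nP + nQ)`. The distribution of these
#' values (quartiles, percentiles) measures numerical symmetry breaking.
#'
#' @param snapshot A `replicell_snapshot`.
#' @param V Division threshold used for the cell-size filter.
#' @return Named numeric vector, one entry per qualifying cell.
#' @export
minority_frequency <- function(snapshot, V) {
  reps <- snapshot$replicators
  out <- numeric(0)
  for (i in seq_len(nrow(snapshot$cells))) {
    cid <- snapshot$cells$cell_id[i]
    sel <- reps$cell_id == cid
    n_rep <- sum(sel)
    particles <- n_rep + snapshot$cells$substrate[i]
    if (particles * 2 < V || n_rep == 0) next
    nP <- sum(reps$rtype[sel] == "P")
    out[as.character(cid)] <- min(nP, n_rep - nP) / n_rep
  }
  out
}

#' Trait projection: per-replicator mean of one type's four activities
#'
#' The raw heritable values (not clipped at zero) of the four `k^c`
#' entries, averaged per replicator. This scalar projection is what the
#' variance decomposition and Price analysis operate on.
#'
#' @param snapshot A `replicell_snapshot`.
#' @param c Which block, "P" or "Q".
#' @return Numeric vector, one value per replicator.
#' @export
trait_projection <- function(snapshot, c = "P") {
  k <- snapshot_k_matrix(snapshot)
  cols <- if (c == "P") 1:4 else 5:8
  rowMeans(k[, cols, drop = FALSE])
}

#' Within/between-cell variance decomposition and relatedness
#'
#' Decomposes the replicator-level variance of the trait projection into a
#' between-cell component (variance of cell means) and a within-cell
#' component (mean within-cell variance). Every moment counts one
#' replicator as one sample, so cells are weighted by their size and the
#' law of total variance holds exactly:
#' `sigma2_cel + sigma2_mol = total variance`. The ratio
#' `R = sigma2_cel / (sigma2_cel + sigma2_mol)` is the regression
#' coefficient of the cell mean on the individual trait, i.e. genetic
#' relatedness between cellmates.
#'
#' @param snapshot A `replicell_snapshot` (at least 2 replicators).
#' @param c Trait block, "P" or "Q".
#' @return List of class `variance_decomposition` with `sigma2_cel`,
#'   `sigma2_mol`, `R` (NA with a `reason` attribute when both variances
#'   vanish), and `n`.
#' @export
variance_decomposition <- function(snapshot, c = "P") {
  kappa <- trait_projection(snapshot, c)
  if (length(kappa) < 2) stop("need at least 2 replicators")
  cell <- snapshot$replicators$cell_id
  cm <- ave(kappa, cell)            # each replicator's cell mean
  mu <- mean(kappa)
  s_cel <- mean((cm - mu)^2)
  s_mol <- mean((kappa - cm)^2)
  R <- if (s_cel + s_mol > 0) s_cel / (s_cel + s_mol) else NA_real_
  if (is.na(R)) attr(R, "reason") <- "all traits identical; R undefined"
  structure(list(sigma2_cel = s_cel, sigma2_mol = s_mol, R = R,
                 n = length(kappa)),
            class = "variance_decomposition")
}

#' Price-equation decomposition of one generation of selection
#'
#' Splits the selection differential of a trait into a between-cell
#' covariance (cellular-level selection) and the expected within-cell
#' covariance (molecular-level selection). With faithful transmission the
#' identity `lhs = between + within` is exact:
#' `lhs = <lambda> * (sum(lambda * kappa) / sum(lambda) - <kappa>)`, the
#' mean fitness times the expected trait change. All moments are
#' population moments with one replicator as one sample.
#'
#' @param trait Numeric vector: trait value per replicator.
#' @param fitness Nonnegative vector: expected offspring number `lambda`
#'   per replicator.
#' @param cell Cell membership per replicator.
#' @return List of class `price_terms` with `lhs`, `between`, `within`.
#' @export
price_decompose <- function(trait, fitness, cell) {
  stopifnot(length(trait) == length(fitness), length(trait) == length(cell))
  if (any(fitness < 0)) stop("fitness values must be nonnegative")
  if (sum(fitness) == 0) stop("total fitness is zero")
  lam_bar <- mean(fitness)
  lhs <- lam_bar * (sum(fitness * trait) / sum(fitness) - mean(trait))
  lc <- ave(fitness, cell)
  kc <- ave(trait, cell)
  between <- mean((lc - lam_bar) * (kc - mean(trait)))
  within <- mean((fitness - lc) * (trait - kc))
  structure(list(lhs = lhs, between = between, within = within),
            class = "price_terms")
}

#' Fitness and Fisher reproductive values of a replicator lineage
#'
#' A replicator that is replicated into type P at rate `omega_P` and
#' transcribed into type Q at rate `omega_Q` projects its copy numbers
#' through the matrix `[[omega_P, omega_Q], [omega_P, omega_Q]]` (both P
#' and Q copies produce at the same per-capita rates, since activities are
#' inherited). Its dominant eigenvalue is `lambda = omega_P + omega_Q` and
#' the corresponding left eigenvector -- the reproductive values of the P
#' and Q roles -- is proportional to `(omega_P, omega_Q)`. A role that is
#' never copied (`omega = 0`) has zero reproductive value.
#'
#' @param omega_P,omega_Q Nonnegative rates, not both zero.
#' @return List with `lambda` and `u` (reproductive values normalized to
#'   sum 1).
#' @examples
#' reproductive_value(0, 0.4)$u # c(0, 1)
#' @export
reproductive_value <- function(omega_P, omega_Q) {
  if (omega_P < 0 || omega_Q < 0) stop("rates must be nonnegative")
  lambda <- omega_P + omega_Q
  if (lambda == 0) stop("both rates are zero: fitness undefined")
  list(lambda = lambda,
       u = c(P = omega_P, Q = omega_Q) / lambda)
}

#' Classify the end state of a run
#'
#' Maps end-window statistics onto one of five regimes using explicit,
#' documented thresholds. With `A_c` the mean own-type activity of type
#' `c` (see [own_activity_means()]), the catalyst type `C` is the one with
#' the larger `A_c` and the template type `T` the other:
#' \itemize{
#'   \item catalytic asymmetry: `A_T < eps`, `A_C >= ratio * A_T`, and
#'     `A_C > 2 * eps` (so a population that lost all activity does not
#'     count), with `eps = eps_frac * k_max`;
#'   \item informatic asymmetry: mean reverse-transcription activity
#'     `k^C_{T,C} < eps` with mean transcription activity
#'     `k^C_{C,T} > ratio *` that value;
#'   \item numerical asymmetry: median per-cell minority frequency
#'     `< minority_threshold`.
#' }
#' The label is `"threefold"` for all three, `"catalytic_informatic_only"`
#' without the numerical one, `"incomplete"` for catalytic asymmetry
#' without informatic, `"none"` when there is no catalytic asymmetry and
#' both types stay highly active (`min(A_P, A_Q) > 0.5 k_max`), and
#' `"uncategorized"` otherwise.
#'
#' @param mean_k Named numeric vector of 8 window-averaged activities (in
#'   [k_entry_names()] order).
#' @param minority_median Median per-cell minority frequency over the
#'   window (see [minority_frequency()]).
#' @param k_max Upper activity bound.
#' @param eps_frac,ratio,minority_threshold Classifier thresholds.
#' @param window_len,min_window Length of the averaging window and the
#'   minimum acceptable length; a shorter window raises an error.
#' @return List of class `phase_class` with `label`, the role assignment
#'   and the asymmetry flags.
#' @export
classify_phase <- function(mean_k, minority_median, k_max = 1,
                           eps_frac = 0.05, ratio = 10,
                           minority_threshold = 0.4,
                           window_len = NULL, min_window = 0) {
  if (!is.null(window_len) && window_len < min_window)
    stop("analysis window too short: ", window_len, " < ", min_window)
  stopifnot(length(mean_k) == 8)
  if (!all(is.finite(mean_k)))
    stop("mean activities are not finite (no replicators in the window?)")
  names(mean_k) <- k_entry_names()
  eps <- eps_frac * k_max
  A <- c(P = mean(mean_k[1:4]), Q = mean(mean_k[5:8]))
  cat_type <- names(A)[which.max(A)]
  tmpl_type <- setdiff(c("P", "Q"), cat_type)
  A_C <- A[[cat_type]]; A_T <- A[[tmpl_type]]
  catalytic <- A_T < eps && A_C >= ratio * A_T && A_C > 2 * eps
  trans <- mean_k[[k_index(cat_type, cat_type, tmpl_type)]]
  revtrans <- mean_k[[k_index(cat_type, tmpl_type, cat_type)]]
  informatic <- revtrans < eps && trans > ratio * revtrans
  numerical <- is.finite(minority_median) &&
    minority_median < minority_threshold
  label <-
    if (catalytic && informatic && numerical) "threefold"
    else if (catalytic && informatic) "catalytic_informatic_only"
    else if (catalytic) "incomplete"
    else if (min(A) > 0.5 * k_max) "none"
    else "uncategorized"
  structure(list(label = label, catalyst_type = cat_type,
                 template_type = tmpl_type, A = A,
                 transcription = trans, reverse_transcription = revtrans,
                 minority_median = minority_median,
                 catalytic = catalytic, informatic = informatic,
                 numerical = numerical),
            class = "phase_class")
}

#' @export
print.phase_class <- function(x, ...) {
  cat(sprintf("<phase_class> %s (catalyst %s: A = %.3f; template %s: A = %.3f)\n",
              x$label, x$catalyst_type, x$A[[x$catalyst_type]],
              x$template_type, x$A[[x$template_type]]))
  invisible(x)
}

#' Classify the end state of a completed run
#'
#' Convenience wrapper: averages the trajectory of a [run_simulation()]
#' result over its final window and applies [classify_phase()].
#'
#' @param run A `replicell_run`.
#' @param window_frac Fraction of the run used as the averaging window.
#' @param ... Passed on to [classify_phase()].
#' @return A `phase_class` object.
#' @export
classify_run <- function(run, window_frac = 0.2, ...) {
  tr <- run$trajectory
  t1 <- max(tr$step)
  t0 <- t1 - window_frac * t1
  w <- tr[tr$step >= t0, ]
  mean_k <- colMeans(w[, k_entry_names(), drop = FALSE], na.rm = TRUE)
  minority <- median(w$minority_mean, na.rm = TRUE)
  classify_phase(mean_k, minority, k_max = run$params$k_max,
                 window_len = t1 - t0, ...)
}

#' Empirical per-template offspring rates from an event log
#'
#' Estimates, for each replicator appearing as a template in a window of
#' the birth log, its rates of producing P-type and Q-type offspring per
#' step -- an empirical counterpart of the rates entering
#' [reproductive_value()]. Diagnostics only; the normalized population
#' means of these rates sum to 1 by construction.
#'
#' @param births Birth event data frame (`step`, `rep_id`, `rtype`,
#'   `template_id`).
#' @param window `c(t0, t1)` step window.
#' @return Data frame with `template_id`, `omega_P`, `omega_Q`.
#' @export
empirical_omega <- function(births, window) {
  b <- births[births$step >= window[1] & births$step <= window[2], ]
  len <- window[2] - window[1] + 1
  tab <- table(b$template_id, factor(b$rtype, levels = c("P", "Q")))
  data.frame(template_id = as.integer(rownames(tab)),
             omega_P = as.numeric(tab[, "P"]) / len,
             omega_Q = as.numeric(tab[, "Q"]) / len)
}
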
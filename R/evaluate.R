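# Text-mining performance metrics over complexes: per-complex P_TM, the
# Delta-N comparison of two filtering algorithms, and aggregate coverage/
# success/accuracy statistics.

#' Per-complex text-mining performance
#'
#' For one protein-protein complex, with the mentions retained by some
#' filtering algorithm grouped by abstract,
#' `P_TM = sum_i N_i_int / sum_i (N_i_int + N_i_non)` over the abstracts
#' with at least one retained mention; an abstract whose residues were all
#' purged is excluded, and if every abstract is purged the value is
#' undefined (`NA`) and the complex drops out of the distribution.
#'
#' @param pool data.frame of retained mentions with columns `abstract_id`
#'   and `interface` (logical flag from the reference complex). Zero rows
#'   give `NA`.
#' @return Number in [0,1], or `NA`.
#' @export
ptm <- function(pool) {
  if (is.null(pool) || !nrow(pool)) return(NA_real_)
  stopifnot(all(c("abstract_id", "interface") %in% names(pool)))
  sum(pool$interface) / nrow(pool)
}

#' P_TM distribution of one filtering algorithm
#'
#' @param pools Named list of per-complex pools (see [ptm()]); names are
#'   complex ids.
#' @return Object of class `ptm_distribution`: data.frame with
#'   `complex_id`, `p_tm` (NA when undefined), `n_int`, `n_non`.
#' @export
ptm_distribution <- function(pools) {
  df <- data.frame(
    complex_id = names(pools),
    p_tm = vapply(pools, ptm, numeric(1)),
    n_int = vapply(pools, function(p) if (is.null(p)) 0L else sum(p$interface), integer(1)),
    n_non = vapply(pools, function(p) if (is.null(p)) 0L else sum(!p$interface), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("ptm_distribution", "data.frame")
  df
}

n_tar <- function(dist, p, tol = 1e-9) {
  v <- dist$p_tm
  sum(!is.na(v) & abs(v - p) <= tol)
}

#' Compare two filtering algorithms at a given P_TM value
#'
#' `Delta N(p) = N_X1(p) - N_X2(p)`, the difference in the number of
#' complexes whose P_TM equals `p` under each algorithm. The endpoints are
#' the informative values: complexes at P_TM = 0 carry only false
#' positives, complexes at P_TM = 1 only true positives, so an effective
#' filter has `Delta N(0) < 0` and `Delta N(1) > 0` against the baseline.
#' Complexes with undefined P_TM are excluded on both sides.
#'
#' @param dist_x1,dist_x2 [ptm_distribution()] objects over the same
#'   complex universe.
#' @param p P_TM value (exact endpoint counting).
#' @return Integer.
#' @export
delta_n <- function(dist_x1, dist_x2, p) {
  n_tar(dist_x1, p) - n_tar(dist_x2, p)
}

#' Histogram of a P_TM distribution
#'
#' Ten equal bins over [0,1] with right-closed edges (the first bin is
#' closed on both sides).
#'
#' @param dist A [ptm_distribution()].
#' @return Named integer vector of bin counts.
#' @export
ptm_histogram <- function(dist) {
  v <- dist$p_tm[!is.na(dist$p_tm)]
  br <- seq(0, 1, by = 0.1)
  table(cut(v, breaks = br, include.lowest = TRUE, right = TRUE))
}

#' Aggregate text-mining statistics over a complex set
#'
#' `L_tot` counts complexes for which at least one abstract retained a
#' residue; `L_int` counts complexes with at least one retained interface
#' residue. Coverage = L_tot / total complexes, success = L_int / total,
#' accuracy = L_int / L_tot (percent).
#'
#' @param pools Named list of per-complex pools (see [ptm()]).
#' @param total_complexes Total number of complexes attempted (>=
#'   `length(pools)`).
#' @return List with `l_tot`, `l_int`, `coverage`, `success`, `accuracy`
#'   (percentages; accuracy `NA` when `l_tot` is 0).
#' @export
aggregate_stats <- function(pools, total_complexes = length(pools)) {
  stopifnot(total_complexes >= length(pools))
  has_res <- vapply(pools, function(p) !is.null(p) && nrow(p) > 0L, logical(1))
  has_int <- vapply(pools, function(p) !is.null(p) && any(p$interface), logical(1))
  l_tot <- sum(has_res); l_int <- sum(has_int)
  list(l_tot = l_tot, l_int = l_int,
       coverage = 100 * l_tot / total_complexes,
       success = 100 * l_int / total_complexes,
       accuracy = if (l_tot > 0) 100 * l_int / l_tot else NA_real_)
}
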
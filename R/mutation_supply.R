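#' Cumulative cell divisions during binary-fission growth
#'
#' Number of cell divisions that occur while a population of `N0` cells
#' doubles for `g` generations: \eqn{N_0 (2^g - 1)} (each division creates
#' one new cell, so divisions equal the net cells produced).
#'
#' @param N0 Starting cell count (`>= 1`).
#' @param g Number of doubling generations (non-negative integer).
#' @return Number of divisions (numeric, exact for moderate sizes).
#' @examples
#' cumulative_divisions(5, 10)  # 5 * (2^10 - 1) = 5115
#' @export
cumulative_divisions <- function(N0, g) {
  stopifnot(is.numeric(N0), is.numeric(g))
  if (any(N0 < 1)) stop("`N0` must be >= 1", call. = FALSE)
  if (any(g < 0) || any(g != floor(g)))
    stop("`g` must be a non-negative integer", call. = FALSE)
  N0 * (2^g - 1)
}

#' Doubling generations needed to grow between two population sizes
#'
#' \eqn{\log_2(N_{final} / N_0)}, the (real-valued) number of binary-fission
#' generations required to expand from `N0` to `N_final` cells. The floored
#' integer is returned alongside for reporting ("~25 generations" style).
#'
#' @param N0 Starting cell count (`>= 1`).
#' @param N_final Final cell count (`>= N0`).
#' @return List with `generations` (real) and `floor` (integer).
#' @examples
#' generations_to_size(5, 2.4e8)  # ~25.5 generations; floor 25
#' @export
generations_to_size <- function(N0, N_final) {
  stopifnot(is.numeric(N0), is.numeric(N_final))
  if (any(N0 < 1)) stop("`N0` must be >= 1", call. = FALSE)
  if (any(N_final < N0))
    stop("`N_final` must be >= `N0`", call. = FALSE)
  g <- log2(N_final / N0)
  list(generations = g, floor = floor(g))
}

#' Mutation-supply parameter set for a focal locus
#'
#' Bundles the quantities needed to compute the expected number of
#' mutations hitting a focal locus during population expansion. The default
#' values are the study parameters for the \emph{binK} sensor-kinase locus
#' of \emph{Vibrio fischeri} MJ11: genomic mutation rate
#' \eqn{2.08 \times 10^{-8}} per bp per division, locus length 2595 bp with
#' roughly 2/3 of positions available for non-synonymous change, and
#' inoculum expansion from 5 to \eqn{2.4 \times 10^{8}} cells.
#'
#' @param mu Per-bp, per-cell-division mutation rate (`>= 0`).
#' @param locus_length_bp Locus length in bp (`>= 1`).
#' @param nonsyn_fraction Fraction of locus positions counted as available
#'   (in `(0, 1]`).
#' @param N0 Starting population size (`>= 1`).
#' @param N_final Final population size (`> N0`).
#' @return A validated list of class `"mutation_supply_params"`.
#' @export
mutation_supply_params <- function(mu = 2.08e-8,
                                   locus_length_bp = 2595,
                                   nonsyn_fraction = 2 / 3,
                                   N0 = 5,
                                   N_final = 2.4e8) {
  stopifnot(is.numeric(mu), is.numeric(locus_length_bp),
            is.numeric(nonsyn_fraction), is.numeric(N0), is.numeric(N_final))
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (locus_length_bp < 1 || locus_length_bp != floor(locus_length_bp))
    stop("`locus_length_bp` must be a positive integer", call. = FALSE)
  if (nonsyn_fraction <= 0 || nonsyn_fraction > 1)
    stop("`nonsyn_fraction` must lie in (0, 1]", call. = FALSE)
  if (N0 < 1) stop("`N0` must be >= 1", call. = FALSE)
  if (N_final <= N0) stop("`N_final` must exceed `N0`", call. = FALSE)
  structure(
    list(mu = mu, locus_length_bp = locus_length_bp,
         nonsyn_fraction = nonsyn_fraction, N0 = N0, N_final = N_final),
    class = "mutation_supply_params"
  )
}

#' Expected number of mutations in a focal locus
#'
#' \eqn{\lambda = \mu \times L \times f_{ns} \times D}: mutation rate per bp
#' per division, times available locus positions, times the number of cell
#' divisions `divisions`. Divisions are counted, not generations x N: for a
#' full expansion from `N0` to `N_final` cells, divisions
#' \eqn{\approx N_{final} - N_0}.
#'
#' @param params A [mutation_supply_params()] object.
#' @param divisions Number of cell divisions over which mutations can arise
#'   (`>= 0`); see [cumulative_divisions()].
#' @return Expected mutation count \eqn{\lambda}.
#' @export
expected_locus_mutations <- function(params, divisions) {
  stopifnot(inherits(params, "mutation_supply_params"), is.numeric(divisions))
  if (any(divisions < 0)) stop("`divisions` must be >= 0", call. = FALSE)
  params$mu * params$locus_length_bp * params$nonsyn_fraction * divisions
}

#' Poisson probability that at least one mutation arises
#'
#' \eqn{P(\ge 1) = 1 - e^{-\lambda}} for a Poisson-distributed mutation
#' count with mean `lambda`.
#'
#' @param lambda Expected mutation count (`>= 0`).
#' @return Probability in `[0, 1]`.
#' @export
prob_at_least_one <- function(lambda) {
  stopifnot(is.numeric(lambda))
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  -expm1(-lambda)
}

#' Mutation-supply summary for a population expansion
#'
#' Convenience wrapper reporting, for a [mutation_supply_params()]
#' configuration: the (real and floored) generations of expansion, the
#' cumulative divisions, the expected locus mutation count \eqn{\lambda}
#' over the whole expansion, and optionally \eqn{\lambda} and
#' \eqn{P(\ge 1)} restricted to the first `first_g` generations of growth.
#'
#' @param params A [mutation_supply_params()] object.
#' @param first_g Optional number of early generations for which to report
#'   the restricted mutation supply (e.g. 10 for "within the first 10
#'   generations of inoculum growth").
#' @return A list with elements `generations`, `generations_floor`,
#'   `divisions_total`, `lambda_total`, `p_any_total`, and when `first_g`
#'   is given also `divisions_first`, `lambda_first`, `p_any_first`.
#' @examples
#' mutation_supply(mutation_supply_params(), first_g = 10)
#' @export
mutation_supply <- function(params = mutation_supply_params(), first_g = NULL) {
  g <- generations_to_size(params$N0, params$N_final)
  div_total <- params$N_final - params$N0
  lam_total <- expected_locus_mutations(params, div_total)
  out <- list(
    generations = g$generations,
    generations_floor = g$floor,
    divisions_total = div_total,
    lambda_total = lam_total,
    p_any_total = prob_at_least_one(lam_total)
  )
  if (!is.null(first_g)) {
    div_first <- cumulative_divisions(params$N0, first_g)
    lam_first <- expected_locus_mutations(params, div_first)
    out$divisions_first <- div_first
    out$lambda_first <- lam_first
    out$p_any_first <- prob_at_least_one(lam_first)
  }
  out
}
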
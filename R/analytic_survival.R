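#' Survival probability of a rare beneficial mutant under periodic bottlenecks
#'
#' First-order (Wahl-Gerrish) approximation for the probability that a
#' beneficial mutant lineage, arising during the growth phase between two
#' periodic population bottlenecks, escapes stochastic loss. A population
#' doubles for `tau` generations and is then diluted back to its starting
#' size; a mutant with selection coefficient `s` (excess doubling exponent,
#' per-generation multiplication factor \eqn{2^{1+s}}) arising during
#' generation `t` survives with probability
#' \deqn{\pi(t, s) = \frac{s \, \tau \, \ln 2}{2^{t-1}},}
#' clamped to \eqn{[0, 1]}. The extinction probability is \eqn{V = 1 - \pi}.
#'
#' The approximation is first order in \eqn{s \tau \ln 2} and is accurate
#' only while that product is small; early-arising, strongly beneficial
#' mutants can push the raw value above 1, in which case it is clamped
#' (set `clamp = FALSE` to inspect the raw value). `t = 1` means the mutant
#' arises during the first generation of the growth phase, so `tau`
#' generations elapse before the bottleneck.
#'
#' @param t Generation of the growth phase in which the mutant arises
#'   (integer-valued, `1 <= t <= tau`). Vectorised.
#' @param s Selection coefficient (non-negative). Vectorised.
#' @param tau Number of generations of growth between successive bottlenecks
#'   (`tau >= 1`). In the squid light-organ system, `tau = 25` for the
#'   inoculum-growth/recruitment bottleneck and `tau = 4` for the daily
#'   venting bottlenecks.
#' @param clamp If `TRUE` (default), clamp the returned probability to
#'   `[0, 1]`; if `FALSE`, return the raw first-order value, which may
#'   exceed 1.
#' @return Numeric vector of survival probabilities.
#' @seealso [extinction_probability()], [required_selection_coefficient()],
#'   [survival_surface()], [mutant_fate_monte_carlo()] for the simulation
#'   cross-check.
#' @examples
#' # a strongly beneficial mutant (s = 2) arising at generation 10 of
#' # inoculum growth has < 10% chance of surviving host recruitment:
#' survival_probability(t = 10, s = 2, tau = 25)
#' @export
survival_probability <- function(t, s, tau, clamp = TRUE) {
  check_survival_query(t, s, tau)
  raw <- s * tau * log(2) / 2^(t - 1)
  if (clamp) pmin(pmax(raw, 0), 1) else raw
}

#' Extinction probability of a rare beneficial mutant
#'
#' Complement of [survival_probability()]: \eqn{V(t, s) = 1 - \pi(t, s)}.
#'
#' @inheritParams survival_probability
#' @return Numeric vector of extinction probabilities in `[0, 1]`.
#' @export
extinction_probability <- function(t, s, tau) {
  1 - survival_probability(t, s, tau, clamp = TRUE)
}

#' Selection coefficient required for a target survival probability
#'
#' Algebraic inverse of [survival_probability()]: the selection coefficient
#' at which a mutant arising at generation `t` attains (raw, unclamped)
#' survival probability `pi_target`,
#' \deqn{s = \pi \, 2^{t-1} / (\tau \ln 2).}
#'
#' @inheritParams survival_probability
#' @param pi_target Target survival probability, in `(0, 1]`.
#' @return Numeric vector of selection coefficients.
#' @examples
#' # selection needed for assured survival when arising at generation 8:
#' required_selection_coefficient(t = 8, pi_target = 1, tau = 25)
#' @export
required_selection_coefficient <- function(t, pi_target, tau) {
  stopifnot(is.numeric(t), is.numeric(pi_target), is.numeric(tau))
  if (any(t < 1) || any(t != floor(t)))
    stop("`t` must be a positive integer generation (t >= 1)", call. = FALSE)
  if (any(tau < 1) || any(tau != floor(tau)))
    stop("`tau` must be a positive integer number of generations", call. = FALSE)
  if (any(pi_target <= 0) || any(pi_target > 1))
    stop("`pi_target` must lie in (0, 1]", call. = FALSE)
  pi_target * 2^(t - 1) / (tau * log(2))
}

#' Survival-probability surface over origin generation and selection strength
#'
#' Evaluates [survival_probability()] on the grid `t_values` x `s_values`
#' for a fixed bottleneck regime, giving the survival surface of a new
#' beneficial mutant as a function of when it arises and how strongly it is
#' selected.
#'
#' @param t_values Origin generations (positive integers, each `<= tau`).
#' @param s_values Selection coefficients (non-negative).
#' @inheritParams survival_probability
#' @param label Free-text label for the bottleneck regime (e.g.
#'   `"recruitment"` or `"venting"`).
#' @return An object of class `"survival_surface"`: a list with elements
#'   `t_values`, `s_values`, `tau`, `label`, and `survival`, a
#'   `length(t_values)` x `length(s_values)` matrix with entries in
#'   `[0, 1]`. Convert with `as.data.frame()` (long format) or export with
#'   [write_surface()].
#' @examples
#' surf <- survival_surface(1:25, c(0.5, 1, 2, 6), tau = 25)
#' head(as.data.frame(surf))
#' @export
survival_surface <- function(t_values, s_values, tau, label = "recruitment") {
  if (length(t_values) == 0 || length(s_values) == 0)
    stop("`t_values` and `s_values` must be non-empty", call. = FALSE)
  check_survival_query(t_values, 0, tau)
  if (any(s_values < 0)) stop("`s_values` must be non-negative", call. = FALSE)
  surv <- outer(t_values, s_values,
                function(t, s) survival_probability(t, s, tau))
  dimnames(surv) <- list(t = format(t_values, trim = TRUE),
                         s = format(s_values, trim = TRUE))
  structure(
    list(t_values = t_values, s_values = s_values, tau = tau,
         label = label, survival = surv),
    class = "survival_surface"
  )
}

#' @export
as.data.frame.survival_surface <- function(x, ...) {
  data.frame(
    t = rep(x$t_values, times = length(x$s_values)),
    s = rep(x$s_values, each = length(x$t_values)),
    survival = as.vector(x$survival)
  )
}

#' @export
print.survival_surface <- function(x, ...) {
  cat(sprintf(
    "Mutant survival surface (tau = %d, %s bottleneck): %d origin generations x %d selection coefficients\n",
    x$tau, x$label, length(x$t_values), length(x$s_values)))
  cat(sprintf("  survival range: %.4g - %.4g\n",
              min(x$survival), max(x$survival)))
  invisible(x)
}

# shared domain validation for (t, s, tau) survival queries
check_survival_query <- function(t, s, tau) {
  stopifnot(is.numeric(t), is.numeric(s), is.numeric(tau))
  if (any(tau < 1) || any(tau != floor(tau)))
    stop("`tau` must be a positive integer number of generations", call. = FALSE)
  if (any(t < 1) || any(t != floor(t)))
    stop("`t` must be a positive integer generation (t >= 1)", call. = FALSE)
  if (any(t > tau))
    stop("`t` must not exceed `tau` (mutant must arise before the bottleneck)",
         call. = FALSE)
  if (any(s < 0))
    stop("`s` must be non-negative", call. = FALSE)
  invisible(TRUE)
}
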
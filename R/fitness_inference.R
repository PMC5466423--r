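#' Malthusian parameter of a lineage over a competition interval
#'
#' Natural log of the ratio of final to starting abundance,
#' \eqn{M = \ln(n_{end}/n_{start})}. May be negative for a declining
#' lineage. Both abundances must be strictly positive; zero or negative
#' abundances are a domain error (handle zero colony counts upstream via
#' the detection-floor censoring in [estimate_selection()]).
#'
#' @param n_end Final abundance (`> 0`). Vectorised.
#' @param n_start Starting abundance (`> 0`). Vectorised.
#' @return Malthusian parameter(s) in natural-log units.
#' @examples
#' malthusian(1, 325)        # a rare lineage: ln(1/325)
#' malthusian(9, 2.4e8)      # wild-type through a severe bottleneck
#' @export
malthusian <- function(n_end, n_start) {
  stopifnot(is.numeric(n_end), is.numeric(n_start))
  if (any(n_end <= 0) || any(n_start <= 0))
    stop("Malthusian parameter undefined: abundances must be > 0 ",
         "(censor zero counts at the detection floor first)", call. = FALSE)
  log(n_end / n_start)
}

#' Selection rate from two Malthusian parameters
#'
#' \eqn{r = M_{focal} - M_{reference}}, the difference of Malthusian
#' parameters (natural-log units) used to compare fitness when one or both
#' lineages decline over the interval.
#'
#' @param M_focal,M_reference Malthusian parameters.
#' @return Selection rate `r` in natural logs.
#' @export
selection_rate <- function(M_focal, M_reference) {
  stopifnot(is.numeric(M_focal), is.numeric(M_reference))
  M_focal - M_reference
}

#' Convert selection coefficients between estimator and simulator scales
#'
#' The competition estimator reports \eqn{s = s_{GR}/\ln 2} where
#' \eqn{s_{GR}} is the relative growth-rate difference; the simulator (and
#' the analytic survival approximation) uses the excess doubling exponent
#' convention, per-generation factor \eqn{2^{1+s_{sim}}}. With both
#' competitors growing for the same number of generations from their
#' founder abundances, \eqn{s_{GR} = s_{sim}}, so the scales differ by the
#' factor \eqn{\ln 2}.
#'
#' @param s Selection coefficient(s) on the source scale.
#' @return The coefficient(s) on the target scale.
#' @export
estimator_to_simulator_s <- function(s) s * log(2)

#' @rdname estimator_to_simulator_s
#' @export
simulator_to_estimator_s <- function(s) s / log(2)

# expected observation-table columns (the unit of fitness estimation:
# one co-colonized host's paired colony counts plus inoculum composition)
observation_columns <- function() {
  c("host_id", "timepoint_hr", "count_evolved", "count_ancestor",
    "dilution_factor", "inoculum_density", "inoculum_frequency_evolved",
    "marker_orientation")
}

validate_observations <- function(obs, where = "observations") {
  if (!is.data.frame(obs))
    stop(sprintf("`%s` must be a data frame", where), call. = FALSE)
  missing <- setdiff(observation_columns(), names(obs))
  if (length(missing) > 0)
    stop(sprintf("`%s` is missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  num_cols <- c("count_evolved", "count_ancestor", "dilution_factor",
                "inoculum_density", "inoculum_frequency_evolved")
  for (cl in num_cols) {
    v <- obs[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop(sprintf("column `%s` must be numeric (check row %s)",
                   cl, paste(utils::head(bad, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad <- which(obs$count_evolved < 0 | obs$count_ancestor < 0)
  if (length(bad) > 0)
    stop(sprintf("negative colony count in row %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  bad <- which(obs$inoculum_frequency_evolved <= 0 |
                 obs$inoculum_frequency_evolved >= 1)
  if (length(bad) > 0)
    stop(sprintf("inoculum_frequency_evolved must lie in (0, 1): row %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  bad <- which(obs$inoculum_density <= 0 | obs$dilution_factor <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive density/dilution in row %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  invisible(obs)
}

#' Selection-coefficient estimates from marked-strain competition counts
#'
#' For each co-colonized host: per-strain starting abundances are the
#' inoculum density times the strain's inoculum frequency; per-strain
#' final abundances are the recovered colony counts times the plating
#' dilution factor. Malthusian parameters \eqn{M = \ln(end/start)} for each
#' competitor give the relative growth-rate difference
#' \deqn{s_{GR} = (M_{Evo} - M_{Anc}) / M_{Anc}} and the selection
#' coefficient \eqn{s = s_{GR} / \ln 2}.
#'
#' A competitor recovered with zero colonies is censored at the plating
#' detection floor (~15 CFU) rather than dropped, and the row is flagged
#' `censored`; this keeps rare-variant hosts in the data set instead of
#' biasing toward co-recovery. Rows where \eqn{M_{Anc} = 0} (undefined
#' \eqn{s_{GR}}) or where both strains are undetected are flagged invalid.
#'
#' @param obs Data frame of competition observations with columns
#'   `host_id`, `timepoint_hr`, `count_evolved`, `count_ancestor`,
#'   `dilution_factor`, `inoculum_density`, `inoculum_frequency_evolved`,
#'   `marker_orientation` (see [read_observations()]).
#' @param detection_floor Abundance assigned to a zero-count competitor
#'   (CFU; default 15, the plating detection limit).
#' @return Data frame: one row per observation with `host_id`,
#'   `timepoint_hr`, `inoculum_frequency_evolved`, `inoculum_density`,
#'   `M_evolved`, `M_ancestor`, `s_GR`, `s`, `censored`, `valid`.
#' @export
estimate_selection <- function(obs, detection_floor = 15) {
  validate_observations(obs, "obs")
  end_e <- obs$count_evolved * obs$dilution_factor
  end_a <- obs$count_ancestor * obs$dilution_factor
  censored <- obs$count_evolved == 0 | obs$count_ancestor == 0
  valid <- !(obs$count_evolved == 0 & obs$count_ancestor == 0)
  end_e[obs$count_evolved == 0] <- detection_floor
  end_a[obs$count_ancestor == 0] <- detection_floor
  start_e <- obs$inoculum_density * obs$inoculum_frequency_evolved
  start_a <- obs$inoculum_density * (1 - obs$inoculum_frequency_evolved)

  M_e <- M_a <- s_GR <- rep(NA_real_, nrow(obs))
  ok <- valid
  M_e[ok] <- malthusian(end_e[ok], start_e[ok])
  M_a[ok] <- malthusian(end_a[ok], start_a[ok])
  zero_anc <- ok & M_a == 0
  valid[zero_anc] <- FALSE           # s_GR undefined when M_Anc = 0
  use <- valid
  s_GR[use] <- (M_e[use] - M_a[use]) / M_a[use]
  data.frame(
    host_id = obs$host_id,
    timepoint_hr = obs$timepoint_hr,
    inoculum_frequency_evolved = obs$inoculum_frequency_evolved,
    inoculum_density = obs$inoculum_density,
    M_evolved = M_e, M_ancestor = M_a,
    s_GR = s_GR, s = s_GR / log(2),
    censored = censored, valid = valid,
    stringsAsFactors = FALSE
  )
}

# bias-corrected percentile bootstrap CI for a mean
bc_bootstrap_ci <- function(x, n_boot = 1e4, conf = 0.95) {
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  obs <- mean(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boots <- rowMeans(matrix(x[idx], nrow = n_boot))
  prop_below <- mean(boots < obs)
  if (prop_below == 0 || prop_below == 1) {       # degenerate resampling
    return(unname(stats::quantile(boots, c((1 - conf) / 2,
                                           1 - (1 - conf) / 2))))
  }
  z0 <- stats::qnorm(prop_below)
  zc <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  probs <- stats::pnorm(2 * z0 + zc)
  unname(stats::quantile(boots, probs))
}

#' Summarise a competition experiment: per-timepoint selection estimates
#'
#' Computes per-host selection-coefficient estimates
#' ([estimate_selection()]), then per timepoint the number of valid
#' uncensored estimates, the mean `s`, and a bias-corrected percentile
#' bootstrap confidence interval for the mean. If two or more timepoints
#' have data, adjacent timepoints are compared with the exact Fisher-Pitman
#' permutation test ([fisher_pitman_test()]). A hard-selection diagnostic
#' regresses `s` on starting evolved frequency: under hard selection
#' (fitness advantage independent of starting frequency) the slope's
#' confidence interval covers zero.
#'
#' @inheritParams estimate_selection
#' @param n_boot Bootstrap resamples for the CI of the mean (default 1e4).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed (bootstrap and Monte-Carlo fallback).
#' @param use_censored Include censored (detection-floor) estimates in the
#'   summaries (default `FALSE`).
#' @return An object of class `"competition_summary"`: list with
#'   `estimates` (per-host data frame), `by_timepoint` (data frame:
#'   timepoint_hr, n, mean_s, ci_lower, ci_upper, degenerate flag),
#'   `timepoint_test` ([fisher_pitman_test()] result or `NULL`),
#'   `frequency_diagnostic` (list: slope, ci, covers_zero) or `NULL`.
#' @export
summarize_experiment <- function(obs, detection_floor = 15, n_boot = 1e4,
                                 conf = 0.95, seed = NULL,
                                 use_censored = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  est <- estimate_selection(obs, detection_floor)
  keep <- est$valid & (use_censored | !est$censored) & is.finite(est$s)
  used <- est[keep, , drop = FALSE]
  tps <- sort(unique(est$timepoint_hr))
  by_tp <- do.call(rbind, lapply(tps, function(tp) {
    x <- used$s[used$timepoint_hr == tp]
    ci <- bc_bootstrap_ci(x, n_boot, conf)
    data.frame(timepoint_hr = tp, n = length(x),
               mean_s = if (length(x) > 0) mean(x) else NA_real_,
               ci_lower = ci[1], ci_upper = ci[2],
               degenerate = length(x) < 2)
  }))

  tp_test <- NULL
  with_data <- by_tp$timepoint_hr[by_tp$n > 0]
  if (length(with_data) >= 2) {
    a <- used$s[used$timepoint_hr == with_data[1]]
    b <- used$s[used$timepoint_hr == with_data[2]]
    tp_test <- fisher_pitman_test(a, b)
  }

  freq_diag <- NULL
  if (nrow(used) >= 3 &&
      length(unique(used$inoculum_frequency_evolved)) >= 2) {
    fit <- stats::lm(s ~ inoculum_frequency_evolved, data = used)
    ci <- stats::confint(fit, "inoculum_frequency_evolved", level = conf)
    freq_diag <- list(slope = unname(stats::coef(fit)[2]),
                      ci = as.numeric(ci),
                      covers_zero = ci[1] <= 0 && ci[2] >= 0)
  }

  structure(
    list(estimates = est, by_timepoint = by_tp, timepoint_test = tp_test,
         frequency_diagnostic = freq_diag),
    class = "competition_summary"
  )
}

#' @export
print.competition_summary <- function(x, ...) {
  cat("Competition experiment summary\n")
  for (i in seq_len(nrow(x$by_timepoint))) {
    r <- x$by_timepoint[i, ]
    cat(sprintf("  %g hr: n = %d, mean s = %.3f [%.3f, %.3f]%s\n",
                r$timepoint_hr, r$n, r$mean_s, r$ci_lower, r$ci_upper,
                if (isTRUE(r$degenerate)) " (degenerate CI)" else ""))
  }
  if (!is.null(x$timepoint_test))
    cat(sprintf("  between-timepoint Fisher-Pitman p = %.4g\n",
                x$timepoint_test$p_value))
  if (!is.null(x$frequency_diagnostic))
    cat(sprintf("  hard-selection diagnostic: slope %.3g [%.3g, %.3g]%s\n",
                x$frequency_diagnostic$slope, x$frequency_diagnostic$ci[1],
                x$frequency_diagnostic$ci[2],
                if (x$frequency_diagnostic$covers_zero)
                  " (consistent with hard selection)" else ""))
  invisible(x)
}
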
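#' Simulated dilution-plating colony counts
#'
#' Emulates plating of a homogenate: the observed colony count is
#' Poisson-distributed with mean `true_abundance / dilution_factor`
#' (optionally negative-binomial with dispersion `dispersion`, since real
#' plate counts overdisperse). The implied abundance (count x dilution) is
#' compared against the plating detection floor (~15 CFU) and flagged when
#' below it.
#'
#' @param true_abundance True abundance(s), CFU (`>= 0`). Vectorised.
#' @param dilution_factor Plating dilution factor (`> 0`).
#' @param detection_floor Minimum detectable abundance (CFU).
#' @param dispersion Optional negative-binomial dispersion (`> 0`; the
#'   count variance is `mu + dispersion * mu^2`). `NULL` for pure Poisson.
#' @param seed Optional integer seed.
#' @return Data frame with `count`, `estimated_abundance`,
#'   `below_detection`.
#' @export
plate_counts <- function(true_abundance, dilution_factor = 1,
                         detection_floor = 15, dispersion = NULL,
                         seed = NULL) {
  stopifnot(is.numeric(true_abundance), is.numeric(dilution_factor))
  if (any(true_abundance < 0))
    stop("`true_abundance` must be >= 0", call. = FALSE)
  if (dilution_factor <= 0)
    stop("`dilution_factor` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- true_abundance / dilution_factor
  count <- if (is.null(dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stopifnot(dispersion > 0)
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  est <- count * dilution_factor
  data.frame(count = count,
             estimated_abundance = est,
             below_detection = est < detection_floor)
}

#' Configuration for a synthetic competition experiment
#'
#' Ground-truth generator settings emulating co-inoculation competition
#' assays in squid: hosts are founded by a small recruited population drawn
#' from an inoculum of known density and evolved-strain frequency, grown in
#' the light organ (to carrying capacity, with daily venting for the later
#' timepoint), and the final population is plated for both colony markers.
#' Defaults mirror the study conditions: founder size 12, capacity
#' \eqn{5\times 10^{5}}, 5% venting survival, inoculum densities 1,600 -
#' 26,600 CFU/mL, evolved frequencies from \eqn{10^{-4}} to 0.5, and a
#' 15-CFU plating detection floor. The 24-hr timepoint is recruitment plus
#' growth to capacity; 48 hr adds one vent/regrow cycle.
#'
#' @param s_true True selection coefficient of the evolved genotype
#'   (simulator scale, per-generation factor \eqn{2^{1+s}}).
#' @param n_hosts Hosts per timepoint.
#' @param timepoints Assay timepoints in hours (24 and/or 48; 24 maps to
#'   one growth phase, 48 adds one vent/regrow cycle).
#' @param founder_size Recruited founder cells per host.
#' @param carrying_capacity Light-organ capacity.
#' @param venting_survival Fraction retained at venting, in `(0, 1)`.
#' @param density_range Range (CFU/mL) from which per-host inoculum
#'   densities are drawn uniformly; or supply `densities`.
#' @param frequency_range Range from which per-host evolved frequencies are
#'   drawn log-uniformly; or supply `frequencies`.
#' @param densities,frequencies Optional explicit per-host values
#'   (recycled).
#' @param dilution_factor Plating dilution factor.
#' @param detection_floor Plating detection floor (CFU).
#' @param growth_generations If given, each growth phase runs exactly this
#'   many doubling generations with no carrying-capacity truncation
#'   (calibration-style cohorts); default `NULL` grows to capacity.
#' @param noise If `FALSE`, growth is deterministic, founders are the
#'   rounded expected composition, plating is exact, and the recorded
#'   inoculum composition is the realized founder composition (so that the
#'   estimator's only error is algebraic). Default `TRUE`: binomial
#'   founder sampling, stochastic growth, Poisson plating.
#' @param condition_on_cocolonization If `TRUE`, founder draws are repeated
#'   until both strains are represented (mirrors analysing only
#'   co-colonized hosts).
#' @param dispersion Optional negative-binomial plating dispersion.
#' @return A validated list of class `"competition_config"`.
#' @export
competition_config <- function(s_true = 0.25,
                               n_hosts = 50,
                               timepoints = c(24, 48),
                               founder_size = 12,
                               carrying_capacity = 5e5,
                               venting_survival = 0.05,
                               density_range = c(1600, 26600),
                               frequency_range = c(1e-4, 0.5),
                               densities = NULL,
                               frequencies = NULL,
                               dilution_factor = 100,
                               detection_floor = 15,
                               growth_generations = NULL,
                               noise = TRUE,
                               condition_on_cocolonization = FALSE,
                               dispersion = NULL) {
  stopifnot(is.numeric(s_true), is.numeric(n_hosts),
            is.numeric(founder_size), is.numeric(carrying_capacity))
  if (n_hosts < 1) stop("`n_hosts` must be >= 1", call. = FALSE)
  if (founder_size < 2)
    stop("`founder_size` must be >= 2 (both strains must be samplable)",
         call. = FALSE)
  if (founder_size > carrying_capacity)
    stop("`founder_size` cannot exceed `carrying_capacity`", call. = FALSE)
  if (venting_survival <= 0 || venting_survival >= 1)
    stop("`venting_survival` must lie in (0, 1)", call. = FALSE)
  if (!all(timepoints %in% c(24, 48)))
    stop("`timepoints` must be drawn from {24, 48}", call. = FALSE)
  structure(
    list(s_true = s_true, n_hosts = n_hosts, timepoints = timepoints,
         founder_size = founder_size, carrying_capacity = carrying_capacity,
         venting_survival = venting_survival, density_range = density_range,
         frequency_range = frequency_range, densities = densities,
         frequencies = frequencies, dilution_factor = dilution_factor,
         detection_floor = detection_floor,
         growth_generations = growth_generations, noise = noise,
         condition_on_cocolonization = condition_on_cocolonization,
         dispersion = dispersion),
    class = "competition_config"
  )
}

# grow a two-strain founder population through n_cycles host cycles;
# returns c(end_ancestor, end_evolved) true abundances
grow_competition <- function(n_anc, n_evo, config, n_cycles,
                             deterministic) {
  counts <- c(anc = n_anc, evo = n_evo)
  genotypes <- data.frame(
    id = c("anc", "evo"), s = c(0, config$s_true),
    parent_id = c(NA_character_, "anc"), origin_generation = c(0L, 0L),
    stringsAsFactors = FALSE)
  state <- population_state(counts, genotypes, phase = "host")
  for (cy in seq_len(n_cycles)) {
    if (cy > 1) {
      if (deterministic) {
        state <- population_state(state$counts * config$venting_survival,
                                  state$genotypes, state$generation, "host")
      } else {
        state <- apply_fractional_bottleneck(state, config$venting_survival)
      }
      if (total_count(state) == 0) break
    }
    if (is.null(config$growth_generations)) {
      state <- grow_to_capacity(state, config$carrying_capacity,
                                mutation_params(),
                                deterministic = deterministic)
    } else {
      for (g in seq_len(config$growth_generations))
        state <- grow_one_generation(state, mutation_params(),
                                     deterministic = deterministic)
    }
  }
  c(anc = unname(state$counts["anc"]), evo = unname(state$counts["evo"]))
}

#' Generate a synthetic competition experiment with known ground truth
#'
#' For each host and timepoint: draws an inoculum density and evolved-strain
#' frequency, samples the recruited founder population binomially from the
#' inoculum composition, grows the two-strain population through the
#' requested host cycles with the evolved genotype at `s_true`, and plates
#' the final population for both markers. Returns an observation table in
#' the exact schema consumed by [estimate_selection()] /
#' [read_observations()], plus a hidden ground-truth table including the
#' per-host deterministic-expectation selection estimate (the value the
#' estimator would return for the realized founders absent growth and
#' plating noise).
#'
#' Some hosts may contain zero evolved founders (as in rare-variant
#' inoculations); their observations are still emitted unless
#' `condition_on_cocolonization` is set in the config.
#'
#' @param config A [competition_config()].
#' @param seed Optional integer seed.
#' @return List with `observations` (data frame, observation schema) and
#'   `ground_truth` (data frame: host_id, timepoint_hr, density, frequency,
#'   founder counts, true end abundances, `s_true`, `s_expected`).
#' @export
generate_competition_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "competition_config"))
  if (!is.null(seed)) set.seed(seed)
  obs_rows <- list()
  truth_rows <- list()
  host_counter <- 0L

  for (tp in config$timepoints) {
    n_cycles <- if (tp == 24) 1L else 2L
    for (h in seq_len(config$n_hosts)) {
      host_counter <- host_counter + 1L
      host_id <- sprintf("host_%03d", host_counter)

      density <- if (!is.null(config$densities)) {
        config$densities[((h - 1L) %% length(config$densities)) + 1L]
      } else {
        stats::runif(1, config$density_range[1], config$density_range[2])
      }
      freq <- if (!is.null(config$frequencies)) {
        config$frequencies[((h - 1L) %% length(config$frequencies)) + 1L]
      } else {
        exp(stats::runif(1, log(config$frequency_range[1]),
                         log(config$frequency_range[2])))
      }

      if (config$noise) {
        repeat {
          n_evo <- stats::rbinom(1L, config$founder_size, freq)
          n_anc <- config$founder_size - n_evo
          if (!config$condition_on_cocolonization ||
              (n_evo >= 1 && n_anc >= 1)) break
        }
      } else {
        n_evo <- round(freq * config$founder_size)
        n_anc <- config$founder_size - n_evo
        if (n_evo < 1 || n_anc < 1)
          stop("noiseless mode requires a frequency giving both strains >= 1 founder",
               call. = FALSE)
      }

      ends <- if (n_evo + n_anc > 0) {
        grow_competition(n_anc, n_evo, config, n_cycles,
                         deterministic = !config$noise)
      } else c(anc = 0, evo = 0)

      # deterministic twin: expectation of the estimator for these founders
      dens_used <- if (config$noise) density else config$founder_size
      freq_used <- if (config$noise) freq else n_evo / config$founder_size
      s_expected <- NA_real_
      if (n_evo >= 1 && n_anc >= 1) {
        det_ends <- if (config$noise) {
          grow_competition(n_anc, n_evo, config, n_cycles,
                           deterministic = TRUE)
        } else ends
        if (all(det_ends > 0)) {
          M_e <- malthusian(det_ends[["evo"]], dens_used * freq_used)
          M_a <- malthusian(det_ends[["anc"]], dens_used * (1 - freq_used))
          if (M_a != 0) s_expected <- (M_e - M_a) / M_a / log(2)
        }
      }

      if (config$noise) {
        plated_a <- plate_counts(ends[["anc"]], config$dilution_factor,
                                 config$detection_floor, config$dispersion)
        plated_e <- plate_counts(ends[["evo"]], config$dilution_factor,
                                 config$detection_floor, config$dispersion)
        count_a <- plated_a$count
        count_e <- plated_e$count
      } else {
        count_a <- ends[["anc"]] / config$dilution_factor
        count_e <- ends[["evo"]] / config$dilution_factor
      }

      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        host_id = host_id, timepoint_hr = tp,
        count_evolved = count_e, count_ancestor = count_a,
        dilution_factor = config$dilution_factor,
        inoculum_density = dens_used,
        inoculum_frequency_evolved = freq_used,
        marker_orientation = if (host_counter %% 2L == 0L)
          "evolved_blue" else "evolved_white",
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        host_id = host_id, timepoint_hr = tp,
        inoculum_density = dens_used,
        inoculum_frequency_evolved = freq_used,
        n_founder_evolved = n_evo, n_founder_ancestor = n_anc,
        true_end_evolved = ends[["evo"]], true_end_ancestor = ends[["anc"]],
        s_true = config$s_true, s_expected = s_expected,
        stringsAsFactors = FALSE)
    }
  }
  list(observations = do.call(rbind, obs_rows),
       ground_truth = do.call(rbind, truth_rows))
}

#' Generate per-lineage outcomes of replicate passage series
#'
#' Runs `n_lineages` independent serial-passage simulations
#' ([run_passage_series()]) and tabulates each lineage's outcome: whether
#' the series completed or went extinct (and at which passage), how many
#' focal-locus variants arose, and whether any variant was detected
#' (segregating) or fixed at the end of the series. Mirrors the bookkeeping
#' of parallel squid lineages scored for symbiont survival and convergent
#' sweeps.
#'
#' @param scheme A [passage_scheme()].
#' @param mut A [mutation_params()].
#' @param n_lineages Number of independent replicate series (`>= 1`).
#' @param seed Optional integer seed (per-lineage seeds are derived from
#'   it).
#' @param seed_mutant Optional `list(t =, s =, count =)` forwarded to
#'   [run_passage_series()] (mutant-fate experiments).
#' @param ... Further arguments passed to [run_passage_series()].
#' @return Data frame with one row per lineage: `lineage`, `status`,
#'   `extinct_at_passage` (`NA` if completed), `n_variants`,
#'   `variant_detected`, `variant_fixed`, `max_variant_freq`.
#' @export
generate_passage_dataset <- function(scheme = passage_scheme(),
                                     mut = mutation_params(),
                                     n_lineages = 10,
                                     seed = NULL,
                                     seed_mutant = NULL,
                                     ...) {
  stopifnot(n_lineages >= 1)
  if (!is.null(seed)) set.seed(seed)
  lineage_seeds <- sample.int(.Machine$integer.max, n_lineages)
  rows <- lapply(seq_len(n_lineages), function(i) {
    res <- run_passage_series(scheme, mut, seed = lineage_seeds[i],
                              seed_mutant = seed_mutant, ...)
    variant_ids <- setdiff(res$genotypes$id, "0")
    freqs <- genotype_frequencies(res$final_state)
    vfreq <- freqs[names(freqs) %in% variant_ids]
    max_vf <- if (length(vfreq) > 0 && total_count(res$final_state) > 0)
      max(vfreq) else 0
    ext_at <- if (grepl("^extinct_at_passage_", res$status))
      as.integer(sub("^extinct_at_passage_", "", res$status)) else NA_integer_
    data.frame(
      lineage = i, status = res$status, extinct_at_passage = ext_at,
      n_variants = length(variant_ids),
      variant_detected = any(res$fates[variant_ids] != "extinct"),
      variant_fixed = any(res$fates[variant_ids] == "fixed"),
      max_variant_freq = max_vf,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
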
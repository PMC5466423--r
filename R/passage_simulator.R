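#' Growth/bottleneck scheme for one serial-passage evolution experiment
#'
#' Describes the regime a symbiont population experiences during one squid
#' passage series: growth of the inoculum culture, recruitment of a small
#' founder population into the juvenile light organ, daily venting of ~95%
#' of the light-organ population at dawn followed by regrowth to capacity,
#' and serial transfer of the ventate to the next host.
#'
#' Defaults are the study conditions of the squid-\emph{Vibrio} system:
#' inoculum expansion from 5 to \eqn{2.4\times 10^{8}} cells, a founder
#' population of 12 cells (2-3 per crypt), light-organ carrying capacity
#' \eqn{5\times 10^{5}} cells, 5% of the population retained at each dawn
#' venting, and 15 hosts in series. `tau_recruitment = 25` and
#' `tau_venting = 4` are the nominal generations of growth preceding the
#' two bottleneck types.
#'
#' @param N0 Inoculum starting cell count.
#' @param N_inoc Inoculum population size at the end of culture growth.
#' @param recruitment_size Founder cells recruited per host.
#' @param carrying_capacity Maximum light-organ population.
#' @param venting_survival Fraction of the light-organ population retained
#'   at dawn venting (in `(0, 1)`).
#' @param cycles_per_host Vent/regrow cycles per host.
#' @param n_hosts Number of hosts passaged in series.
#' @param tau_recruitment,tau_venting Nominal generations of growth between
#'   the respective bottlenecks.
#' @return A validated list of class `"passage_scheme"`.
#' @export
passage_scheme <- function(N0 = 5,
                           N_inoc = 2.4e8,
                           recruitment_size = 12,
                           carrying_capacity = 5e5,
                           venting_survival = 0.05,
                           cycles_per_host = 2,
                           n_hosts = 15,
                           tau_recruitment = 25,
                           tau_venting = 4) {
  stopifnot(is.numeric(N0), is.numeric(N_inoc), is.numeric(recruitment_size),
            is.numeric(carrying_capacity), is.numeric(venting_survival),
            is.numeric(cycles_per_host), is.numeric(n_hosts))
  if (N0 < 1) stop("`N0` must be >= 1", call. = FALSE)
  if (N_inoc <= N0) stop("`N_inoc` must exceed `N0`", call. = FALSE)
  if (recruitment_size < 1)
    stop("`recruitment_size` must be >= 1", call. = FALSE)
  if (carrying_capacity < recruitment_size)
    stop("`carrying_capacity` must be >= `recruitment_size`", call. = FALSE)
  if (venting_survival <= 0 || venting_survival >= 1)
    stop("`venting_survival` must lie in (0, 1)", call. = FALSE)
  if (cycles_per_host < 1) stop("`cycles_per_host` must be >= 1", call. = FALSE)
  if (n_hosts < 0) stop("`n_hosts` must be >= 0", call. = FALSE)
  structure(
    list(N0 = N0, N_inoc = N_inoc, recruitment_size = recruitment_size,
         carrying_capacity = carrying_capacity,
         venting_survival = venting_survival,
         cycles_per_host = cycles_per_host, n_hosts = n_hosts,
         tau_recruitment = tau_recruitment, tau_venting = tau_venting),
    class = "passage_scheme"
  )
}

#' Mutation parameters for the focal beneficial class
#'
#' @param mu_locus Per-cell-division mutation rate to the focal beneficial
#'   class (`>= 0`). Obtain from genomic rate and target size via
#'   [expected_locus_mutations()] reasoning (rate x locus bp x available
#'   fraction).
#' @param s_new Selection coefficient (simulator scale: per-generation
#'   factor \eqn{2^{1+s}}) assigned to newly arisen mutants.
#' @return A validated list of class `"mutation_params"`.
#' @export
mutation_params <- function(mu_locus = 0, s_new = 0) {
  stopifnot(is.numeric(mu_locus), is.numeric(s_new))
  if (mu_locus < 0) stop("`mu_locus` must be >= 0", call. = FALSE)
  structure(list(mu_locus = mu_locus, s_new = s_new),
            class = "mutation_params")
}

#' Lineage-resolved population state
#'
#' A population is a set of genotype lineages with integer cell counts, a
#' genotype table carrying each lineage's selection coefficient and
#' ancestry, a generation counter, and a phase label.
#'
#' @param counts Named numeric vector of non-negative cell counts; names
#'   are genotype ids.
#' @param genotypes Data frame with columns `id`, `s`, `parent_id`,
#'   `origin_generation`; one row per genotype in `counts`. Defaults to a
#'   single ancestral genotype `"0"` with `s = 0`.
#' @param generation Generation counter (`>= 0`).
#' @param phase `"inoculum"` or `"host"`.
#' @return An object of class `"population_state"`.
#' @examples
#' population_state(c(`0` = 5))
#' @export
population_state <- function(counts,
                             genotypes = NULL,
                             generation = 0L,
                             phase = c("inoculum", "host")) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(counts))
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("`counts` must have unique genotype-id names", call. = FALSE)
  if (any(counts < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (is.null(genotypes)) {
    genotypes <- data.frame(id = names(counts),
                            s = 0,
                            parent_id = NA_character_,
                            origin_generation = 0L,
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(genotypes),
            all(c("id", "s", "parent_id", "origin_generation") %in%
                  names(genotypes)))
  if (anyDuplicated(genotypes$id))
    stop("genotype ids must be unique", call. = FALSE)
  if (!all(names(counts) %in% genotypes$id))
    stop("every counted genotype must appear in the genotype table",
         call. = FALSE)
  structure(
    list(counts = counts, genotypes = genotypes,
         generation = as.integer(generation), phase = phase),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d genotype(s), total %.4g cells, generation %d (%s phase)\n",
              length(x$counts), sum(x$counts), x$generation, x$phase))
  invisible(x)
}

#' Total cell count of a population state
#' @param state A [population_state()].
#' @return Total number of cells.
#' @export
total_count <- function(state) {
  stopifnot(inherits(state, "population_state"))
  sum(state$counts)
}

#' Genotype frequencies of a population state
#' @param state A [population_state()].
#' @return Named numeric vector of frequencies (empty-population states
#'   return all-`NaN`).
#' @export
genotype_frequencies <- function(state) {
  stopifnot(inherits(state, "population_state"))
  state$counts / sum(state$counts)
}

# Minimal-variance stochastic rounding: floor(x) + Bernoulli(frac(x)).
# Preserves expectation; adds at most Bernoulli variance per lineage, so
# bottleneck binomial sampling remains the dominant noise source (the
# regime assumed by the analytic survival approximation).
stochastic_round <- function(x) {
  fl <- floor(x)
  fr <- x - fl
  fl + (stats::runif(length(x)) < fr)
}

#' Advance a population by one generation of binary-fission growth
#'
#' Each genotype with selection coefficient `s` multiplies by
#' \eqn{2^{1+s}} per generation (the ancestral `s = 0` class exactly
#' doubles). Non-integer expected counts are realised by stochastic
#' rounding (floor plus a Bernoulli draw on the fractional part) so that
#' expectations are preserved with minimal added variance. Lineages whose
#' count exceeds `det_threshold` are updated deterministically
#' (expected-value updating) - the hybrid scheme keeps desk-scale runtime
#' while rare lineages retain full drift.
#'
#' New mutants are seeded as Poisson(`mu_locus` x divisions-this-generation)
#' independent count-1 lineages (divisions equal the net new cells
#' produced). Each mutant is assigned parent lineage proportionally to the
#' parent's share of divisions, receives `s_new`, and is deducted from its
#' parent's newborn cells so totals are conserved.
#'
#' @param state A [population_state()].
#' @param mut A [mutation_params()]; default is mutation-free growth.
#' @param det_threshold Per-genotype count above which updating is
#'   deterministic (default `1e6`).
#' @param deterministic If `TRUE`, force expected-value updating for all
#'   lineages (counts may become non-integer).
#' @return The grown [population_state()], generation incremented.
#' @export
grow_one_generation <- function(state, mut = mutation_params(),
                                det_threshold = 1e6,
                                deterministic = FALSE) {
  stopifnot(inherits(state, "population_state"),
            inherits(mut, "mutation_params"))
  counts <- state$counts
  s_vec <- state$genotypes$s[match(names(counts), state$genotypes$id)]
  expected <- counts * 2^(1 + s_vec)
  if (deterministic) {
    new_counts <- expected
  } else {
    det <- counts > det_threshold
    new_counts <- expected
    new_counts[!det] <- stochastic_round(expected[!det])
  }
  genotypes <- state$genotypes
  generation <- state$generation + 1L

  if (mut$mu_locus > 0) {
    divisions <- pmax(new_counts - counts, 0)
    n_new <- stats::rpois(1L, mut$mu_locus * sum(divisions))
    if (n_new > 0) {
      parent_idx <- sample.int(length(counts), n_new, replace = TRUE,
                               prob = divisions)
      next_id <- max(suppressWarnings(as.integer(genotypes$id)), 0L,
                     na.rm = TRUE)
      for (k in seq_len(n_new)) {
        p <- parent_idx[k]
        if (new_counts[p] < 1) next  # parent newborn pool exhausted
        next_id <- next_id + 1L
        id <- as.character(next_id)
        new_counts[p] <- new_counts[p] - 1
        new_counts[id] <- 1
        genotypes <- rbind(genotypes, data.frame(
          id = id, s = mut$s_new, parent_id = names(counts)[p],
          origin_generation = generation, stringsAsFactors = FALSE))
      }
    }
  }
  population_state(new_counts, genotypes, generation, state$phase)
}

#' Fractional (venting-type) population bottleneck
#'
#' Each cell survives independently with probability `fraction` (binomial
#' sampling per genotype), emulating the daily expulsion of most of the
#' light-organ population at dawn. Expected per-genotype frequency is
#' unchanged. Lineages above `det_threshold` are thinned deterministically.
#'
#' @param state A [population_state()].
#' @param fraction Survival fraction, in `(0, 1]` (venting a fraction `v`
#'   of the population means `fraction = 1 - v`).
#' @param det_threshold Per-genotype count above which thinning is
#'   deterministic.
#' @return The bottlenecked [population_state()].
#' @export
apply_fractional_bottleneck <- function(state, fraction,
                                        det_threshold = 1e6) {
  stopifnot(inherits(state, "population_state"), is.numeric(fraction))
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(state)
  counts <- state$counts
  det <- counts > det_threshold
  out <- counts
  out[det] <- counts[det] * fraction
  out[!det] <- stats::rbinom(sum(!det), size = round(counts[!det]),
                             prob = fraction)
  population_state(out, state$genotypes, state$generation, state$phase)
}

#' Fixed-size (recruitment-type) population bottleneck
#'
#' Draws exactly `size` cells without replacement across genotypes
#' (multivariate hypergeometric sampling), emulating recruitment of a small
#' founder population (~12 cells) into a juvenile light organ.
#'
#' @param state A [population_state()].
#' @param size Number of founder cells to draw (`1 <= size <=` total count).
#' @return The founder [population_state()].
#' @export
apply_fixed_bottleneck <- function(state, size) {
  stopifnot(inherits(state, "population_state"), is.numeric(size))
  counts <- round(state$counts)
  total <- sum(counts)
  if (size < 1 || size != floor(size))
    stop("`size` must be a positive integer", call. = FALSE)
  if (size > total)
    stop("`size` exceeds the total cell count", call. = FALSE)
  out <- numeric(length(counts))
  names(out) <- names(counts)
  remaining <- size
  pool_rest <- total
  for (i in seq_along(counts)) {
    pool_rest <- pool_rest - counts[i]
    if (remaining == 0) break
    if (i == length(counts)) {
      out[i] <- remaining
    } else {
      out[i] <- stats::rhyper(1L, m = counts[i], n = pool_rest,
                              k = remaining)
      remaining <- remaining - out[i]
    }
  }
  population_state(out, state$genotypes, state$generation, state$phase)
}

# Grow until total >= capacity (or max_generations); overshoot is truncated
# proportionally across genotypes with stochastic rounding of fractional
# cells for sub-threshold lineages. Returns state plus generations grown.
grow_to_capacity <- function(state, capacity, mut, det_threshold = 1e6,
                             deterministic = FALSE, max_generations = 100L) {
  gens <- 0L
  while (total_count(state) < capacity && gens < max_generations) {
    state <- grow_one_generation(state, mut, det_threshold, deterministic)
    gens <- gens + 1L
  }
  total <- total_count(state)
  if (total > capacity) {
    scaled <- state$counts * (capacity / total)
    if (!deterministic) {
      small <- scaled <= det_threshold
      scaled[small] <- stochastic_round(scaled[small])
    }
    state <- population_state(scaled, state$genotypes, state$generation,
                              state$phase)
  }
  attr(state, "generations_grown") <- gens
  state
}

#' One host day: regrowth to carrying capacity, then venting
#'
#' Grows the light-organ population by whole generations until the total
#' reaches `carrying_capacity` (overshoot truncated proportionally across
#' genotypes, since growth halts at capacity), then applies the venting
#' bottleneck retaining `venting_survival` of the population. An extinct
#' input population is returned unchanged with attribute `extinct = TRUE`
#' (extinction is an outcome, not an error).
#'
#' @param state A [population_state()] (`phase` should be `"host"`).
#' @param scheme A [passage_scheme()].
#' @param mut A [mutation_params()].
#' @param det_threshold Hybrid-updating threshold, see
#'   [grow_one_generation()].
#' @param deterministic Force expected-value updating.
#' @return The post-venting [population_state()], with attributes
#'   `generations_grown` and, if the input was empty, `extinct = TRUE`.
#' @export
run_host_cycle <- function(state, scheme, mut = mutation_params(),
                           det_threshold = 1e6, deterministic = FALSE) {
  stopifnot(inherits(state, "population_state"),
            inherits(scheme, "passage_scheme"))
  if (total_count(state) == 0) {
    attr(state, "extinct") <- TRUE
    return(state)
  }
  state <- grow_to_capacity(state, scheme$carrying_capacity, mut,
                            det_threshold, deterministic)
  gens <- attr(state, "generations_grown")
  if (scheme$venting_survival < 1)
    state <- apply_fractional_bottleneck(state, scheme$venting_survival,
                                         det_threshold)
  attr(state, "generations_grown") <- gens
  state
}

#' Simulate a full serial-passage series through squid hosts
#'
#' Runs the inoculum growth phase (`N0` to `N_inoc` cells, with mutation),
#' then for each host in series: a fixed recruitment bottleneck of
#' `recruitment_size` founder cells, followed by `cycles_per_host`
#' growth-to-capacity/venting cycles. The ventate (post-venting population)
#' of each host seeds the next host's recruitment. If every lineage goes
#' extinct the series ends early with the status recorded.
#'
#' @param scheme A [passage_scheme()].
#' @param mut A [mutation_params()].
#' @param seed Optional integer seed for reproducibility.
#' @param seed_mutant Optional list `list(t =, s =, count = 1)`: seed a
#'   mutant lineage (id `"M"`) with selection coefficient `s` during
#'   generation `t` of the inoculum phase, for mutant-fate experiments.
#' @param det_threshold Hybrid-updating threshold.
#' @param deterministic Force expected-value updating.
#' @return An object of class `"passage_trajectory"`: list with
#'   `trajectory` (data frame: passage, cycle, generation, genotype_id, s,
#'   count; passage 0 / cycle 0 is the end of the inoculum phase; cycle 0
#'   within a passage is the founder population), `genotypes`, `fates`
#'   (per-genotype: `extinct`, `segregating`, or `fixed` at series end),
#'   `status` (`"completed"` or `"extinct_at_passage_<k>"`), `final_state`,
#'   and `seed`.
#' @export
run_passage_series <- function(scheme = passage_scheme(),
                               mut = mutation_params(),
                               seed = NULL,
                               seed_mutant = NULL,
                               det_threshold = 1e6,
                               deterministic = FALSE) {
  stopifnot(inherits(scheme, "passage_scheme"))
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  note <- function(state, passage, cycle) {
    keep <- state$counts > 0
    if (!any(keep)) return()
    s_vec <- state$genotypes$s[match(names(state$counts), state$genotypes$id)]
    rows[[length(rows) + 1L]] <<- data.frame(
      passage = passage, cycle = cycle, generation = state$generation,
      genotype_id = names(state$counts)[keep], s = s_vec[keep],
      count = unname(state$counts[keep]), stringsAsFactors = FALSE)
  }

  # inoculum phase
  state <- population_state(c(`0` = scheme$N0), phase = "inoculum")
  g <- 0L
  while (total_count(state) < scheme$N_inoc) {
    state <- grow_one_generation(state, mut, det_threshold, deterministic)
    g <- g + 1L
    if (!is.null(seed_mutant) && g == seed_mutant$t &&
        !"M" %in% state$genotypes$id) {
      cnt <- if (is.null(seed_mutant$count)) 1 else seed_mutant$count
      counts <- state$counts
      counts["M"] <- cnt
      genotypes <- rbind(state$genotypes, data.frame(
        id = "M", s = seed_mutant$s, parent_id = "0",
        origin_generation = g, stringsAsFactors = FALSE))
      state <- population_state(counts, genotypes, state$generation,
                                state$phase)
    }
    if (g > 200L) stop("inoculum failed to reach N_inoc", call. = FALSE)
  }
  if (total_count(state) > scheme$N_inoc) {  # truncate overshoot at N_inoc
    scaled <- state$counts * (scheme$N_inoc / total_count(state))
    if (!deterministic) {
      small <- scaled <= det_threshold
      scaled[small] <- stochastic_round(scaled[small])
    }
    state <- population_state(scaled, state$genotypes, state$generation,
                              state$phase)
  }
  note(state, 0L, 0L)

  status <- "completed"
  if (scheme$n_hosts > 0) {
    for (h in seq_len(scheme$n_hosts)) {
      if (total_count(state) < scheme$recruitment_size) {
        status <- sprintf("extinct_at_passage_%d", h)
        break
      }
      founders <- apply_fixed_bottleneck(state, scheme$recruitment_size)
      state <- population_state(founders$counts, founders$genotypes,
                                founders$generation, phase = "host")
      note(state, h, 0L)
      for (cy in seq_len(scheme$cycles_per_host)) {
        state <- run_host_cycle(state, scheme, mut, det_threshold,
                                deterministic)
        note(state, h, cy)
        if (total_count(state) == 0) break
      }
      if (total_count(state) == 0) {
        status <- sprintf("extinct_at_passage_%d", h)
        break
      }
    }
  }

  trajectory <- do.call(rbind, rows)
  freqs <- genotype_frequencies(state)
  fates <- vapply(state$genotypes$id, function(id) {
    f <- if (id %in% names(freqs)) freqs[[id]] else 0
    if (is.na(f) || f == 0) "extinct" else if (f == 1) "fixed" else "segregating"
  }, character(1))
  structure(
    list(trajectory = trajectory, genotypes = state$genotypes,
         fates = fates, status = status, final_state = state, seed = seed),
    class = "passage_trajectory"
  )
}

#' @export
print.passage_trajectory <- function(x, ...) {
  cat(sprintf("passage_trajectory: %d genotype(s), status %s\n",
              nrow(x$genotypes), x$status))
  tab <- table(factor(x$fates, levels = c("extinct", "segregating", "fixed")))
  cat(sprintf("  fates: %d extinct, %d segregating, %d fixed\n",
              tab[["extinct"]], tab[["segregating"]], tab[["fixed"]]))
  invisible(x)
}

#' Monte-Carlo fate of a single mutant lineage under periodic bottlenecks
#'
#' Seeds one mutant cell (selection coefficient `s`, per-generation factor
#' \eqn{2^{1+s}}) during generation `t` of a growth phase of `tau`
#' generations, and follows the lineage through the bottleneck at the end
#' of the phase and through subsequent growth/bottleneck cycles. Growth of
#' the lineage is deterministic doubling with stochastic rounding; each
#' bottleneck thins the lineage binomially with survival probability
#' `dilution` (default \eqn{2^{-\tau}}, the dilution that returns the
#' resident population to its pre-growth size). The resident population is
#' treated as deterministic background.
#'
#' By default replicates run until the lineage either dies out or exceeds
#' `establish_threshold` cells immediately after a bottleneck (at which
#' point eventual extinction is vanishingly unlikely for `s > 0`), i.e. the
#' estimate approximates the probability of eventual survival that the
#' analytic approximation [survival_probability()] targets. Set `n_cycles`
#' to instead score survival through a fixed number of bottlenecks.
#'
#' @param t Generation of mutant origin within the growth phase
#'   (`1 <= t <= tau`).
#' @param s Selection coefficient (simulator scale, `>= 0`).
#' @param tau Generations of growth between bottlenecks.
#' @param dilution Per-cell bottleneck survival probability (default
#'   `2^-tau`).
#' @param replicates Number of Monte-Carlo replicates (`>= 1`).
#' @param seed Optional integer seed.
#' @param n_cycles If given, score survival (lineage count > 0) after
#'   exactly this many bottlenecks instead of running to fate.
#' @param establish_threshold Post-bottleneck count at which a lineage is
#'   scored as established (survival) in run-to-fate mode.
#' @param max_cycles Safety cap on cycles in run-to-fate mode; lineages
#'   still alive at the cap are scored as surviving.
#' @return List with `estimate` (survival frequency), `ci` (95%
#'   Clopper-Pearson interval), `ci99` (99% interval), `survived`,
#'   `replicates`.
#' @examples
#' mutant_fate_monte_carlo(t = 1, s = 0.05, tau = 4, replicates = 1000,
#'                         seed = 1)
#' @export
mutant_fate_monte_carlo <- function(t, s, tau,
                                    dilution = 2^(-tau),
                                    replicates = 1e4,
                                    seed = NULL,
                                    n_cycles = NULL,
                                    establish_threshold = 200,
                                    max_cycles = 500L) {
  check_survival_query(t, s, tau)
  stopifnot(replicates >= 1)
  if (dilution <= 0 || dilution > 1)
    stop("`dilution` must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  growth_factor <- 2^(1 + s)
  counts <- rep(1, replicates)       # one mutant cell per replicate
  alive <- rep(TRUE, replicates)
  survived <- rep(FALSE, replicates)
  to_fate <- is.null(n_cycles)
  cycles_done <- 0L
  gens_first <- tau - t              # growth remaining in the origin cycle

  # expected post-bottleneck survivors >= threshold: extinction negligible,
  # freeze the replicate as surviving to avoid astronomically large counts
  assured <- establish_threshold / dilution

  repeat {
    gens <- if (cycles_done == 0L) gens_first else tau
    for (g in seq_len(gens)) {
      idx <- which(alive)
      if (length(idx) == 0) break
      counts[idx] <- stochastic_round(counts[idx] * growth_factor)
      alive[idx] <- counts[idx] > 0
      if (to_fate) {
        big <- alive & counts >= assured
        survived[big] <- TRUE
        alive[big] <- FALSE
      }
    }
    idx <- which(alive)
    if (length(idx) > 0) {
      # cap keeps rbinom in integer range; survival scoring is unaffected
      counts[idx] <- stats::rbinom(length(idx),
                                   size = pmin(counts[idx], 2^30),
                                   prob = dilution)
      alive[idx] <- counts[idx] > 0
    }
    cycles_done <- cycles_done + 1L
    if (to_fate) {
      est <- alive & counts >= establish_threshold
      survived[est] <- TRUE
      alive[est] <- FALSE            # fate decided
      if (!any(alive) || cycles_done >= max_cycles) {
        survived[alive] <- TRUE      # alive at cap: score as surviving
        break
      }
    } else if (cycles_done >= n_cycles) {
      survived[alive] <- TRUE
      break
    }
  }

  k <- sum(survived)
  ci95 <- stats::binom.test(k, replicates)$conf.int
  ci99 <- stats::binom.test(k, replicates, conf.level = 0.99)$conf.int
  list(estimate = k / replicates,
       ci = as.numeric(ci95),
       ci99 = as.numeric(ci99),
       survived = k,
       replicates = replicates)
}
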
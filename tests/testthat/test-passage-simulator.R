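test_that("growth doubles the ancestor and applies 2^(1+s) to mutants", {
  st <- population_state(c(`0` = 5))
  g1 <- grow_one_generation(st)
  expect_identical(unname(g1$counts[["0"]]), 10)
  expect_identical(g1$generation, 1L)

  # deterministic mode: s = 1 quadruples
  st2 <- two_strain_state(100, 100, s_evo = 1)
  g2 <- grow_one_generation(st2, deterministic = TRUE)
  expect_identical(unname(g2$counts[["anc"]]), 200)
  expect_identical(unname(g2$counts[["evo"]]), 400)

  # stochastic rounding preserves the expectation for fractional factors
  set.seed(5)
  st3 <- two_strain_state(0, 1000, s_evo = 0.5)
  reps <- vapply(1:500, function(i)
    sum(grow_one_generation(st3)$counts[["evo"]]), numeric(1))
  expected <- 1000 * 2^1.5
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 1e-9)
})

test_that("fractional bottlenecks thin binomially without creating cells", {
  st <- population_state(c(`0` = 1e6))
  expect_identical(apply_fractional_bottleneck(st, 1), st)
  expect_error(apply_fractional_bottleneck(st, 0), "fraction")
  expect_error(apply_fractional_bottleneck(st, 1.2), "fraction")

  set.seed(31)
  survivors <- vapply(1:200, function(i)
    total_count(apply_fractional_bottleneck(st, 0.05, det_threshold = 1e7)),
    numeric(1))
  expect_true(all(survivors <= 1e6))
  se <- sqrt(1e6 * 0.05 * 0.95) / sqrt(200)
  expect_lt(abs(mean(survivors) - 5e4), 3 * se)
})

test_that("venting-style sampling leaves expected lineage frequency unchanged", {
  # genotype at frequency 0.3: mean post-bottleneck frequency 0.3
  set.seed(77)
  st <- two_strain_state(7000, 3000, s_evo = 1)
  n_rep <- 1e4
  freqs <- vapply(seq_len(n_rep), function(i) {
    post <- apply_fractional_bottleneck(st, 0.05)
    unname(genotype_frequencies(post)[["evo"]])
  }, numeric(1))
  se <- stats::sd(freqs) / sqrt(n_rep)
  expect_lt(abs(mean(freqs) - 0.3), 3 * se)
})

test_that("fixed bottlenecks draw a multivariate hypergeometric sample", {
  st <- population_state(c(`0` = 5))
  expect_identical(apply_fixed_bottleneck(st, 5)$counts, st$counts)
  expect_error(apply_fixed_bottleneck(st, 6), "exceeds")
  expect_error(apply_fixed_bottleneck(st, 0), "positive")

  # inclusion probability of a singleton lineage: 10/10000
  set.seed(13)
  st2 <- two_strain_state(9999, 1, s_evo = 0)
  n_rep <- 1e4
  included <- vapply(seq_len(n_rep), function(i)
    apply_fixed_bottleneck(st2, 10)$counts[["evo"]] > 0, logical(1))
  p <- 10 / 10000
  se <- sqrt(p * (1 - p) / n_rep)
  expect_lt(abs(mean(included) - p), 3 * se)
  # bottlenecks conserve: never create cells
  expect_identical(total_count(apply_fixed_bottleneck(st2, 10)), 10)
})

test_that("host cycles grow to capacity then vent", {
  scheme <- passage_scheme()
  # 12 founders reach 5e5 in ceil(log2(5e5/12)) = 16 doubling generations
  st <- population_state(c(`0` = 12), phase = "host")
  grown <- run_host_cycle(st, passage_scheme(venting_survival = 1 - 1e-12),
                          deterministic = TRUE)
  expect_identical(attr(grown, "generations_grown"), 16L)
  expect_equal(total_count(grown), 5e5, tolerance = 1e-6)

  # post-vent expected total = 0.05 x capacity
  set.seed(101)
  totals <- vapply(1:200, function(i) {
    st <- population_state(c(`0` = 12), phase = "host")
    total_count(run_host_cycle(st, scheme))
  }, numeric(1))
  se <- stats::sd(totals) / sqrt(200)
  expect_lt(abs(mean(totals) - 0.05 * 5e5), 3 * se)

  # venting_survival ~ 1 makes the cycle growth-only
  scheme_nv <- passage_scheme(venting_survival = 1 - 1e-12)
  st <- population_state(c(`0` = 12), phase = "host")
  out <- run_host_cycle(st, scheme_nv)
  expect_gte(total_count(out), 5e5 - 1)

  # extinction is an outcome, not an error
  empty <- population_state(c(`0` = 0), phase = "host")
  out <- run_host_cycle(empty, scheme)
  expect_true(isTRUE(attr(out, "extinct")))
  expect_identical(total_count(out), 0)
})

test_that("passage series bookkeeping: phases, fates, degenerate schemes", {
  scheme <- passage_scheme(N0 = 5, N_inoc = 1e4, recruitment_size = 12,
                           carrying_capacity = 1e3, cycles_per_host = 2,
                           n_hosts = 3)
  # mu = 0, single ancestor: exactly one genotype throughout
  res <- run_passage_series(scheme, seed = 42)
  expect_identical(unique(res$trajectory$genotype_id), "0")
  expect_identical(res$status, "completed")
  expect_identical(unname(res$fates["0"]), "fixed")
  # generations strictly increase within each passage
  for (p in unique(res$trajectory$passage)) {
    gen <- res$trajectory$generation[res$trajectory$passage == p]
    expect_true(all(diff(gen) >= 0))
  }

  # n_hosts = 0: inoculum phase only
  res0 <- run_passage_series(passage_scheme(N_inoc = 1e4, n_hosts = 0),
                             seed = 1)
  expect_identical(unique(res0$trajectory$passage), 0L)

  # identical seeds give identical trajectories
  res_a <- run_passage_series(scheme, mutation_params(1e-6, 1), seed = 7)
  res_b <- run_passage_series(scheme, mutation_params(1e-6, 1), seed = 7)
  expect_identical(res_a$trajectory, res_b$trajectory)
})

test_that("strong selection raises fixation frequency of a seeded mutant", {
  scheme <- passage_scheme(N0 = 5, N_inoc = 1e5, recruitment_size = 12,
                           carrying_capacity = 1e4, cycles_per_host = 2,
                           n_hosts = 5)
  fixation_freq <- function(s, n_rep = 100, seed_base = 1000) {
    fixed <- vapply(seq_len(n_rep), function(i) {
      res <- run_passage_series(scheme, seed = seed_base + i,
                                seed_mutant = list(t = 1, s = s, count = 1))
      isTRUE(res$fates[["M"]] == "fixed")
    }, logical(1))
    mean(fixed)
  }
  freqs <- vapply(c(0, 0.5, 2, 5), fixation_freq, numeric(1))
  # fixation frequency non-decreasing in s; beneficial beats neutral
  expect_true(all(diff(freqs) >= 0))
  expect_gt(freqs[4], freqs[1])
})

test_that("neutral lineage frequency is conserved in expectation", {
  # with all s = 0, a lineage's expected frequency stays at its start
  scheme <- passage_scheme(N0 = 100, N_inoc = 1e4, recruitment_size = 50,
                           carrying_capacity = 5e3, cycles_per_host = 2,
                           n_hosts = 2)
  set.seed(404)
  n_rep <- 300
  final_freq <- vapply(seq_len(n_rep), function(i) {
    st <- two_strain_state(70, 30, s_evo = 0, phase = "host")
    for (cy in 1:4) st <- run_host_cycle(st, scheme)
    f <- genotype_frequencies(st)[["evo"]]
    if (is.nan(f)) NA_real_ else f
  }, numeric(1))
  # extinct replicates carry frequency 0
  final_freq[is.na(final_freq)] <- 0
  se <- stats::sd(final_freq) / sqrt(n_rep)
  expect_lt(abs(mean(final_freq) - 0.3), 3 * se)
})

test_that("Monte-Carlo mutant fate agrees with the analytic approximation", {
  # triples inside the approximation's validity domain (s*tau*ln2 small)
  cases <- list(c(t = 1, s = 0.02, tau = 4),
                c(t = 2, s = 0.05, tau = 4),
                c(t = 3, s = 0.1, tau = 4))
  for (cs in cases) {
    analytic <- survival_probability(cs["t"], cs["s"], cs["tau"],
                                     clamp = FALSE)
    expect_lte(analytic, 0.2)
    mc <- mutant_fate_monte_carlo(cs["t"], cs["s"], cs["tau"],
                                  replicates = 1e4, seed = 42)
    expect_true(mc_within_oracle_band(mc$estimate, analytic, 1e4))
  }
})

test_that("single-bottleneck mutant fate reduces to one-cell binomial survival", {
  # mutant arising in the last generation: one cell, survival ~ dilution
  mc <- mutant_fate_monte_carlo(t = 4, s = 0, tau = 4, dilution = 0.05,
                                replicates = 1e4, seed = 7, n_cycles = 1)
  se <- sqrt(0.05 * 0.95 / 1e4)
  expect_lt(abs(mc$estimate - 0.05), 3 * se)
  expect_true(mc$ci[1] <= 0.05 && 0.05 <= mc$ci[2])

  # replicates = 1: degenerate 0/1 estimate with a valid CI
  one <- mutant_fate_monte_carlo(t = 1, s = 1, tau = 4, replicates = 1,
                                 seed = 3)
  expect_true(one$estimate %in% c(0, 1))
  expect_length(one$ci, 2)
})
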
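make_obs <- function(count_evolved, count_ancestor, density = 1e4,
                     freq = 0.5, dilution = 1, timepoint = 24,
                     host = "h1") {
  data.frame(host_id = host, timepoint_hr = timepoint,
             count_evolved = count_evolved,
             count_ancestor = count_ancestor,
             dilution_factor = dilution, inoculum_density = density,
             inoculum_frequency_evolved = freq,
             marker_orientation = "evolved_blue",
             stringsAsFactors = FALSE)
}

test_that("Malthusian parameters are natural-log abundance ratios", {
  expect_equal(malthusian(1, 325), log(1 / 325))
  expect_equal(malthusian(1, 325), -5.784, tolerance = 1e-3)
  expect_equal(malthusian(9, 2.4e8), log(9 / 2.4e8))
  expect_equal(malthusian(9, 2.4e8), -17.10, tolerance = 1e-3)
  expect_identical(malthusian(100, 100), 0)
  expect_error(malthusian(0, 10), "censor")
  expect_error(malthusian(10, 0), "censor")
})

test_that("selection rate is the antisymmetric difference of M values", {
  expect_identical(selection_rate(2, 2), 0)
  expect_equal(selection_rate(malthusian(1, 325), malthusian(9, 2.4e8)),
               log(1 / 325) - log(9 / 2.4e8))
  a <- -5.8; b <- -17.1
  expect_identical(selection_rate(a, b), -selection_rate(b, a))
})

test_that("scale conversion between estimator and simulator conventions", {
  expect_identical(estimator_to_simulator_s(0), 0)
  expect_equal(simulator_to_estimator_s(log(2)), 1)
  s <- c(-0.5, 0, 0.3, 1.7, 6)
  expect_equal(estimator_to_simulator_s(simulator_to_estimator_s(s)), s)
})

test_that("selection estimation implements s_GR and s = s_GR/ln2", {
  # construct counts so M_evo = 2 * M_anc: start 5000 each (f = 0.5),
  # end_anc = 5000*e, end_evo = 5000*e^2
  obs <- make_obs(count_evolved = 5000 * exp(2), count_ancestor = 5000 * exp(1))
  est <- estimate_selection(obs)
  expect_equal(est$M_ancestor, 1)
  expect_equal(est$M_evolved, 2)
  expect_equal(est$s_GR, 1)
  expect_equal(est$s, 1 / log(2))

  # equal fitness: s = 0
  est0 <- estimate_selection(make_obs(700, 700))
  expect_equal(est0$s_GR, 0)
  expect_identical(est0$s, 0)

  # s_GR = 0.693 -> s = 1.000
  expect_equal(0.693 / log(2), 1, tolerance = 1e-3)

  # dilution factor scales both end abundances
  est_d <- estimate_selection(make_obs(50 * exp(2), 50 * exp(1),
                                       dilution = 100))
  expect_equal(est_d$s, est$s)
})

test_that("zero counts are censored at the detection floor and flagged", {
  obs <- make_obs(count_evolved = 0, count_ancestor = 800, freq = 0.01)
  est <- estimate_selection(obs, detection_floor = 15)
  expect_true(est$censored)
  expect_true(est$valid)
  expect_equal(est$M_evolved, log(15 / (1e4 * 0.01)))

  # both strains undetected: invalid
  est2 <- estimate_selection(make_obs(0, 0))
  expect_false(est2$valid)

  # M_anc = 0 makes s_GR undefined
  est3 <- estimate_selection(make_obs(900, 5000))
  expect_false(est3$valid)
  expect_true(is.na(est3$s))
})

test_that("experiment summaries report per-timepoint means, CIs, tests", {
  cfg <- competition_config(s_true = 0.5, n_hosts = 30,
                            timepoints = c(24, 48), frequencies = 0.5,
                            densities = 12, growth_generations = 5,
                            dilution_factor = 1)
  d <- generate_competition_experiment(cfg, seed = 21)
  sm <- summarize_experiment(d$observations, seed = 21, n_boot = 2000)
  expect_identical(sm$by_timepoint$timepoint_hr, c(24, 48))
  expect_true(all(sm$by_timepoint$n > 0))
  expect_true(all(sm$by_timepoint$ci_lower <= sm$by_timepoint$mean_s))
  expect_true(all(sm$by_timepoint$ci_upper >= sm$by_timepoint$mean_s))
  expect_s3_class(sm$timepoint_test, "fp_test")
  expect_output(print(sm), "Competition experiment summary")

  # single observation: degenerate CI, flagged
  one <- summarize_experiment(make_obs(5000 * exp(2), 5000 * exp(1)),
                              n_boot = 100)
  expect_true(one$by_timepoint$degenerate)
  expect_true(is.na(one$by_timepoint$ci_lower))

  # duplicated timepoints with identical counts: between-timepoint p = 1
  dup <- rbind(
    make_obs(4000, 2000, host = "a", timepoint = 24),
    make_obs(4000, 2000, host = "b", timepoint = 24),
    make_obs(4000, 2000, host = "c", timepoint = 48),
    make_obs(4000, 2000, host = "d", timepoint = 48))
  sm_dup <- summarize_experiment(dup, n_boot = 100)
  expect_equal(sm_dup$timepoint_test$p_value, 1)
})

test_that("noiseless synthetic data round-trips s_true through the estimator", {
  for (s_true in c(0.25, 1, 3)) {
    cfg <- competition_config(s_true = s_true, n_hosts = 3, timepoints = 24,
                              frequencies = 0.5, growth_generations = 5,
                              dilution_factor = 1, noise = FALSE)
    d <- generate_competition_experiment(cfg, seed = 1)
    est <- estimate_selection(d$observations)
    recovered <- estimator_to_simulator_s(est$s)
    expect_lt(max(abs(recovered - s_true) / s_true), 1e-9)
  }
})

test_that("estimated s is frequency-independent under hard selection", {
  # large founding populations (in-vitro-style competition): founder
  # sampling is unbiased across 1e-4..0.5, so the slope CI covers zero
  cfg <- competition_config(s_true = 1, n_hosts = 50, timepoints = 24,
                            founder_size = 1e5, carrying_capacity = 1e7,
                            densities = 1e5,
                            frequency_range = c(1e-4, 0.5),
                            growth_generations = 5, dilution_factor = 10)
  d <- generate_competition_experiment(cfg, seed = 2)
  sm <- summarize_experiment(d$observations, seed = 2, n_boot = 1000)
  expect_true(sm$frequency_diagnostic$covers_zero)
  # and the recovered mean sits at the configured coefficient
  expect_equal(sm$by_timepoint$mean_s[1], simulator_to_estimator_s(1),
               tolerance = 0.05)
})
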
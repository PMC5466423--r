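test_that("plated counts are Poisson around abundance/dilution with a floor", {
  z <- plate_counts(0, dilution_factor = 10)
  expect_identical(z$count, 0L)
  expect_true(z$below_detection)

  set.seed(3)
  draws <- plate_counts(rep(1e4, 1e4), dilution_factor = 100)
  se <- sqrt(100 / 1e4)   # Poisson variance = mean
  expect_lt(abs(mean(draws$count) - 100), 3 * se)

  # expected abundance 10 with floor 15: flagged below detection
  low <- plate_counts(10, dilution_factor = 1, detection_floor = 15,
                      seed = 5)
  expect_true(all(low$below_detection[low$count * 1 < 15]))
  # overdispersed option inflates variance
  set.seed(9)
  nb <- plate_counts(rep(1e4, 5e3), dilution_factor = 100,
                     dispersion = 0.5)
  expect_gt(stats::var(nb$count), 2 * stats::var(draws$count))
})

test_that("generated competition tables are schema-valid for estimation", {
  cfg <- competition_config(s_true = 0.25, n_hosts = 8)
  d <- generate_competition_experiment(cfg, seed = 11)
  expect_identical(nrow(d$observations), 16L)     # 8 hosts x 2 timepoints
  expect_identical(nrow(d$ground_truth), 16L)
  # generated tables feed the estimator with zero manual editing
  est <- estimate_selection(d$observations)
  expect_identical(nrow(est), 16L)
  # and survive a write/read round trip
  path <- tempfile(fileext = ".tsv")
  write_observations(d$observations, path, seed = 11)
  back <- read_observations(path)
  expect_equal(back$count_evolved, d$observations$count_evolved)

  # impossible geometry is rejected
  expect_error(competition_config(founder_size = 100, carrying_capacity = 50),
               "carrying_capacity")
})

test_that("rare-variant founder inclusion matches binomial sampling", {
  # evolved frequency 1e-4, founder 12: P(>= 1 evolved founder)
  # = 1 - (1 - 1e-4)^12 ~ 1.2e-3
  cfg <- competition_config(s_true = 0, n_hosts = 2e4, timepoints = 24,
                            frequencies = 1e-4, densities = 1e4,
                            growth_generations = 2, dilution_factor = 1)
  d <- generate_competition_experiment(cfg, seed = 31)
  p_inc <- mean(d$ground_truth$n_founder_evolved >= 1)
  p_true <- 1 - (1 - 1e-4)^12
  se <- sqrt(p_true * (1 - p_true) / 2e4)
  expect_lt(abs(p_inc - p_true), 3 * se)
})

test_that("neutral cohorts recover s near zero", {
  cfg <- competition_config(s_true = 0, n_hosts = 100, timepoints = 24,
                            frequencies = 0.5, densities = 12,
                            growth_generations = 5, dilution_factor = 1)
  d <- generate_competition_experiment(cfg, seed = 41)
  sm <- summarize_experiment(d$observations, seed = 41, n_boot = 2000)
  ci <- c(sm$by_timepoint$ci_lower[1], sm$by_timepoint$ci_upper[1])
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("passage datasets tabulate lineage fates", {
  scheme <- passage_scheme(N0 = 5, N_inoc = 1e4, recruitment_size = 12,
                           carrying_capacity = 1e3, cycles_per_host = 1,
                           n_hosts = 3)
  # mu = 0: no lineage ever reports a variant; 10 lineages -> 10 rows
  d0 <- generate_passage_dataset(scheme, mutation_params(0), n_lineages = 10,
                                 seed = 51)
  expect_identical(nrow(d0), 10L)
  expect_true(all(d0$n_variants == 0))
  expect_true(all(!d0$variant_detected))

  # a strongly beneficial mutation class fixes more often than a neutral
  # one (paired seeds)
  d_sel <- generate_passage_dataset(scheme, mutation_params(1e-4, s_new = 5),
                                    n_lineages = 60, seed = 61)
  d_neu <- generate_passage_dataset(scheme, mutation_params(1e-4, s_new = 0),
                                    n_lineages = 60, seed = 61)
  expect_gt(mean(d_sel$variant_fixed), mean(d_neu$variant_fixed))
})
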
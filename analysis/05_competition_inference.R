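#!/usr/bin/env Rscript
# Selection-coefficient inference from synthetic co-inoculation
# competitions: (i) an in-vivo-style cohort emulating the study design
# (12-cell founders, inoculum densities 1,600-26,600 CFU/mL, evolved
# frequencies 1e-4..0.5, 24 and 48 hr timepoints, 15-CFU detection floor),
# and (ii) an in-vitro-style cohort (large founding populations) where the
# hard-selection diagnostic is free of recruitment-sampling artifacts.

library(vibriopassage)
dir.create("results", showWarnings = FALSE)
seed <- 20260105

## (i) in-vivo emulation -----------------------------------------------
cfg_vivo <- competition_config(s_true = 0.25, n_hosts = 50,
                               timepoints = c(24, 48),
                               condition_on_cocolonization = TRUE)
d_vivo <- generate_competition_experiment(cfg_vivo, seed = seed)
write_observations(d_vivo$observations, "results/competition_observations.tsv",
                   seed = seed, config = list(s_true = cfg_vivo$s_true))
write_table(d_vivo$ground_truth, "results/competition_ground_truth.tsv",
            seed = seed)
est <- estimate_selection(d_vivo$observations)
write_table(est, "results/competition_estimates.tsv", seed = seed)

sm <- summarize_experiment(d_vivo$observations, seed = seed)
cat("In-vivo-style cohort (s_true = 0.25 simulator scale, co-colonized",
    "hosts only):\n\n")
print(sm)

fd <- sm$frequency_diagnostic
cat("\nThe negative frequency slope above is a recruitment-sampling\n",
    "artifact: conditioning on co-colonization at founder size 12 makes\n",
    "rare-variant hosts 'jackpot' hosts (one realized founder where\n",
    "~0.001 were expected), inflating their estimates. The study's\n",
    "design carries the same effect.\n", sep = "")

## (ii) in-vitro-style cohort: estimator-level diagnostic ---------------
cfg_vitro <- competition_config(s_true = 1, n_hosts = 50, timepoints = 24,
                                founder_size = 1e5, carrying_capacity = 1e7,
                                densities = 1e5,
                                frequency_range = c(1e-4, 0.5),
                                growth_generations = 5, dilution_factor = 10)
d_vitro <- generate_competition_experiment(cfg_vitro, seed = seed + 1)
sm2 <- summarize_experiment(d_vitro$observations, seed = seed + 1)
fd2 <- sm2$frequency_diagnostic
cat(sprintf(
  "\nIn-vitro-style cohort (founders 1e5, s_true = 1 -> estimator scale %.3f):\n  mean s = %.3f; frequency slope %.3g [%.3g, %.3g] -> %s\n",
  simulator_to_estimator_s(1), sm2$by_timepoint$mean_s[1],
  fd2$slope, fd2$ci[1], fd2$ci[2],
  if (fd2$covers_zero) "independent of starting frequency (hard selection)"
  else "frequency-dependent"))

## worked single-host example ------------------------------------------
cat("\nWorked example: a rare variant recovered at 1 CFU-equivalent against\n")
cat("a declining wild-type background (selection-rate formulation):\n")
M_rare <- malthusian(1, 325)
M_wt <- malthusian(9, 2.4e8)
cat(sprintf("  M(rare) = ln(1/325) = %.3f; M(wt) = ln(9/2.4e8) = %.3f\n",
            M_rare, M_wt))
cat(sprintf("  selection rate r = %.2f natural logs\n",
            selection_rate(M_rare, M_wt)))
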
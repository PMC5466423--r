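# Independent brute-force oracle for the two-sample permutation test:
# enumerates every 0/1 assignment vector of the pooled values (via binary
# expansion, a different code path from the package's combn-over-values
# enumeration) and computes the mean difference directly per assignment.
brute_force_permutation_p <- function(group_a, group_b,
                                      alternative = "two.sided") {
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  n_a <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  tol <- 1e-8 * max(1, abs(obs), abs(diff(range(pooled))))
  diffs <- c()
  for (code in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(bits) != n_a) next
    diffs <- c(diffs, mean(pooled[bits]) - mean(pooled[!bits]))
  }
  switch(alternative,
         two.sided = mean(abs(diffs) >= abs(obs) - tol),
         greater   = mean(diffs >= obs - tol),
         less      = mean(diffs <= obs + tol))
}

# Oracle-agreement band for Monte-Carlo vs the analytic survival
# approximation: 99% binomial CI half-width or +/-30% relative, whichever
# is wider (the formula is itself a first-order approximation).
mc_within_oracle_band <- function(mc_estimate, analytic_pi, replicates) {
  half_ci <- stats::qnorm(0.995) *
    sqrt(analytic_pi * (1 - analytic_pi) / replicates)
  band <- max(half_ci, 0.3 * analytic_pi)
  abs(mc_estimate - analytic_pi) <= band
}

# Two-lineage population state used across simulator tests
two_strain_state <- function(n_anc, n_evo, s_evo, phase = "host") {
  population_state(
    c(anc = n_anc, evo = n_evo),
    data.frame(id = c("anc", "evo"), s = c(0, s_evo),
               parent_id = c(NA_character_, "anc"),
               origin_generation = c(0L, 0L), stringsAsFactors = FALSE),
    phase = phase)
}
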
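#!/usr/bin/env Rscript
# Mutation supply to the focal sensor-kinase locus (binK) during inoculum
# expansion: expected number of non-synonymous hits and the Poisson
# probability that at least one arises early in growth.

library(vibriopassage)
dir.create("results", showWarnings = FALSE)

params <- mutation_supply_params()   # study defaults: binK in MJ11
ms <- mutation_supply(params, first_g = 10)

tab <- data.frame(
  quantity = c("generations of expansion (5 -> 2.4e8 cells)",
               "generations (floor)",
               "cell divisions, whole expansion",
               "expected binK non-syn mutations, whole expansion",
               "P(>=1 binK mutation), whole expansion",
               "cell divisions, first 10 generations",
               "expected binK non-syn mutations, first 10 generations",
               "P(>=1 binK mutation), first 10 generations"),
  value = c(ms$generations, ms$generations_floor, ms$divisions_total,
            ms$lambda_total, ms$p_any_total, ms$divisions_first,
            ms$lambda_first, ms$p_any_first))
write_table(tab, "results/mutation_supply.tsv",
            config = unclass(params))

cat("Mutation supply to binK under the study parameter table\n")
cat(sprintf("  (mu = %.3g /bp/division, %d bp x %.3f available, %g -> %g cells):\n\n",
            params$mu, params$locus_length_bp, params$nonsyn_fraction,
            params$N0, params$N_final))
print(transform(tab, value = signif(value, 4)), row.names = FALSE)

cat("\nNote: the printed parameter set implies ~8.6e3 expected locus\n",
    "mutations over the full expansion - orders of magnitude above the\n",
    "companion literature values (~1e2), which are not recoverable from\n",
    "this parameter table; the table's inputs are reported as given and\n",
    "all parameters are explicit, so alternative rates can be supplied\n",
    "via mutation_supply_params().\n", sep = "")

# sensitivity: a mutation rate at the 1e-10 scale reported by
# fluctuation-test literature for related vibrios
alt <- mutation_supply(mutation_supply_params(mu = 1e-10), first_g = 10)
cat(sprintf(
  "\nAt mu = 1e-10 /bp/division the same geometry gives lambda = %.1f\n(whole expansion) and P(>=1 in first 10 generations) = %.2g.\n",
  alt$lambda_total, alt$p_any_first))
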
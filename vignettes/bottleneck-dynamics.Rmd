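---
title: "Bottleneck population dynamics and selection inference in the squid-Vibrio system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottleneck population dynamics and selection inference in the squid-Vibrio system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibriopassage)
```

## The system and the model

Juvenile *Euprymna scolopes* squid acquire their *Vibrio fischeri* light-organ
symbionts from seawater through an extreme demographic funnel. A cultured
inoculum expands from a handful of cells to ~2.4 × 10⁸; each hatchling then
recruits only ~10-12 founder cells (2-3 per crypt); the light-organ population
regrows to its carrying capacity of ~5 × 10⁵ cells and is vented by 95% at
every dawn. Serial passage of symbionts through a sequence of hosts therefore
exposes every lineage to one severe fixed-size bottleneck (recruitment)
followed by repeated fractional bottlenecks (venting), separated by phases of
rapid binary-fission growth.

This package models that regime at three levels:

1. **Closed form.** `survival_probability(t, s, tau)` implements the
   first-order branching-process approximation (after Wahl and Gerrish) for
   the probability that a beneficial mutant arising during generation `t` of
   a `tau`-generation growth phase escapes stochastic loss through the
   subsequent bottlenecks:
   π(t, s) = s·τ·ln2 / 2^(t−1), clamped to [0, 1], with extinction
   V = 1 − π. Here `s` is the excess doubling exponent: a mutant multiplies
   by 2^(1+s) per generation while the ancestor doubles.
2. **Simulation.** `run_passage_series()` and friends simulate
   lineage-resolved populations through inoculum growth, recruitment,
   venting, and regrowth; `mutant_fate_monte_carlo()` estimates survival of
   a single seeded mutant lineage directly.
3. **Inference.** `estimate_selection()` recovers selection coefficients
   from marked-strain competition counts the way the experimental assay
   does: Malthusian parameters M = ln(end/start) per strain, relative
   growth-rate difference s_GR = (M_Evo − M_Anc)/M_Anc, and s = s_GR/ln2.

A synthetic-data layer (`generate_competition_experiment()`,
`generate_passage_dataset()`) emulates the raw data the assays produce -
founder sampling, growth, venting, dilution plating with a 15-CFU detection
floor - with known ground truth, so the estimators and the simulator are
testable end to end without any external data.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `N0` | 5 | cells | inoculum starting population |
| `N_inoc` | 2.4e8 | cells | inoculum size at host exposure (~25.5 doublings from `N0`) |
| `recruitment_size` | 12 | cells | founder population per host (2-3 cells per crypt); the literature also quotes "~10", so it is configurable |
| `carrying_capacity` | 5e5 | cells | juvenile light-organ capacity |
| `venting_survival` | 0.05 | fraction | 95% of the population is expelled at dawn |
| `tau_recruitment` | 25 | generations | growth preceding the colonization bottleneck |
| `tau_venting` | 4 | generations | daily regrowth between ventings |
| `mu` (locus supply) | 2.08e-8 | /bp/division | genomic rate from the study's parameter table |
| locus | 2595 bp × 2/3 | bp | *binK* length × available non-synonymous fraction |
| detection floor | 15 | CFU | dilution-plating sensitivity per light organ |

Two selection-coefficient scales coexist and are easy to conflate. The
*simulator* scale multiplies a mutant by 2^(1+s) per generation; the
*estimator* scale is s = s_GR/ln2. When both competitors grow the same
number of generations from their founder abundances the scales differ by
exactly ln2, and `estimator_to_simulator_s()` / `simulator_to_estimator_s()`
convert between them. Under realistic in-vivo geometry (shared carrying
capacity, start abundances taken from inoculum concentration rather than
founder counts) the estimator's expectation is **not** a fixed rescaling of
the simulator coefficient; the generator therefore emits per-host
deterministic-expectation values (`ground_truth$s_expected`) as the honest
reference for noisy cohorts.

## Numerical and design choices

**Stochastic rounding, not Poisson offspring.** Growth realises non-integer
expected counts as floor + Bernoulli(fractional part). This preserves
expectations while adding at most Bernoulli variance per lineage per
generation, keeping bottleneck binomial sampling the dominant noise source -
the regime the closed-form approximation assumes. Poisson-distributed
offspring would roughly double the per-cycle offspring variance of a rare
lineage and halve its establishment probability, so the simulation would
systematically disagree with the analytic formula it is meant to check.
Mutation *arrivals* remain Poisson (rate = per-division probability × cell
divisions that generation), which is the Luria-Delbrück accounting.

**Hybrid scale switching.** Lineages above 10⁶ cells (configurable) update
deterministically; rare lineages stay fully stochastic. Fixed-size
recruitment sampling is always exact multivariate hypergeometric.

**Carrying capacity.** Growth proceeds in whole generations until the total
reaches capacity; overshoot is truncated proportionally across genotypes
(there is no published within-host density-regulation model to be more
clever with). Venting is applied after growth reaches capacity; whether
venting interrupts the final generation of growth is unstated in the source
material, and this convention is the simplest consistent one.

**Origin-generation convention.** `t = 1` means the mutant is present as one
cell at the end of the first growth generation, so it undergoes `tau − t`
further doublings before the bottleneck.

**Validity domain of the closed form.** π = s·τ·ln2/2^(t−1) is first order
in s·τ·ln2. The Monte-Carlo cross-checks therefore run where that product is
small (≤ ~0.3) and raw π ≤ 0.2, and agreement is scored against the wider of
the 99% binomial CI and ±30% relative. Outside that domain the closed form
can be off by an order of magnitude - e.g. at (t = 8, s = 0.5, τ = 25) it
gives 0.068 while simulation gives ~0.75, because once a lineage expects
more than one post-bottleneck survivor its establishment is near-certain,
which the linearisation ignores. `analysis/02_mutant_fate_check.R`
reproduces both regimes. This is a property of the approximation itself, so
the package reports raw (unclamped) values on request and treats the
simulator as the arbiter away from small s·τ.

**Exact permutation test.** The Fisher-Pitman test enumerates all
C(n, n_a) assignments when that count is below a cap (default 10⁶),
counting ties as "as extreme" under a small relative tolerance; above the
cap it falls back to Monte-Carlo with the observed assignment included in
numerator and denominator. The null rejection rate at α = 0.05 sits just
below nominal because the exact distribution is discrete.

**Censoring.** A competitor recovered with zero colonies is censored at the
15-CFU detection floor rather than dropped, and flagged; dropping such hosts
would bias the data set toward co-recovery. Censored estimates are excluded
from cohort summaries by default.

**Bootstrap CI.** Mean selection coefficients per timepoint get a
bias-corrected percentile bootstrap CI (default 10⁴ resamples, seeded); the
source material reports 95% CIs without naming a method, and BC percentile
is a reasonable default for small skewed samples.

## What the generator emulates - and what it does not

The competition generator reproduces the assay's observable layer: binomial
founder sampling from the inoculum composition, two-strain growth with the
evolved genotype at `s_true`, optional venting for the 48-hr timepoint
(24 hr ≈ recruitment + growth to capacity; 48 hr adds one vent/regrow cycle
of ~4-5 generations - the within-organ generation count between 24 and
48 hr is not published and is configurable), and Poisson plating counts
(optionally negative-binomial, since real plate counts overdisperse). It
does **not** model crypt substructure (the light organ is treated as one
well-mixed population), host sanctioning, marker/plasmid fitness effects
(the `marker_orientation` column is carried so users can test for them), or
luminescence phenotypes. Passing tests on these synthetic cohorts show that
the estimators recover known ground truth under the stated noise model; they
cannot show that the biological assumptions hold in real light organs.

One emergent artifact deserves emphasis: restricting analysis to
co-colonized hosts (as any real competition analysis must) makes
rare-variant hosts "jackpot" hosts at 12-cell founder sizes - a host at
frequency 10⁻⁴ that contains the variant at all contains ~830× more of it
than the inoculum frequency predicts - which inflates low-frequency
estimates and produces a spurious negative slope of s on starting frequency.
The hard-selection diagnostic (slope of s on frequency, CI covering zero) is
therefore well-posed only for cohorts with large founding populations
(in-vitro-style competitions), and that is how the package's acceptance
checks run it; the in-vivo artifact is demonstrated, not hidden, in
`analysis/05_competition_inference.R`.

## Known discrepancies in the source quantities

Three printed quantities are not reproducible from their own stated inputs,
and the package computes what the inputs imply rather than targeting the
printed numbers: (i) the expected number of *binK* mutations over inoculum
expansion - the parameter table implies ~8.6 × 10³, while ~325 and 185 are
quoted in different places (the cited mutation-rate literature is at the
10⁻¹⁰ scale, which would give ~40); (ii) the Poisson probability of an early
*binK* mutation (0.004 as printed; the table's parameters give 0.17 for the
first 10 generations); (iii) the worked selection rate
r = ln(1/325) − ln(9/2.4 × 10⁸), which evaluates to 11.3 natural logs, not
5.6 (a per-generation normalisation may be implied but is not stated).
Similarly, the claim that assured survival requires "s ~ 6 early in
expansion" matches the inverse formula only near origin generation 7-8
(`required_selection_coefficient(8, 1, 25)` ≈ 7.4); the exact generation
meant is not stated. All four are documented here and in the README and left
as computed.

## Problem sizes

The test suite and analysis scripts use desk-scale sizes chosen to keep
Monte-Carlo standard errors well inside the asserted tolerances: 10⁴
replicates for single-lineage fate and bottleneck-unbiasedness checks, 2 × 10⁴
growth replicates for the mutation-supply cross-check, 2,000 null replicates
for the permutation-test size check, cohorts of 50 hosts per condition for
estimator bias, and 100 replicate series per selection strength for fixation
ordering. Replicate-series properties use a scaled-down passage scheme
(inoculum 10⁵, capacity 10⁴, 5 hosts) that preserves the regime structure
(severe fixed bottleneck, fractional ventings, growth to capacity) while
keeping each series to a few hundred generation updates.
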
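---
title: "Inferring the order and timing of population divergence with coalescent ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the order and timing of population divergence with coalescent ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalabc)
library(tibble)
```

## The inference problem

`coalabc` implements likelihood-free (approximate Bayesian computation, ABC)
inference for the demographic history of a set of regional populations
sampled at a single, fully linked mitochondrial locus. The motivating system
is a phylogeographic design with three mainland populations of the New World
screwworm fly — a South Amazon group (SAG, 249 sequences), a North Amazon
group (NAG, 53) and a North/Central American group (NC, 15) — typed at a
combined 1752-bp mtDNA fragment with high haplotype diversity (~0.95–0.97),
low nucleotide diversity (~0.004) and no haplotypes shared between groups.
The scientific questions are the *order* of the two population splits
(north-first or south-first), their *timing*, and whether post-divergence
*admixture* between the Amazonian groups is needed to explain the data.

Because a single non-recombining locus carries limited information, the
analysis is cast as a comparison of eight fully specified demographic
scenarios (`Sc1`–`Sc8`) under a common prior system, followed by parameter
estimation under the winning scenario and a posterior-predictive check.

## The generative model

Each simulated dataset is produced in three stages.

**Structured coalescent.** Lineages are traced backward in time. Within a
population of haploid size $N$ (effective number of mtDNA gene copies;
maternal lineages), each pair coalesces at rate $1/N$ per generation.
Demographic events act instantaneously at their drawn times: a *merge*
moves every lineage of a source population into a destination (a
forward-time split), an *admixture pulse* moves each lineage of a target
population to a donor independently with the drawn rate, and a *resize*
changes a population's size stepwise (a forward-time expansion when the
older size is smaller). Waiting times between events are exact
exponentials; there is no time discretization. Ties between simultaneous
events are resolved in listed order. There is no continuous growth and no
ongoing migration — admixture is a pulse, by design.

**Sequence evolution.** The locus evolves under HKY with a proportion
$p_{inv} = 0.92$ of invariant sites and gamma-distributed rate
heterogeneity (shape 2) on the remaining sites. Site rates are drawn once
per dataset, shared across branches, and rescaled so their mean over *all*
sites is 1; the HKY generator is scaled to unit stationary rate. The drawn
mutation rate $\mu$ (per site per generation) is therefore the realized
mean rate. Whether the original simulation machinery drew "92% invariant"
as a fixed count or per-site probability is not documented; we use a
per-site probability. The transition/transversion ratio and base
frequencies are not documented either; we default to $\kappa = 2$ and
equal frequencies, both configurable (including empirical frequencies via
`empirical_base_freqs()`). Mutations are placed by exact event-level
sampling: a Poisson/jump-chain scheme when base frequencies are equal
(state-independent leaving rates), otherwise per-branch Gillespie
simulation with state-dependent rates; the two samplers agree in law and
are cross-checked in the test suite.

**Summary statistics.** Each dataset is reduced to the fixed 12-statistic
vector: per population the number of haplotypes, the number of segregating
sites and the mean number of pairwise differences, plus the three pairwise
$F_{ST}$ values. For the ABC vector we use the Hudson estimator
$F_{ST} = 1 - H_w/H_b$ with unweighted within-population averaging — the
common sequence-based choice for ABC reference tables; the estimator used
by the original ABC software is not stated, which is a comparability
caveat. Negative estimates are kept as computed (information for the
regression step); clamp only for display. The descriptive report
(`diversity_report()`) is a separate code path: haplotype and nucleotide
diversity with Nei's sampling variances, and an AMOVA-style $\Phi_{ST}$
with a label-permutation test, mirroring how such tables are produced by
population-genetics software rather than by the ABC machinery.

## Scenarios, priors and constraints

The prior system (`default_priors()`) is uniform on every parameter in its
native units, including the mutation rate on $[10^{-11}, 10^{-7}]$ (a
log-uniform switch exists but uniform-on-the-rate is the fidelity choice).
The joint prior is truncated by the inequality constraints
$t_{exp} \le t_2 < t_3$, $N_{anc} < N_{NC} \le N_{NAG} \le N_{SAG}$ and
$N_1..N_8 > N_{anc}$, with $t_{adm1} < t_2$ and $t_2 < t_{adm2} < t_3$ in
the admixture scenarios (the upper bound on $t_{adm2}$ is our addition —
the pulse must precede the root merge to be meaningful). Sampling is by
rejection from the unconstrained joint, so accepted draws follow the
truncated prior exactly; a test compares the marginals against an
independent brute-force filter.

`Sc1`–`Sc3` place the older split ($t_3$) between NC and the common South
American ancestor and the younger split ($t_2$) between NAG and SAG;
`Sc4`–`Sc6` mirror the order. Within each triple the scenarios differ in
the expansion regime: one shared expansion time (`Sc1`/`Sc4`), independent
per-population expansion times (`Sc2`/`Sc5`), or expansions coincident with
the divergence events (`Sc3`/`Sc6`). The exact epoch-size wiring of the
study design is conveyed only graphically and cannot be recovered from
text, so we fix a documented convention: `N1`–`N3` are the per-population
pre-expansion sizes, `N4` the ancestral branch size between the splits, and
`N5`–`N8` remain available to user-defined scenario files (the prior
constrains all eight above `N_anc`). `Sc7` adds an NAG→SAG pulse (rate
`ra`) at $t_{adm1} < t_2$. `Sc8` is the more ambiguous "older admixture"
case. We implement it the way admixture events work in the standard
scenario grammar (an admixed population is *founded* from two parents and
its branch terminates there): SAG originates at $t_{adm2}$ as an admixture
of the NAG lineage (rate `rb`) and the ancestor's direct continuation,
which below $t_3$ is carried by the NC branch; the admixed founding takes
the place of the $t_2$ split, with $t_{exp} \le t_{adm2} < t_3$. An
earlier ghost-branch reading (SAG persisting above its founding and
receiving a pulse) makes Sc8 strictly more flexible than Sc1 and able to
out-fit it on Sc1's own data, which is both inexpressible in the original
grammar and destroys the identifiability the scenario set is meant to
have; we therefore rejected it. `rc` stays in the prior set for user
scenarios, and all of this is overridable through scenario files.
Scenario files are versioned YAML (`write_scenario()` / `read_scenario()`),
so all of these conventions can be overridden without touching code.

Effective sizes are used directly as haploid coalescent sizes, appropriate
for a maternally inherited marker; no ploidy/sex scaling is applied (none
is documented for the study design), and a user can rescale the priors if
a different convention is wanted.

## The ABC machinery

**Reference table.** `build_reference_table()` repeats
draw → genealogy → sequences → statistics per scenario. The desk-scale
default used throughout the package's own experiments is $10^4$ simulations
per scenario with selection fraction 0.01; the original design's
$10^6$/0.1–1% is a configuration, not a different code path. Tables carry
their seed and per-scenario counts, serialize to CSV with a manifest
header, and concatenate via `bind_reference_tables()` for checkpointed
builds.

**Rejection.** Statistics are standardized by their reference-table
standard deviation (MAD available by option; the normalization used by the
original software is unstated, SD is the conventional choice). The
`ceiling(f n)` records closest in Euclidean distance are kept, ties broken
by record index. A statistic that is constant across the table is given
unit scale and therefore contributes nothing.

**Scenario choice.** Scenario identity is regressed on the standardized
statistic deviations by multinomial logistic regression (`nnet::multinom`)
over the selected records, and fitted probabilities are evaluated at the
observed point, where the linear predictor reduces to the intercepts. The
95% confidence intervals use the asymptotic covariance of the ML estimator
via the delta method on the intercepts — the source describes "the
limiting distribution of the maximum likelihood estimators" without
mechanics, and this is our concrete reading. Complete separation (easy
with well-separated scenarios) triggers a weakly regularized refit
(`decay = 0.01`) with a warning. The direct rejection frequency is always
reported alongside as a cross-check; on well-separated synthetic problems
the two agree closely, but this is logged by the experiments rather than
asserted as an invariant.

**Parameter estimation.** Local-linear regression adjustment in the
Beaumont style: each parameter is mapped through a logit over its prior
interval, regressed on the standardized statistic deviations with
Epanechnikov kernel weights over the rejection distance, and the residuals
about the fit at the observed point are back-transformed. The logit
guarantees adjusted draws inside the prior box; it does not re-impose the
inequality constraints, so consumers that must simulate from the posterior
(the model check) reject and redraw the rare violating parameter sets.
A singular design falls back to a ridge-regularized solve with a warning.
Summaries are the weighted mean, median, 2.5%/97.5% quantiles (step-interpolated
weighted quantiles) and a mode from a Gaussian kernel density with
Silverman's bandwidth on the weighted sample — a mode estimator is needed
for comparability with mode-centred reporting, and this is the standard
default.

**Model check.** `abc_model_check()` draws parameter sets from the
weighted posterior, simulates pseudo-observed datasets, and reports where
each observed statistic falls in its posterior-predictive distribution as
a mid-p position $P(sim < obs) + \tfrac12 P(sim = obs)$ plus the two-sided
version; with one pseudo-observed dataset the mid-p is 0, ½ or 1 by
construction.

**Time scales.** Split times are simulated in generations and reported in
years through the adult life-history model $T = \alpha + s/(1-s)$ days per
generation, with $\alpha = 20$ d and daily survival $s = 0.798$ giving
$T = 23.95$ d; `posterior_times()` produces the side-by-side
generations/years summaries. Full precision is kept internally; rounding
is display-only.

## The synthetic-data generator

`generate_pseudo_observed()` and `make_benchmark_suite()` produce
study-like datasets with known ground truth: the default `study_template()`
fixes the 249/53/15 sampling design, the 1752-site locus and the HKY+I+Γ
settings above. `sc1_reference_params()` centres the ground-truth preset on
posterior-mode-like values for the single-expansion north-first history
(present-day sizes $2.08\times10^6 / 5.75\times10^5 / 9.8\times10^4$,
splits at 233k and 139k generations, shared expansion at 110k), with
$\mu = 1.47\times10^{-8}$ — a rate chosen to put simulated nucleotide
diversity near the observed ~0.004 rather than taken from the very wide
rate prior. Under this preset the generator reproduces the qualitative
pattern of the real data (no NC haplotypes shared with the South American
pool, nucleotide diversity ~0.002–0.004); haplotype diversity for the
Amazonian samples lands at or slightly above the observed 0.95–0.97 while
the small NC sample falls below it — a reminder that a single-locus
template cannot be tuned to every observed margin at once (the test suite
logs these calibration values on every run). The generator
emulates the *structure* of the study data, not its content: it does not
attempt the real haplotype network, the island groups, or the observed
230-haplotype composition, so passing recovery experiments demonstrate
internal consistency of the machinery, not correctness of any historical
claim about the real populations.

Truth records (scenario, parameters, seeds) are written beside each
dataset and are sufficient to re-simulate it bit-exactly; datasets
round-trip through FASTA + population-map files unchanged.

## Experiment sizes and numerical choices

The package's own validation experiments (the heavier blocks of the test
suite) use sizes chosen to make the Monte-Carlo noise small relative to
the assertions while staying desk-scale: $10^4$ replicates for the
pairwise-coalescence and Watterson checks, $10^4$ simulations per scenario
for the recovery experiment (20 pseudo-observed datasets), and 100
datasets for the credible-interval coverage experiment at selection
fraction 0.01. The recovery experiment follows the hierarchical protocol
(divergence scenarios first, then admixture, then best against best) and
asserts recovery among the six divergence scenarios: because `Sc7`/`Sc8`
nest `Sc1` at extreme admixture rates, an "is the truth ranked first"
question against them is not well-posed for a single locus — the data
cannot refute a nearly-zero pulse — so the full-protocol outcome is
reported but not asserted. The ground truth for recovery uses a strong
shared-expansion signature with the NAG/SAG split inside every competing
scenario's reachable range, the "well-separated" regime where the six
divergence histories make distinct predictions. Other choices worth knowing: coalescence uses the
continuous-time approximation (sizes here are far above the regime where
discrete generations matter); equal event times execute in listed order;
the logit transform clamps at $10^{-9}$ relative to the interval to keep
boundary draws finite; weighted quantiles use step interpolation; and the
rejection distance of the farthest selected record defines the
Epanechnikov bandwidth, so the boundary record gets weight zero (uniform
weights are substituted in the degenerate all-equal-distance case).

## Limitations

Beyond the explicit non-goals (no recombination, no continuous growth, no
ongoing migration, no serial sampling, no multi-locus support), the main
caveats are: the $F_{ST}$ estimator and several substitution-model
constants of the original pipeline are undocumented and were fixed here by
convention; scenario `Sc8`'s wiring and the epoch-size assignments are
interpretations of a graphical description; and single-locus mtDNA data
have limited power to separate nested expansion regimes, so scenario
probabilities among the close alternatives (`Sc1`–`Sc3`) should be read
with the same caution the original analysis applies.
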
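# coalabc

Coalescent-based approximate Bayesian computation (ABC) for inferring the
order and timing of divergence among regional populations sampled at a
single linked mitochondrial locus.

The package targets a common phylogeographic design: a few regional
populations (here SAG, NAG and NC — South Amazon, North Amazon and
North/Central America, sampled at 249/53/15 mtDNA sequences of a combined
1752-bp fragment), a set of competing demographic scenarios that differ in
split order, expansion regime and admixture, and the question of which
history explains the data and on what time scale. Because the likelihood of
sequence data under such histories is intractable, inference is
simulation-based:

1. **Simulate.** For each scenario `Sc1`–`Sc8`, draw parameters from the
   prior (uniform intervals truncated by `t_exp <= t_2 < t_3`,
   `N_anc < N_NC <= N_NAG <= N_SAG`, `N1..N8 > N_anc`), run a structured
   coalescent (splits, admixture pulses, stepwise size changes), and evolve
   the locus under HKY with 92% invariant sites and gamma(2) rate
   heterogeneity.
2. **Summarize.** Reduce each dataset to 12 statistics: per-population
   haplotype counts, segregating sites, mean pairwise differences, and the
   three pairwise Hudson F_ST values (`F_ST = 1 - H_w/H_b`).
3. **Compare and estimate.** Keep the simulations closest to the observed
   vector (standardized Euclidean distance); fit a multinomial logistic
   regression of scenario on statistic deviations to get posterior scenario
   probabilities with asymptotic 95% CIs; adjust the accepted parameters by
   weighted local-linear regression on a logit scale (Beaumont-style) to get
   posterior summaries; convert split times to years via the life-history
   generation time `T = alpha + s/(1-s)` (23.95 days at `alpha = 20`,
   `s = 0.798`).
4. **Check.** Simulate from the fitted posterior and locate every observed
   statistic in its posterior-predictive distribution.

A synthetic-data module generates study-like datasets with known ground
truth (FASTA + population map + truth record), so the whole pipeline is
testable without any sequence download. Descriptive diversity tables
(haplotype/nucleotide diversity with SDs, AMOVA-style Phi_ST with
permutation p-values) are included for reporting.

## Worked example

Simulate a pseudo-observed dataset under the single-expansion north-first
history (`Sc1`) with a clearly separated parameter set, then run the ABC
analysis against a desk-scale reference table. The comparison follows the
hierarchical protocol: the six divergence-only scenarios are compared
first (the admixture scenarios nest `Sc1` at extreme rates and are
compared in their own stage).

```r
library(coalabc)
library(tibble)

template <- study_template()                  # 249/53/15 samples, 1752 sites
truth <- tibble(N_SAG = 2e6, N_NAG = 5e5, N_NC = 1e5,
                N1 = 5000, N2 = 4000, N3 = 3000, N4 = 5000, N_anc = 1500,
                t_exp = 7e4, t_2 = 2.5e5, t_3 = 7e5, mu = 2e-8)
pod <- generate_pseudo_observed("Sc1", params = truth,
                                template = template, seed = 42)
obs <- summary_vector(pod$alignment)
obs
#> # A tibble: 1 x 12
#>   nhap_SAG nhap_NAG nhap_NC segs_SAG segs_NAG segs_NC mpd_SAG mpd_NAG mpd_NC
#>      <dbl>    <dbl>   <dbl>    <dbl>    <dbl>   <dbl>   <dbl>   <dbl>  <dbl>
#> 1      120       37       9       95       53      13    4.72    4.71   3.26
#> # i 3 more variables: fst_SAG_NAG 0.799, fst_SAG_NC 0.897, fst_NAG_NC 0.886

specs <- lapply(paste0("Sc", 1:8), build_scenario)
tbl <- build_reference_table(specs, n_per_scenario = 2000,
                             config = template, seed = 1)   # ~45 s

div <- tbl[tbl$scenario %in% paste0("Sc", 1:6), ]
mc  <- abc_model_choice(rejection_select(div, obs, fraction = 0.01))
tidy(mc)
#> # A tibble: 6 x 6
#>   scenario n_selected freq_direct      prob  conf_low conf_high
#>   <chr>         <int>       <dbl>     <dbl>     <dbl>     <dbl>
#> 1 Sc1              26       0.217 9.50e-  1 8.01e-  1 1   e+  0
#> 2 Sc2              23       0.192 4.97e-  2 0         1.99e-  1
#> 3 Sc3               0       0     0         0         0
#> 4 Sc4              30       0.25  4.11e-198 4.11e-198 4.11e-198
#> 5 Sc5              41       0.342 1.39e-197 1.39e-197 1.39e-197
#> 6 Sc6               0       0     0         0         0
```

The logistic regression evaluated at the observed point puts the
generating scenario first (`Sc1`, p = 0.95) against its nested relative
`Sc2` (independent expansion times); the mirrored-order scenarios
`Sc4`/`Sc5` appear among the raw nearest records (`freq_direct`) but get
essentially zero regression probability. Parameter estimation under the
winning scenario, with split times in generations and years:

```r
tbl1 <- tbl[tbl$scenario == "Sc1", ]
post <- abc_estimate(rejection_select(tbl1, obs, fraction = 0.05),
                     build_scenario("Sc1"))
posterior_times(post)
#> # A tibble: 6 x 7
#>   term     mean  median    mode    q025    q975 unit
#>   <chr>   <dbl>   <dbl>   <dbl>   <dbl>   <dbl> <chr>
#> 1 t_2   271809. 284877. 307223. 139261. 343345. generations
#> 2 t_2    17823.  18680.  20146.   9132.  22514. years
#> 3 t_3   726933. 730999. 710566. 401524. 978634. generations
#> 4 t_3    47667.  47934.  46594.  26329.  64172. years
#> 5 t_exp  66530.  63902.  62269.  60358.  86588. generations
#> 6 t_exp   4363.   4190.   4083.   3958.   5678. years
```

The true values (t_2 = 250k, t_3 = 700k, t_exp = 70k generations) sit
inside every 95% interval, and the year scale follows from the 23.95-day
generation time. A posterior-predictive check flags nothing:

```r
chk <- abc_model_check(build_scenario("Sc1"), post, obs,
                       config = template, n_pod = 200, seed = 3)
all(tidy(chk)$p_two_sided > 0.05)
#> [1] TRUE
```

At less separated parameter values (splits closer together, posterior-mode
scale as in `sc1_reference_params()`), a single mtDNA locus identifies the
split *order* only weakly in any one dataset — the same limitation the
hierarchical protocol and the credible intervals are designed to expose
rather than hide.

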
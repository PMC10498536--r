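# discountnet

Graph-theoretical analysis of gray-matter **structural covariance networks**
in groups defined by **delay discounting** — the behavioral economist's index
of impulsive choice.

People discount the value of delayed rewards hyperbolically: a reward of
amount *A* delivered after *D* days is worth

&nbsp;&nbsp;&nbsp;&nbsp;*SV* = *A* / (1 + *k·D*)

where *k* (per day) is the individual discount rate. Given a series of
choices between a fixed immediate reward and larger delayed rewards, each
subject's *k* and choice sensitivity *β* are estimated by maximum likelihood
under a logistic choice rule, *P*(choose delayed) = 1 / (1 + e^(−β(SV₁ −
SV₂))). Splitting a cohort at the median *k* yields high- and
low-discounting groups.

Brain regions whose gray-matter volumes covary across subjects within a
group form a *structural covariance network*: after residualizing regional
volumes against age, sex, education and total intracranial volume, the 90 ×
90 matrix of between-region Pearson correlations (AAL-90 parcellation) is
thresholded — negative correlations zeroed, then exactly the
⌊S·N(N−1)/2⌋ strongest edges kept at each sparsity S in 0.25–0.53 (step
0.01) so both groups have identical edge counts. On each binarized network
the package computes:

- **clustering coefficient** C_p and **characteristic path length** L_p,
- their normalized versions γ = C_p/C_p^rand and λ = L_p/L_p^rand against
  100 degree-preserving (Maslov–Sneppen) random networks,
- **small-worldness** σ = γ/λ (σ > 1 marks small-world organization),
- nodal **betweenness centrality** BC_i = Σ_{j≠i≠k} δ_jk(i)/δ_jk, normalized
  by the network mean, with hubs defined as nodes > mean + 1 SD.

Group differences in all of these are tested with nonparametric permutation
tests (random relabelings of the corrected volumes preserving group sizes;
two-sided add-one p-values; empirical 95% null bands), with nodal results
additionally screened at the node-count correction 1/N (0.011 for 90
nodes).

Because subject-level data of this kind are rarely shareable, the package
ships a **factor-model synthetic-data generator** with closed-form
correlation oracles: regions load on their own community's latent factor
(`within_loading`) and on the other communities' factors
(`between_loading`), plus demographic confounds and Gaussian noise. Every
pipeline stage is validated against this ground truth, including planted
group differences with a known direction.

## Worked example

```r
library(discountnet)

# 1. behavioral stage: one simulated subject, 120 trials, true k = 0.02
choices <- generate_choices(choice_config(k_true = 0.02, seed = 3), subject_id = "s01")
fit <- fit_discounting(choices)
fit[, c("k", "beta", "log_k", "neg_log_lik", "degenerate")]
#>            k       beta    log_k neg_log_lik degenerate
#> 1 0.02038142 0.01084495 -3.893132     2.81102      FALSE
```

The fitted discount rate (0.0204/day) recovers the generating 0.02; `log_k`
is the natural-log transform used for group statistics.

```r
# 2. network stage: two-group synthetic cohort, planted clustering deficit
scenario <- morph_scenario("planted", seed = 7)
tab <- residualize(generate_morphometry(scenario$high, scenario$low, seed = 7))
net <- zero_negatives(covariance_matrix(tab, "low"))
bin <- binarize_at_sparsity(net, 0.25)
bin
#> cov_network (group low): 90 regions, n = 35; binarized at sparsity 0.25 (1001 edges)

small_world(bin, n_random = 100, seed = 7)
#> Cp 0.9460  Lp 2.5184  gamma 4.018  lambda 1.438  sigma 2.793  (100 nulls, 0 disconnected pairs)
```

1001 edges is exactly ⌊0.25 · 4005⌋, and σ = 2.79 > 1 places the network
firmly in the small-world regime. Cohort-level demographics reproduce
standard pooled statistics, e.g. for two groups of 35 with ages
21.943 ± 2.920 vs 22.057 ± 2.555:

```r
two_sample_t_from_summaries(21.943, 2.920, 35, 22.057, 2.555, 35)$t_value
#> [1] -0.1738188   # df = 68
chi_square_2x2(21, 14, 18, 17)$chi_square
#> [1] 0.5210918
nodal_threshold(90)
#> [1] 0.011
```

The `analysis/` directory holds the numbered end-to-end workflow
(`01_simulate_cohort.R` → `04_group_inference.R`); each step writes its
tables under `results/` and prints what it found. On the default planted
scenario the high-discounting group shows lower clustering at all 29
thresholds (permutation p < 0.05 throughout) — the planted direction.

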
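---
title: "Methods: delay discounting, structural covariance networks, and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delay discounting, structural covariance networks, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discountnet)
```

This vignette documents the models, estimators and numerical conventions
behind `discountnet`, the choices made where the methods literature leaves
the design open, and what the synthetic validation does and does not
establish.

## The behavioral model

Each intertemporal choice pits a fixed immediate reward (10,000 KRW) against
a larger delayed reward (11,000–48,000 KRW at 2–180 days). Subjective value
is hyperbolic, $SV = A/(1 + kD)$ with the discount rate $k$ in units of
day$^{-1}$, and choices are stochastic through a logistic rule
$P_1 = (1 + e^{-\beta(SV_1 - SV_2)})^{-1}$, where $\beta$ (in units of
1/currency) scales how deterministically a subject follows the value
difference. Both parameters are fitted per subject by maximizing the
Bernoulli likelihood.

Design choices:

- **Estimation on the log scale.** The likelihood is optimized over
  $(\log k, \log\beta)$ with box-bounded L-BFGS-B, which enforces
  positivity without constrained optimization. Bounds are
  $k \in [10^{-6}, 10]$, $\beta \in [10^{-8}, 10]$ — generous on both sides
  of any behaviorally plausible value.
- **Multi-start.** The likelihood can be multimodal in $\beta$ when choices
  are nearly separable, so fits start from the grid
  $\log_{10} k \in \{-4,\dots,-1\} \times \log_{10}\beta \in \{-4,-3,-2\}$
  and keep the best converged optimum.
- **Degenerate choosers.** A subject choosing the same option on every
  trial carries no information about an indifference point; the likelihood
  is monotone in $k$ and flat in the limit. Such fits are flagged
  (`degenerate = TRUE`) with $k$ pinned at the search bound on the side the
  data point to, rather than reported as converged estimates.
- **Log transform.** `log_k` is the natural logarithm (with `log10_k`
  alongside); group statistics on $k$ should use the log scale, whose
  distribution across subjects is far closer to normal.
- **Numerical stability.** Choice probabilities and the log-likelihood go
  through `plogis(..., log.p = TRUE)`, which is accurate for
  $|\beta \,\Delta SV|$ of several hundred, so separable subjects do not
  produce `-Inf` likelihoods.

The cohort is split at the median $k$: above-median subjects form the
high-discounting group, below-median the low group. With an odd cohort the
single median scorer is excluded (leaving equal groups); two or more
subjects tied exactly at the median would make the split ill-defined and
raise an error rather than an arbitrary assignment.

## Structural covariance networks

Regional gray-matter volumes (90 regions, AAL-90 labels by default) are
first residualized against age, sex, education and total intracranial
volume by ordinary least squares with intercept, fitted **once over the
pooled cohort**. Correcting before the group split matches the
order of operations implied by permuting "corrected" volumes later; a
`scope = "within_group"` option exists for sensitivity analyses. OLS makes
the residuals exactly orthogonal to every covariate, idempotent under
re-residualization, and invariant to affine covariate recoding (so 0/1 vs
1/2 sex coding is immaterial). A rank-deficient covariate design is an
error that names the collinear columns.

Each group's network is the Pearson correlation matrix of the corrected
volumes across that group's subjects. Conventions:

- the diagonal is zeroed (no self-edges);
- strictly negative correlations are set to zero before thresholding, and
  the count of zeroed entries is logged;
- at sparsity $S$ exactly $\lfloor S \cdot N(N-1)/2 \rfloor$ strongest
  positive edges are kept. The floor guarantees the nominal sparsity is
  never exceeded and makes both groups' edge counts identical by
  construction. Ties at the cutoff (measure-zero on real data, certain on
  toy fixtures) are broken deterministically by weight, then row, then
  column index — making edge sets nested across increasing sparsity and
  results bit-reproducible;
- the sparsity grid 0.25–0.53 in steps of 0.01 (29 thresholds) is built
  with rounding to the step's decimal precision so floating-point drift
  cannot drop the endpoint.

## Graph topology

Clustering coefficient, characteristic path length and betweenness
centrality follow the standard binary-undirected definitions (nodes of
degree < 2 contribute clustering 0; betweenness counts each unordered pair
once with endpoints excluded). The implementations are igraph's; the test
suite certifies them *exactly* against brute-force oracles — triangle
enumeration, BFS distance matrices, and dynamic-programming shortest-path
counting — on hundreds of random graphs of up to 12 nodes.

**Disconnection policy.** Characteristic path length is averaged over pairs
with finite distance, and the number of infinite pairs is reported
alongside rather than silently dropped or mapped to an arbitrary constant.
At sparsity 0.25 a connectivity check warns when any node is isolated.
This keeps the rule auditable: a threshold network that fragments is
visible in every output table.

**Null model.** "Matched random networks" are degree-preserving
Maslov–Sneppen rewirings (10 attempted swaps per edge), the field standard
for covariance networks; an input admitting no swap (a complete graph)
yields nulls equal to the input with a warning. Normalized clustering
$\gamma$, normalized path length $\lambda$ and small-worldness
$\sigma = \gamma/\lambda$ use the mean over 100 nulls for observed
networks. Null seeds derive deterministically from the master seed with
fixed offsets per (group, threshold, permutation), so whole runs are
reproducible from one integer.

**Hubs.** Betweenness is normalized by the network mean (so normalized
values average exactly 1) and hubs are nodes exceeding mean + 1 sample SD
($N-1$ denominator; the convention is stated because the literature rarely
is). A zero-variance profile has no hubs; an all-zero betweenness vector
(complete graph) makes hub analysis undefined and errors.

## Permutation inference

Group differences (high minus low) in clustering, path length and $\sigma$
at every threshold — and in nodal normalized betweenness at sparsity
0.25 — are tested by randomly reassigning the *corrected* volumes to two
pseudo-groups of the original sizes. The covariate correction is **not**
refitted inside permutations: the correction is a preprocessing step of the
data, not part of the group comparison.

- p-values are two-sided with the add-one estimator
  $(1 + \#\{|T_{\text{perm}}| \ge |T_{\text{obs}}|\})/(1 + B)$, which never
  returns 0 and is valid at finite $B$.
- The 95% band is the empirical 2.5–97.5 percentile interval of the null
  differences, so the "observed point outside the gray band" display logic
  and the p < 0.05 decision agree up to permutation discreteness.
- $\sigma$ inside permutations uses a reduced null ensemble (default 20
  rewirings instead of 100) to keep $B \times 29$ threshold evaluations
  tractable; null means of $C_p$ and $L_p$ are stable enough that this
  changes only Monte-Carlo noise. The setting is recorded in the run
  manifest.
- Permutation replicates in which any stage fails (e.g. a pathological
  relabeling with too few positive correlations) are excluded and counted,
  never imputed.
- Nodal results are screened at p < 0.05 and at the node-count correction
  $1/N$ rounded to 3 decimals (0.011 for 90 nodes), which adapts
  automatically to other parcellation sizes.

Cohort demographics use the classical pooled-variance two-sample $t$
(df $= n_1 + n_2 - 2$), computable from summary statistics alone, and the
Pearson $\chi^2$ on 2×2 counts **without** continuity correction — the
convention that reproduces standard published demographic tables.

## The synthetic generator: what it emulates, what it does not

Volumes follow a community factor model: with $C$ communities, region $j$
in community $c$ loads `within_loading` on factor $c$ and `between_loading`
on each other factor, plus covariate effects and i.i.d. Gaussian noise.
This parameterization was chosen over direct covariance sampling because it
has a closed-form implied correlation matrix (`analytic_correlation()`,
exact oracle for every covariance-stage test) and because community
strength maps directly onto clustering, the quantity the analysis cares
about. When within- and between-loadings coincide the regions are fully
exchangeable and the implied correlation is uniform — a useful degenerate
check.

Defaults (chosen once as the reference study condition, then frozen): 35
subjects per group, 90 regions, 4 communities, within-loading 1.0,
between-loading 0.2, noise SD 0.6, and covariates on the demographic scales
of a young-adult cohort (age 22 ± 2.7 y, education 15 ± 1.3 y, TIV
1550 ± 150). These values put every binarized network in the small-world
regime ($\sigma > 1$) across the full 0.25–0.53 grid — the property that
motivates that threshold range in the first place. The `"planted"` scenario
lowers the high group's within-loading to 0.6, a segregation deficit strong
enough to be detectable by the permutation test at $n = 35$ per group; the
`"null"` scenario makes the groups exchangeable for type-I-error studies.

The generator deliberately omits several features of real morphometry:
spatial smoothness and inter-regional distance effects, non-Gaussian volume
distributions, site/scanner effects, and hemispheric symmetry. Passing
tests therefore establish that the *pipeline* is correct and calibrated —
not that real gray-matter covariance has this structure.

Two empirical limitations surfaced by the validation are worth knowing:

- **Nodal betweenness is volatile.** On binarized correlation networks of
  this size, per-node betweenness differences have permutation nulls widest
  exactly where effects are planted; single-cohort localization of a
  planted bridge community by smallest p-values is unreliable, and only the
  community-averaged difference across replicate cohorts singles it out.
  Nodal findings at $n \approx 35$ per group should be read accordingly.
- **$\sigma$ differences track both numerator and denominator.** Weakening
  within-community loadings lowers clustering and $\sigma$ together; the
  planted scenario fixes the direction of the clustering difference, not of
  $\sigma$ separately.

## Problem sizes used in the shipped validation

The test suite runs the full study geometry (90 regions, 35 + 35 subjects,
29 thresholds) wherever the check is about correctness, and scales
repetition counts to what the property needs: 400 null-scenario cohorts at
200 permutations each for type-I calibration, 200 simulated subjects for
discount-rate recovery, 100 nulls per threshold for the small-world regime
check, and 200 random small graphs for the exact oracle comparison. The
`analysis/` drivers default to 200 permutations with 50/10 observed/inner
nulls; the study-scale settings (1,000 permutations, 100 nulls) are the
`run_config()` defaults and scale runtime linearly.
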
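---
title: "Evaluating polygenic scores with the liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating polygenic scores with the liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsrisk)
```

## The problem

A polygenic risk score (PGS) summarises common-variant predisposition as a
weighted sum of allele dosages. For a screening programme the two questions
that matter are: how well does the PGS separate people who will develop the
disease within a fixed horizon from those who will not (discrimination), and
do the absolute risks we attach to PGS strata match what is actually
observed (calibration)? `pgsrisk` implements the full evaluation workflow
for 5-year risks across cohort and ancestry subgroups: scoring and
within-subgroup standardization, a liability-threshold mapping from
discrimination to relative risks, competing-risk life-table absolute risks,
and the discrimination/calibration machinery (AUC with stratified-bootstrap
intervals, paired DeLong comparisons, expected/observed ratios, case
capture, risk-threshold screening ages).

## The liability-threshold mapping

The core model treats the standardized PGS $Z$ and a latent liability $L$
as standard bivariate normal with correlation $\rho$; disease occurs within
the horizon iff $L > t = \Phi^{-1}(1-K)$, where $K$ is the case proportion.
Then

$$P(\text{case} \mid Z = z) = \Phi\!\left(\frac{\rho z - t}{\sqrt{1-\rho^2}}\right),$$

and dividing by $K$ gives the relative risk versus the population average
(`individual_relative_risk()`). Quantile relative risks
(`quantile_relative_risks()`) are means of this quantity over
equal-probability normal bins, by adaptive quadrature on $z \in [-8, 8]$
with absolute tolerance $10^{-9}$; their probability-weighted mean is 1 by
construction and the implementation refuses to return a table violating
this identity beyond $10^{-6}$.

The model is anchored to data through the observed AUC: conditioning on
case status truncates $L$, so the case and control $Z$ distributions have
truncated-normal means $\rho\phi(t)/K$ and $-\rho\phi(t)/(1-K)$ and matching
variances, and the binormal formula gives a closed-form AUC
(`auc_from_rho()`). This normal approximation (the case/control mixtures
are not exactly normal) was checked against $10^6$-draw simulations across
$\rho \in [0.1, 0.5]$, $K \in [0.02, 0.2]$: the error stays below 0.005
AUC, well inside the sampling noise of any cohort this size. The inverse
mapping (`rho_from_auc()`) is bracketed root finding with round-trip error
below $10^{-6}$; we chose the forward-model inversion over the
$d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$ shortcut because it is
self-consistent by construction ($d$ is still reported on the model object
for comparison with other software).

Two bin conventions coexist deliberately: *estimated* RRs use theoretical
standard-normal cut points (they are population quantities), while
*observed* RRs (`observed_quantile_rr()`) use equal-count empirical bins
with stable assignment of ties, so the sample is partitioned evenly.
Observed intervals use the Katz log method,
$\mathrm{SE}(\log RR) = \sqrt{1/x_i - 1/n_i + 1/X - 1/N}$; bins with zero
cases report $RR = 0$ with an undefined (NA) interval rather than applying
a continuity correction, because no correction rule is standard enough to
silently impose.

## Absolute risks under competing mortality

`age_specific_risk()` computes cause-specific cumulative incidence from a
rate table of piecewise-constant hazards per 5-year band (incidence
$\lambda_c$, competing mortality $\lambda_d$, both per person-year):

$$\text{risk} = \sum_j S_j\,\frac{\lambda_{c,j}}{\lambda_{c,j}+\lambda_{d,j}}
  \left(1 - e^{-(\lambda_{c,j}+\lambda_{d,j})\Delta_j}\right),$$

with $S_j$ the probability of being alive and event-free at the start of
sub-interval $j$. Because hazards are constant within bands the integration
is exact at band boundaries; a horizon crossing a boundary splits the final
band proportionally, and splitting a band into two with identical hazards
changes nothing (tested at $10^{-12}$). Sub-intervals with both hazards
zero contribute exactly zero (no 0/0). Ages outside the rate table are a
hard error, never an extrapolation — registry rates drive these numbers and
inventing them would be silently wrong, e.g. where screening-programme age
limits distort observed incidence in the oldest bands.

Age-PGS-specific risks multiply the band's absolute risk by the
individual's (or quantile's) relative risk (`age_pgs_risk()`). The product
is an approximation that can exceed 1 for extreme strata; it is capped at 1
with a warning rather than rescaled, keeping the convention transparent.

## Evaluation machinery

- `auc()` is the Mann–Whitney statistic with midrank ties.
- `bootstrap_auc_ci()` resamples cases and controls separately
  (stratified), keeping every replicate's case/control sizes fixed, and
  returns the percentile interval (not BCa — the percentile interval is
  what common ROC tooling reports, and pinning the choice makes the tests
  exact).
- `delong_test()` uses the placement-value covariance for paired AUCs. A
  comparison between rank-identical scores has zero variance; it is
  reported as degenerate with $\Delta\mathrm{AUC}=0$ and NA p-value instead
  of a meaningless z-statistic.
- `expected_observed()` uses $\mathrm{SE}(\log E/O) = 1/\sqrt{O}$ for
  whole-cohort designs. For case-cohort designs (a random sub-cohort plus
  all cases, with weight $1/f$ on sub-cohort non-cases and 1 on cases) the
  interval comes from a stratified bootstrap resampling sub-cohort members
  and outside-sub-cohort cases separately (B = 1000 by default); the robust
  variance recipe is not standardised across the literature, so the
  bootstrap is this package's documented choice.
- `stratified_evaluate()` applies the reporting rules: prevalent cases are
  excluded from the incident analysis set (a sensitivity mode includes them
  as cases), and strata with fewer than 10 incident cases are skipped and
  listed rather than reported with unstable estimates.
- `case_capture()` includes boundary ties in the top group, so "top 10%"
  never silently shrinks below a tenth of the sample.
- Exported tables suppress counts of five or fewer as "≤5", the
  confidentiality convention for small cohort cells.

## What the synthetic generator does and does not emulate

`simulate_liability_cohort()` draws cohorts from exactly the
bivariate-normal liability structure the estimator assumes, with
configurable $\rho$, prevalence, age-band weights (defaults available at
the five built-in cohort-subgroup profiles of
`cohort_subgroup_profiles()`, at reduced scale) and per-group raw-score
location/scale shifts. `simulate_event_time_cohort()` replaces the scalar
prevalence with competing exponential clocks per age band, re-drawn at
band boundaries, optionally multiplying the incidence hazard by the
liability-model relative risk. `simulate_case_cohort()` adds the
case-cohort design, `simulate_pc_mixture()` isotropic ancestry clusters in
4-PC space, and `simulate_genotypes_and_weights()` independent
Hardy–Weinberg variants with known true scores.

Because the generator and the estimator share the model, passing tests
demonstrate *internal* consistency — correct formulas, correct inversion,
correct intervals — not that real cohorts follow the model. Real data add
linkage disequilibrium, ancestry-specific effect attenuation,
age-dependent $\rho$, screening-driven ascertainment and healthy-volunteer
bias, none of which are simulated. That is precisely why the evaluation
functions take observed cohort tables as first-class inputs.

All generators fan a single global seed into per-operation substreams
keyed by fixed labels (`substream_seed()`), so adding one randomised
operation to a pipeline never perturbs another's draws, and every run is
bit-reproducible.

## Numerical and design choices

- Standardization uses the sample (n−1) SD; the tests pin the convention
  (raw scores 1, 2, 3 map to Z-scores −1, 0, 1).
- Missing dosages: `"mean_impute"` (default) substitutes twice the
  effect-allele frequency estimated from non-missing samples, keeping the
  denominator at the full variant count, mirroring common scoring-tool
  behaviour; `"drop"` removes the variant from that sample's numerator and
  denominator. Samples with no usable variants are flagged, never scored 0.
- Allele harmonization matches by variant id first, then by
  chromosome/position with strand-ambiguous A/T and C/G pairs excluded
  from the fallback; swapped alleles are scored on the complemented dosage
  $2 - d$, which leaves raw scores bit-identical.
- Ancestry assignment is Lloyd's k-means initialized at the supplied
  reference centroids (deterministic), Euclidean in 4-PC space, stopping
  when assignments stabilize or after 100 iterations; an emptied cluster
  keeps its centroid and triggers a warning instead of an error.
- Relatedness pruning removes one uniformly chosen member per listed pair,
  in input order, skipping pairs already broken.

## Problem sizes used in the test suite

Monte-Carlo oracle comparisons use $10^6$ draws (binomial/Katz
3-standard-error bands); parameter recovery uses a cohort of
$2 \times 10^5$ at $\rho = 0.25$, $K = 0.015$; the DeLong null simulation
uses 1000 replicates at 150 cases/150 controls; bootstrap-interval coverage
uses 500 whole-procedure replicates at 200/200 with B = 500. These sizes
make the stochastic checks sharp enough to catch formula errors while
keeping the full suite around a minute.

## Worked example

```{r, eval = FALSE}
rates <- rate_table(seq(40, 75, 5), seq(45, 80, 5),
                    c(1.2, 1.7, 2.1, 2.3, 2.6, 2.9, 3.1, 3.0) / 1000,
                    c(0.6, 0.9, 1.4, 2.2, 3.5, 5.6, 9.0, 14.0) / 1000)
sim <- simulation_config(20000, rho = 0.22, prevalence = 0.021,
                         age_band_weights =
                           subgroup_age_band_weights("QSkin-EUR"),
                         seed = 42)
res <- run_pipeline(analysis_config(sim = sim, rates = rates, seed = 42))
res$evaluation$auc
res$quantile_rr
res$crossing
```

## Known limitations

- The multiplicative age × RR combination ignores the (small) feedback of
  PGS strata on the competing-mortality term.
- The AUC↔ρ mapping assumes a single $\rho$ per subgroup; age-varying
  discrimination is visible only through stratified evaluation, not in the
  model itself.
- Calibration intervals for case-cohort designs are bootstrap percentile
  intervals; for very small case counts they can be wide and asymmetric.
- No time-to-event C-statistics, reclassification indices or
  decision-curve analysis; no PGS training, imputation or kinship
  inference.
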
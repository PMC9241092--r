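---
title: "Quantifying the effects of gender-age-imbalanced sampling and missing covariates on norm-health models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalanced sampling and missing covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normgaps)
```

## The problem

Global household surveys such as the DHS routinely under-sample men and
adolescents. When a research question concerns *community-level* social
norms — here, the discordance between adults' professed attitudes and their
apparent behaviours regarding pre-marital sex — and an *individual-level*
outcome — adolescent HIV status — gender-age-imbalanced sampling and wholly
unasked covariates may both distort the estimated association. `normgaps`
implements, as a tested and reusable pipeline, a simulation framework for
measuring those distortions: a balanced synthetic survey with known ground
truth is resampled to the gender-age margins of imbalanced surveys, and the
shift in the fitted association is assessed with a bootstrap test for
effect-measure interaction; missing covariates are assessed with Wald tests
of fully adjusted against reduced models.

## The model

For adolescents (15–24 years) of one sex, the risk of prevalent HIV is
modelled log-linearly in the community discordance of adults (25–49 years)
of one sex, giving four sex-stratified pathways (female~female,
female~male, male~female, male~male):

$$\log \Pr(Y_{ic} = 1) = \beta_0 + \beta_1 D_{c}^{(g)} + \gamma' x_{ic},$$

where $D_c^{(g)}$ is the cluster-level discordance for adult gender $g$ in
units of 10 percentage points, and $x_{ic}$ collects individual demographic
covariates (age group, education, marital status, residence) and
community-level proportions of belief/behaviour items (IPV history, belief
in marital fidelity, belief that beating is justified, large partner age
difference, alcohol before sex). $\exp(\beta_1)$ is the prevalence ratio
(relative risk) per 10-pp discordance. Fitting is survey-weighted
modified-Poisson (log link on a binary outcome) via IRLS; variance is a
cluster-robust sandwich aggregated at the primary sampling unit.

**Discordance definition.** The cluster-level gap
$D = 10\,[\,p_\text{behaviour} - (1 - p_\text{attitude})\,]$ — the
design-weighted share of adults with apparent pre-marital sex behaviour
minus the share professing approval. The exact attitude/behaviour
constructions of the source study's appendix were not available; the gap is
isolated behind `discordance_gap()` and the `definition` argument of
`compute_discordance()` so that an alternative formula can be swapped in
without touching anything else. Cells with fewer than
`min_adults_per_cluster` (default 10) contributing adults are excluded from
modelling: proportions from a handful of adults are dominated by binomial
noise and can reach the degenerate extremes ($D = \pm 10$).

## The synthetic world

`generator_config()` defaults describe a Zambia-2007-like balanced survey,
chosen once:

* 300 clusters, 25 households per cluster, mean 1.4 eligible respondents
  per household — about 10,500 eligible respondents, matching the study's
  eligible sample of 10,562.
* Gender-age shares: 45.3% male; 28.9% of females and 26.8% of males aged
  15–24, split equally between 15–19 and 20–24 (the split is not printed
  anywhere; equal is the neutral choice).
* Eligibility behaviour: 55% / 90% of adolescents aged 15–19 / 20–24 report
  ever having sex; 80% of respondents have an HIV test result.
* Cluster-level norm proportions are logit-normal: attitude mean 0.75,
  behaviour mean 0.40, between-cluster SD 0.6 on the logit scale. That SD
  implies an intraclass correlation of roughly 0.10, typical of
  community-level attitude items.
* Baseline adolescent HIV risk 0.05 (female) and 0.025 (male); true
  same-gender slopes log(1.27) and log(1.37) per 10-pp discordance — the
  balanced-data prevalence ratios the framework is meant to recover — and
  null cross-gender slopes.
* Design weights are inverse stratum-by-cluster inclusion probabilities
  with mild log-normal variation (coefficient of variation ≤ 0.3):
  weighting machinery is exercised without dominating the variance.

The generator draws the *realised* per-cluster discordance (same function
and same minimum-adults threshold as the analysis) into the risk model, so
the fitted model is exactly correctly specified and the estimand equals the
generative parameter. Adolescents in cells below the adult threshold
receive the gender-mean exposure; they are excluded from any correctly
specified analysis anyway. Parameterisations whose realised risk exceeds 1
are *rejected with an error*, not truncated — truncation would silently
change the estimand. `generate_valid_survey()` redraws with derived
sub-seeds for simulation studies; the redraw count is recorded.

### Column dictionary

Respondent tables (generated, read or written as CSV) carry:

| column | meaning |
|---|---|
| `id`, `cluster_id`, `stratum_id`, `household_id` | record id; primary sampling unit; urban/rural design stratum; household |
| `gender`, `age_years`, `age_group` | binary sex proxy; age in years; `15-19` / `20-24` / `25-49` |
| `ever_had_sex`, `hiv_tested`, `hiv_positive` | eligibility indicators and HIV status (`hiv_positive` non-missing only when tested) |
| `design_weight` | inverse-inclusion-probability weight (recalculated after resampling) |
| `education`, `marital`, `residence` | `none/primary/secondary`; `never_formerly/currently`; `urban/rural` |
| `attitude_disapproves_premarital`, `behaviour_premarital` | adult norm indicators (NA for adolescents) |
| `ipv_history` ... `alcohol_before_sex` | the five belief/behaviour items |
| `disc_female`, `disc_male`, `cl_<item>` | attached cluster-level exposures (after `attach_cluster_exposures()`) |
| `imbalance`, `source_id` | merged datasets only: arm indicator and originating record |

**What the generator does not emulate:** non-response correlated with HIV
status, measurement error in self-reports, spatial correlation between
clusters, age-specific fertility of the norm items, or real DHS recode
structure. A green test therefore establishes that the *pipeline* behaves
as designed under its stated world, not that any particular real survey is
biased.

## Resampling and weight recalculation

`resample_to_distribution()` draws, uniformly with replacement within each
of the six gender-age cells, exactly the target count per cell — exact
marginal matching is guaranteed by construction. Records keep their
cluster/stratum identifiers; duplicated draws are distinct rows of the same
cluster.

The recalculated weight is the source weight times a per-stratum factor,
with two rules (`recalc_factor()`):

* **selection**: $w' = w \cdot N_s / m_s$. The expected recalculated
  weight mass of each stratum equals its source mass, i.e. the resampled
  dataset still *represents the source population*. A consequence — which
  we verified analytically and by simulation — is that the expected
  weighted estimating equations of the resampled arm coincide with the
  balanced arm's at every parameter value, so weighted analyses are
  asymptotically *immune* to the induced imbalance and the interaction
  test has no power against any mixture shift.
* **representative** (pipeline default): $w' = w \cdot W N_s / (M W_s)$.
  Total weight mass is conserved, but stratum weighted shares follow the
  *target* unweighted distribution: the resampled arm represents the
  imbalanced population it mimics. Only under this rule can imbalanced
  sampling shift weighted estimates at all — which is the phenomenon the
  framework exists to measure, and which the source study observed.

The exact recalculation formula of the study's appendix was unavailable;
both candidate readings of "adjust for the probability of resampling" are
provided, the mass-conserving one matching the stated design contract and
the representative one matching the observed behaviour of the method.

Cluster-level exposures (discordance, group-item proportions) are computed
once from the balanced source and carried by resampled rows as cluster
attributes. Re-estimating them per replicate would add exposure
measurement noise that differs between arms and break the interaction
test's null; computing them first corresponds to resampling rows of an
analysis-ready table.

## The interaction test and its p-value rule

For each of `B` merged replicates (balanced copy + resampled copy +
`imbalance` indicator), the interaction model adds `imbalance` and
`discordance × imbalance`. Replicate coefficients are aggregated as means
and SDs. The source study under-specifies how its summary p-values were
computed; three rules are implemented:

* `robust` (default): $z = \bar\beta / \widehat{\mathrm{se}}$ with
  $\widehat{\mathrm{se}}^2 = \overline{\mathrm{se}^2_\text{robust}} -
  s^2 (1 - 1/B)$, floored at $s^2/B$, referred to a $t_{B-1}$
  distribution. The per-replicate cluster-robust variances capture the
  survey-sampling noise shared by both arms plus the resampling noise; the
  across-replicate variance $s^2$ estimates the resampling component, of
  which averaging retains only $1/B$. This rule tests the superpopulation
  null of no effect-measure interaction and is calibrated under it
  (empirically: rejection ≈ 0.05 under a homogeneous generator).
* `mc_se`: $z = \bar\beta / (s/\sqrt{B})$. Tests the *conditional* null
  that resampling leaves this particular dataset's estimand unchanged —
  exact under selection weights, but anti-conservative under
  representative weights, where reweighting a finite sample shifts the
  estimand by $O_p(n^{-1/2})$ even without any effect modification.
* `replicate_sd`: $z = \bar\beta / s$, the rule the across-replicate
  mean-and-SD presentation suggests. Because the replicate mean
  concentrates while $s$ does not shrink, this rule is severely
  conservative (rejection ≈ 0 under the null at B = 25); it is retained
  for comparability, not recommended.

Relative risks are reported for both arms: balanced
$\exp(\bar\beta_\text{disc})$, imbalanced
$\exp(\overline{\beta_\text{disc} + \beta_\text{int}})$, each with a 95%
interval under the active rule, plus a flag for whether the imbalanced-arm
interval excludes the balanced-arm point estimate ("biased away from
baseline").

## Variance estimation

The sandwich uses the bias-reduced CR2 adjustment (per-cluster
$(I - H_{gg})^{-1/2}$ residual scaling in the working-WLS representation)
by default; the plain CR0 estimator with a $G/(G-1)$ factor is available.
With ~300 clusters CR0 measurably under-covers (simulated coverage ≈
0.90–0.92 at nominal 0.95); CR2 restores ≈ 0.93–0.95.

## Missing covariates

The six availability scenarios ship as an editable CSV matrix
(`inst/extdata/covariate_scenarios.csv`): IPV and partner-age-difference
items are unavailable to female-HIV models in scenarios {3,4,6} and {5,6};
alcohol-before-sex is unavailable to male-HIV models in scenarios
{2,4,5,6}; scenarios cover 5+9+2+5+1+3 = 25 surveys. `wald_full_vs_reduced()`
tests joint nullity of the scenario-removed coefficients with the full
model's robust covariance, reported as $F = W/\mathrm{df}$ with the
chi-square reference on $W$ (large survey n); a scenario removing nothing
for a pathway returns the defined no-op ($F = 0$, $p = 1$). The joint
imbalance-missingness variant applies the same test to the interaction
model on every replicate and refers the *mean* F to the same reference —
documented as approximate, mirroring the mean-F aggregation of the source
design.

## Inter-survey meta-analysis

Across targets, logistic regressions relate gender-age shares (entered one
at a time — 25 observations cannot support a joint model; a joint fit would
be requested explicitly and warned about) to whether the interaction was
significant (OR per 1 percentage point of share), and linear regressions
relate shares to the interaction coefficient and the RR (slope per unit
proportion). Constant outcomes are flagged inestimable; separation is
detected and flagged rather than trusted.

## Numerical choices and degenerate inputs

* GLM convergence tolerance 1e-10 (closed-form cases reproduce to 1e-8).
* Aliased nuisance columns are dropped; an aliased or exploding
  (|coefficient| > 20) exposure term flags the fit non-converged, and
  non-converged replicates are dropped with a logged count (summary flagged
  unreliable above 10% drop).
* All randomness derives from one master seed through named sub-streams
  (`derive_seed()`), so replicates are reproducible individually and the
  whole pipeline is byte-deterministic.
* Tidy CSVs print numerics at 6 significant digits in fixed column order
  for diff-stability.
* No multiple-testing correction across scenarios and pathways, matching
  the per-test 0.05 convention of the source design.

## Known limitations

* The discordance formula and the resampling weight formula are stated
  substitutes for unavailable appendix equations, isolated behind single
  functions.
* The mean-F reference for the joint missingness test is approximate.
* Preset six-stratum vectors beyond the printed marginals are illustrative
  averages, flagged as such in the shipped CSV.
* The framework compares variants of one underlying dataset; it cannot
  compare outcomes across genuinely different surveys.
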
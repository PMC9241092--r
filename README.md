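# normgaps

Survey programmes like the DHS routinely under-sample men and adolescents,
and many surveys never ask whole blocks of questions. `normgaps` is an R
package for quantifying what those *gender data gaps* do to a
community-norm epidemiology model: the association between adult
attitude–behaviour discordance regarding pre-marital sex (a cluster-level
exposure, in 10-percentage-point units) and adolescent HIV risk. It is
aimed at epidemiologists and survey methodologists who want to stress-test
norm–health models against realistic sampling imbalance before trusting
them.

The core machinery:

* a **synthetic multi-stage cluster survey generator** with a known
  log-linear risk model (`generate_survey()`), defaulting to a
  Zambia-2007-like balanced survey of ~10,500 eligible respondents with
  true prevalence ratios of 1.27 (female) and 1.37 (male) per 10-pp
  discordance;
* **eligibility, distribution and discordance construction**
  (`filter_eligible()`, `compute_distribution()`, `compute_discordance()`)
  and metadata screening by the inclusion rules (`screen_surveys()`);
* **stratified resampling with replacement** to any target gender-age
  distribution with design-weight recalculation
  (`resample_to_distribution()`, `bootstrap_merged()`), including packaged
  preset targets (`builtin_presets()`: balanced Zambia 45.3% male, Mali
  2006 at 20.8%, Haiti 2012 at 41.2%, Senegal 2010 with a 5.0% female
  adolescent share, ...);
* **survey-weighted modified-Poisson models** (log link on binary HIV
  status) with bias-reduced cluster-robust (CR2) variance
  (`fit_weighted_poisson()`), the **bootstrap test for effect-measure
  interaction** between discordance and the imbalance indicator
  (`interaction_test()`), **Wald tests** for the six covariate-availability
  scenarios (`wald_full_vs_reduced()`, `joint_imbalance_missingness()`),
  and an **inter-survey meta-analysis** (`fit_significance_logit()`,
  `fit_outcome_linear()`);
* a **pipeline driver** (`run_pipeline()`) producing a manifest, tidy
  CSVs and a plain-text report, byte-deterministic in its master seed.

The model, for adolescents of one sex and adult discordance of one sex
(four pathways), is

    log Pr(HIV) = b0 + b1 * D + gamma' x,   RR per 10 pp = exp(b1)

with D the cluster attitude–behaviour gap in 10-pp units and x individual
demographics plus community item proportions. See `vignette("methods")`
for assumptions, parameter defaults, and the design decisions (weight
recalculation rules, p-value rules, CR2 variance).

## Worked example

```r
library(normgaps)

world    <- generate_survey(generator_config(seed = 7))
eligible <- filter_eligible(world$data)
disc     <- compute_discordance(eligible)
eligible <- attach_cluster_exposures(eligible, disc,
              items = c("ipv_history", "belief_fidelity",
                        "belief_beating_justified",
                        "partner_age_diff_large", "alcohol_before_sex"))

reps <- bootstrap_merged(eligible, resample_spec(
  preset_target("MAI06", nrow(eligible)), n_bootstrap = 25, base_seed = 1))
summarise_rr(interaction_test(reps, model_spec("female", "female")))
```

which prints (seed 7):

```
  pathway      rr_balanced    rr_imbalanced interaction_p
1      ff 1.16 (1.06–1.28) 1.17 (1.06–1.28)       0.79211
  significant_interaction biased_away
1                   FALSE       FALSE
```

The balanced arm estimates a prevalence ratio of 1.16 per 10-pp
discordance with a 95% interval (1.06–1.28) covering the generative truth
of 1.27; resampling this survey to the Mali-2006 gender-age margins
(20.8% male) neither shifts the coefficient significantly (interaction
p = 0.79) nor biases the RR interval away from the balanced baseline —
with a homogeneous true effect, recalculated weights, and this one
target, imbalance alone does not distort the estimate.

A full experiment over several targets, pathways and missingness
scenarios:

```r
bundle <- run_pipeline(run_config(targets = c("MAI06", "HAI12", "SEN10"),
                                  B = 100, base_seed = 1,
                                  out_dir = "results/run1"))
cat(readLines(file.path("results/run1", "report.txt")), sep = "\n")
```

A thin CLI wrapper with `generate`, `resample`, `run-all` and `report`
subcommands ships at `inst/cli/normgaps-cli.R` (JSON configs mirroring
`run_config()`).

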
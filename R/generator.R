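#' Generator configuration for DHS-like synthetic surveys
#'
#' Builds and validates the configuration of the synthetic multi-stage cluster
#' survey generator. Defaults describe a Zambia-2007-like balanced survey:
#' 300 clusters of roughly 35 respondents (about 10,500 eligible respondents),
#' gender-age shares with 45.3% males and within-gender adolescent (15-24)
#' shares of 28.9% (female) and 26.8% (male) split equally between 15-19 and
#' 20-24, and a log-linear adolescent HIV risk model whose same-gender
#' discordance slopes are log(1.27) (female) and log(1.37) (male) per
#' 10-percentage-point discordance.
#'
#' @param n_clusters Number of primary sampling units (communities).
#' @param households_per_cluster Households sampled per cluster.
#' @param respondents_per_household Mean eligible respondents per household
#'   (each household draws `1 + Poisson(mean - 1)` respondents).
#' @param urban_fraction Fraction of clusters classified urban, in \[0, 1\].
#' @param gender_age_shares Named length-6 vector of probabilities over the
#'   gender-age strata (see [ga_strata()]), summing to 1.
#' @param baseline_hiv_risk Named per-gender baseline adolescent HIV
#'   probability at zero discordance and reference covariates, each in (0, 1).
#' @param true_log_rr_per_10pp Named log relative risks per 10-pp discordance
#'   for the four pathways `ff`, `fm`, `mf`, `mm` (first letter: adolescent
#'   outcome gender; second: adult exposure gender).
#' @param effect_modifiers Named length-6 vector of additive log-RR offsets to
#'   the same-gender discordance slope, by adolescent gender-age stratum
#'   (all zero = homogeneous effect).
#' @param covariate_effects Named log-RRs for covariates entering the risk
#'   model. Individual-level names: `urban`, `education_secondary`,
#'   `currently_married`. Group-level items (see `group_level_items`) act
#'   through mean-centred cluster-level adult proportions.
#' @param group_level_items Character vector of item covariates acting at the
#'   cluster (community) level; the rest act on the respondent's own indicator.
#' @param attitude_mean,behaviour_mean Population means of the cluster-level
#'   adult proportions disapproving of, and reporting, pre-marital sex.
#' @param cluster_sd Between-cluster standard deviation of norm and item
#'   proportions on the logit scale.
#' @param item_means Named population means of the five belief/behaviour items.
#' @param ever_sex_rates Named probabilities that an adolescent of each
#'   adolescent age group reports ever having had sex.
#' @param hiv_test_rate Probability a respondent has an HIV test result.
#' @param missingness_scenario Optional covariate-availability scenario id
#'   (1-6) applied to the generated dataset, see [enumerate_scenarios()].
#' @param min_adults_per_cluster Minimum adults per (cluster, gender) cell
#'   for the realised discordance entering the risk model; must match the
#'   analysis threshold for the fitted model to be correctly specified.
#' @param seed Integer master seed; the generator is bit-reproducible.
#'
#' @return An object of class `normgaps_config` (a validated list).
#' @export
generator_config <- function(n_clusters = 300L,
                             households_per_cluster = 25L,
                             respondents_per_household = 1.4,
                             urban_fraction = 0.4,
                             gender_age_shares = zambia_shares(),
                             baseline_hiv_risk = c(female = 0.05, male = 0.025),
                             true_log_rr_per_10pp = c(ff = log(1.27), fm = 0,
                                                      mf = 0, mm = log(1.37)),
                             effect_modifiers = NULL,
                             covariate_effects = default_covariate_effects(),
                             group_level_items = NORM_ITEMS,
                             attitude_mean = 0.75,
                             behaviour_mean = 0.40,
                             cluster_sd = 0.6,
                             item_means = default_item_means(),
                             ever_sex_rates = c(`15-19` = 0.55, `20-24` = 0.90),
                             hiv_test_rate = 0.80,
                             missingness_scenario = NULL,
                             min_adults_per_cluster = 10L,
                             seed = 1L) {
  if (is.null(effect_modifiers)) {
    effect_modifiers <- stats::setNames(rep(0, 6L), ga_labels())
  }
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    households_per_cluster = as.integer(households_per_cluster),
    respondents_per_household = respondents_per_household,
    urban_fraction = urban_fraction,
    gender_age_shares = normalise_named(gender_age_shares, ga_labels(),
                                        "gender_age_shares"),
    baseline_hiv_risk = normalise_named(baseline_hiv_risk, GENDERS,
                                        "baseline_hiv_risk"),
    true_log_rr_per_10pp = normalise_named(true_log_rr_per_10pp,
                                           c("ff", "fm", "mf", "mm"),
                                           "true_log_rr_per_10pp"),
    effect_modifiers = normalise_named(effect_modifiers, ga_labels(),
                                       "effect_modifiers"),
    covariate_effects = covariate_effects,
    group_level_items = group_level_items,
    attitude_mean = attitude_mean,
    behaviour_mean = behaviour_mean,
    cluster_sd = cluster_sd,
    item_means = item_means,
    ever_sex_rates = ever_sex_rates,
    hiv_test_rate = hiv_test_rate,
    missingness_scenario = missingness_scenario,
    min_adults_per_cluster = as.integer(min_adults_per_cluster),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "normgaps_config")
}

# Five belief/behaviour items used as (by default) group-level covariates
NORM_ITEMS <- c("ipv_history", "belief_fidelity", "belief_beating_justified",
                "partner_age_diff_large", "alcohol_before_sex")

default_item_means <- function() {
  c(ipv_history = 0.30, belief_fidelity = 0.60,
    belief_beating_justified = 0.35, partner_age_diff_large = 0.25,
    alcohol_before_sex = 0.20)
}

default_covariate_effects <- function() {
  c(urban = 0.25, education_secondary = -0.25, currently_married = 0.20,
    ipv_history = 0.15, belief_fidelity = -0.10,
    belief_beating_justified = 0.10, partner_age_diff_large = 0.20,
    alcohol_before_sex = 0.20)
}

#' Zambia-like balanced gender-age shares
#'
#' Six-stratum shares with 45.3% male respondents and within-gender
#' adolescent shares of 28.9% (female) and 26.8% (male), the adolescent block
#' split equally between 15-19 and 20-24.
#' @return Named length-6 numeric vector summing to 1.
#' @export
zambia_shares <- function() {
  shares_from_marginals(male_share = 0.453, adol_female = 0.289,
                        adol_male = 0.268)
}

# Build a 6-stratum share vector from three marginals (equal 15-19 / 20-24
# split within the adolescent block).
shares_from_marginals <- function(male_share, adol_female, adol_male) {
  f <- 1 - male_share
  out <- c(
    f * adol_female / 2, f * adol_female / 2, f * (1 - adol_female),
    male_share * adol_male / 2, male_share * adol_male / 2,
    male_share * (1 - adol_male)
  )
  stats::setNames(out, ga_labels())
}

normalise_named <- function(x, expected, what) {
  if (length(x) != length(expected)) {
    config_error(sprintf("%s must have %d entries (%s)", what,
                         length(expected), paste(expected, collapse = ", ")))
  }
  if (is.null(names(x)) || all(names(x) == "")) {
    names(x) <- expected
  }
  if (!setequal(names(x), expected)) {
    config_error(sprintf("%s must be named by %s", what,
                         paste(expected, collapse = ", ")))
  }
  x[expected]
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_clusters) || cfg$n_clusters < 1L) {
    config_error("n_clusters must be a positive integer")
  }
  if (cfg$households_per_cluster < 1L) {
    config_error("households_per_cluster must be a positive integer")
  }
  if (cfg$respondents_per_household < 1) {
    config_error("respondents_per_household must be >= 1")
  }
  if (cfg$urban_fraction < 0 || cfg$urban_fraction > 1) {
    config_error("urban_fraction must lie in [0, 1]")
  }
  s <- cfg$gender_age_shares
  if (any(s < 0) || abs(sum(s) - 1) > 1e-9) {
    config_error("gender_age_shares must be >= 0 and sum to 1 (tolerance 1e-9)")
  }
  b <- cfg$baseline_hiv_risk
  if (any(b <= 0) || any(b >= 1)) {
    config_error("baseline_hiv_risk must lie in (0, 1) for each gender")
  }
  for (p in c("attitude_mean", "behaviour_mean")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      config_error(sprintf("%s must lie in (0, 1)", p))
    }
  }
  if (cfg$cluster_sd < 0) config_error("cluster_sd must be >= 0")
  if (!is.null(cfg$missingness_scenario) &&
      !(cfg$missingness_scenario %in% 1:6)) {
    config_error("missingness_scenario must be in 1..6")
  }
  invisible(cfg)
}

#' Generate a synthetic multi-stage cluster survey
#'
#' Draws a respondent-level dataset emulating a DHS-style survey: clusters
#' nested in urban/rural strata, households within clusters, design weights
#' proportional to inverse inclusion probabilities with mild variation,
#' individual demographic covariates, adult attitude/behaviour indicators from
#' cluster-level logit-normal norm proportions, and adolescent HIV status
#' drawn from a log-linear (Poisson-type) risk model in the realised
#' cluster-level discordance. Parameterisations yielding a risk above 1 are
#' rejected with an error naming the offending gender-age stratum.
#'
#' @param config A [generator_config()].
#' @return A list with elements `data` (the respondent data.frame; see the
#'   package vignette for the column dictionary) and `truth` (a
#'   `synthetic_truth` object recording every generative parameter and the
#'   cluster-level norm draws).
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "normgaps_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  with_seed(derive_seed(config$seed, "generator", 0L), {
    gen <- generate_survey_impl(config)
  })
  gen
}

generate_survey_impl <- function(cfg) {
  K <- cfg$n_clusters
  # --- design: strata, clusters, households -------------------------------
  urban <- stats::rbinom(K, 1L, cfg$urban_fraction) == 1L
  cluster_w <- exp(stats::rnorm(K, 0, 0.15)) * ifelse(urban, 0.9, 1.1)
  hh_per_cluster <- cfg$households_per_cluster
  n_hh <- K * hh_per_cluster
  hh_cluster <- rep(seq_len(K), each = hh_per_cluster)
  hh_size <- 1L + stats::rpois(n_hh, max(cfg$respondents_per_household - 1, 0))
  n <- sum(hh_size)
  cluster_id <- rep(hh_cluster, times = hh_size)
  household_id <- rep(seq_len(n_hh), times = hh_size)

  # --- respondent demographics -------------------------------------------
  strata <- ga_strata()
  cell <- sample.int(6L, n, replace = TRUE, prob = cfg$gender_age_shares)
  gender <- strata$gender[cell]
  age_group <- strata$age_group[cell]
  lo <- c(`15-19` = 15L, `20-24` = 20L, `25-49` = 25L)[age_group]
  hi <- c(`15-19` = 19L, `20-24` = 24L, `25-49` = 49L)[age_group]
  age_years <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  adult <- age_group == "25-49"

  design_weight <- cluster_w[cluster_id] * exp(stats::rnorm(n, 0, 0.1))
  design_weight <- design_weight / mean(design_weight)

  education <- sample(c("none", "primary", "secondary"), n, replace = TRUE,
                      prob = c(0.15, 0.55, 0.30))
  marital <- ifelse(stats::runif(n) < ifelse(adult, 0.70, 0.25),
                    "currently", "never_formerly")
  residence <- ifelse(urban[cluster_id], "urban", "rural")
  ever_had_sex <- stats::runif(n) <
    ifelse(adult, 0.97, cfg$ever_sex_rates[age_group])
  hiv_tested <- stats::runif(n) < cfg$hiv_test_rate

  # --- cluster-level norm proportions (logit-normal) ----------------------
  norm_draws <- expand.grid(cluster_id = seq_len(K), gender = GENDERS,
                            stringsAsFactors = FALSE)
  norm_draws$attitude_p <- stats::plogis(
    stats::rnorm(nrow(norm_draws), stats::qlogis(cfg$attitude_mean),
                 cfg$cluster_sd))
  norm_draws$behaviour_p <- stats::plogis(
    stats::rnorm(nrow(norm_draws), stats::qlogis(cfg$behaviour_mean),
                 cfg$cluster_sd))
  att_mat <- matrix(norm_draws$attitude_p, nrow = K,
                    dimnames = list(NULL, GENDERS))
  beh_mat <- matrix(norm_draws$behaviour_p, nrow = K,
                    dimnames = list(NULL, GENDERS))
  gidx <- match(gender, GENDERS)
  attitude <- rep(NA, n)
  behaviour <- rep(NA, n)
  attitude[adult] <- stats::runif(sum(adult)) <
    att_mat[cbind(cluster_id[adult], gidx[adult])]
  behaviour[adult] <- stats::runif(sum(adult)) <
    beh_mat[cbind(cluster_id[adult], gidx[adult])]

  # --- belief / behaviour items (all respondents) -------------------------
  items <- names(cfg$item_means)
  item_p <- sapply(items, function(it) {
    stats::plogis(stats::rnorm(K, stats::qlogis(cfg$item_means[[it]]),
                               cfg$cluster_sd))
  })
  item_cols <- lapply(items, function(it) {
    stats::runif(n) < item_p[cluster_id, it]
  })
  names(item_cols) <- items

  data <- data.frame(
    id = seq_len(n), cluster_id = cluster_id,
    stratum_id = ifelse(urban[cluster_id], "urban", "rural"),
    household_id = household_id, gender = gender, age_years = age_years,
    age_group = age_group, ever_had_sex = ever_had_sex,
    hiv_tested = hiv_tested, hiv_positive = NA,
    design_weight = design_weight, education = education, marital = marital,
    residence = residence, attitude_disapproves_premarital = attitude,
    behaviour_premarital = behaviour, stringsAsFactors = FALSE
  )
  for (it in items) data[[it]] <- item_cols[[it]]

  # --- realised cluster discordance (same definition and minimum-adults
  # threshold as the analysis, so the fitted model is correctly specified;
  # adolescents of excluded cells get the gender-mean exposure and are not
  # part of any analysis anyway) ------------------------------------------
  disc <- compute_discordance(data, cfg$min_adults_per_cluster)
  kept <- disc[!disc$excluded, , drop = FALSE]
  dmat <- matrix(NA_real_, nrow = K, ncol = 2L,
                 dimnames = list(NULL, GENDERS))
  dmat[cbind(kept$cluster_id, match(kept$gender, GENDERS))] <- kept$discordance
  for (g in GENDERS) {
    miss <- is.na(dmat[, g])
    if (any(miss)) dmat[miss, g] <- mean(dmat[, g], na.rm = TRUE)
  }

  # --- cluster-level (group) covariates: centred adult proportions --------
  group_items <- intersect(cfg$group_level_items, items)
  cl_group <- sapply(items, function(it) {
    v <- cluster_item_proportion(data, it)
    v - cfg$item_means[[it]]
  })

  # --- log-linear adolescent HIV risk -------------------------------------
  adol <- !adult
  lp <- log(cfg$baseline_hiv_risk[gender[adol]])
  strat <- ga_label(gender[adol], age_group[adol])
  same <- ifelse(gender[adol] == "female", "ff", "mm")
  cross <- ifelse(gender[adol] == "female", "fm", "mf")
  slope_same <- cfg$true_log_rr_per_10pp[same] + cfg$effect_modifiers[strat]
  slope_cross <- cfg$true_log_rr_per_10pp[cross]
  d_f <- dmat[cluster_id[adol], "female"]
  d_m <- dmat[cluster_id[adol], "male"]
  d_same <- ifelse(gender[adol] == "female", d_f, d_m)
  d_cross <- ifelse(gender[adol] == "female", d_m, d_f)
  lp <- lp + slope_same * d_same + slope_cross * d_cross

  ce <- cfg$covariate_effects
  add_eff <- function(lp, nm, x) if (nm %in% names(ce)) lp + ce[[nm]] * x else lp
  lp <- add_eff(lp, "urban", as.numeric(residence[adol] == "urban"))
  lp <- add_eff(lp, "education_secondary",
                as.numeric(education[adol] == "secondary"))
  lp <- add_eff(lp, "currently_married",
                as.numeric(marital[adol] == "currently"))
  for (it in items) {
    if (!it %in% names(ce)) next
    if (it %in% group_items) {
      lp <- lp + ce[[it]] * cl_group[cluster_id[adol], it]
    } else {
      lp <- lp + ce[[it]] * as.numeric(item_cols[[it]][adol])
    }
  }

  p <- exp(lp)
  if (any(p > 1)) {
    worst <- strat[which.max(p)]
    param_error(sprintf(
      paste0("log-linear risk exceeds 1 (max %.3f) for stratum %s; ",
             "reduce baseline_hiv_risk, slopes, or cluster_sd"),
      max(p), worst))
  }
  hiv <- rep(NA, n)
  hiv[adol] <- stats::runif(sum(adol)) < p
  hiv[!hiv_tested] <- NA
  data$hiv_positive <- hiv

  if (!is.null(cfg$missingness_scenario)) {
    data <- apply_missingness_scenario(data, cfg$missingness_scenario)
  }
  attr(data, "normgaps_meta") <- list(provenance = "synthetic",
                                      source = "balanced")

  truth <- structure(list(
    config = cfg,
    true_log_rr_per_10pp = cfg$true_log_rr_per_10pp,
    effect_modifiers = cfg$effect_modifiers,
    covariate_effects = cfg$covariate_effects,
    cluster_norms = norm_draws,
    cluster_discordance = dmat,
    seed = cfg$seed
  ), class = "synthetic_truth")

  list(data = data, truth = truth)
}

# Weighted adult proportion of a binary item per cluster (vector over all
# cluster ids 1..K; NA-free via overall fallback)
cluster_item_proportion <- function(data, item) {
  adults <- data[data$age_group == "25-49", , drop = FALSE]
  K <- max(data$cluster_id)
  out <- rep(NA_real_, K)
  if (nrow(adults)) {
    x <- as.numeric(adults[[item]])
    w <- adults$design_weight
    keep <- !is.na(x)
    num <- rowsum((w * x)[keep], adults$cluster_id[keep])
    den <- rowsum(w[keep], adults$cluster_id[keep])
    out[as.integer(rownames(num))] <- num / den
  }
  out[is.na(out)] <- mean(out, na.rm = TRUE)
  out
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic survey truth (seed", x$seed, ")\n")
  cat("  true log RR per 10-pp discordance:\n")
  print(round(x$true_log_rr_per_10pp, 4))
  if (any(x$effect_modifiers != 0)) {
    cat("  effect modifiers (log-RR offsets):\n")
    print(round(x$effect_modifiers[x$effect_modifiers != 0], 4))
  } else {
    cat("  homogeneous effect (no modifiers)\n")
  }
  invisible(x)
}

#' Generate a survey, redrawing on risk-validation rejection
#'
#' [generate_survey()] rejects (rather than truncates) realisations whose
#' log-linear risk exceeds 1 — typically a small cluster cell whose sampled
#' adults are unanimous, yielding the extreme discordance of 10. For
#' simulation studies this helper redraws with deterministically derived
#' sub-seeds until a valid realisation appears, so the draw is a rejection
#' sample over valid worlds and remains reproducible. The number of
#' rejections is recorded in the truth object (`n_rejected`).
#'
#' @param config A [generator_config()].
#' @param max_tries Attempts before giving up.
#' @return As [generate_survey()].
#' @export
generate_valid_survey <- function(config, max_tries = 10L) {
  if (!inherits(config, "normgaps_config")) {
    config <- do.call(generator_config, config)
  }
  base <- config$seed
  for (try in seq_len(max_tries)) {
    config$seed <- if (try == 1L) base else
      derive_seed(base, "generator", 7919L * try)
    gen <- tryCatch(generate_survey(config),
                    error = function(e) {
                      if (inherits(e, "normgaps_param_error")) NULL else stop(e)
                    })
    if (!is.null(gen)) {
      gen$truth$n_rejected <- try - 1L
      return(gen)
    }
  }
  param_error(sprintf(
    "no valid realisation in %d tries; the parameterisation is too close to risk 1",
    max_tries))
}

#' Apply a covariate-availability scenario to a dataset
#'
#' Sets every response of each covariate that the scenario marks unavailable
#' to `NA`, emulating a survey in which the underlying questions were never
#' asked. The operation is idempotent; all other columns are untouched.
#'
#' @param dataset A respondent data.frame.
#' @param scenario A scenario id in 1..6 or a `covariate_scenario` object
#'   from [enumerate_scenarios()].
#' @return The dataset with unavailable covariate columns fully `NA`.
#' @export
apply_missingness_scenario <- function(dataset, scenario) {
  sc <- as_scenario(scenario)
  for (cov in unique(sc$unavailable$covariate)) {
    if (!cov %in% names(dataset)) {
      data_error(sprintf("covariate '%s' not present in dataset", cov))
    }
    dataset[[cov]] <- dataset[[cov]][NA]
  }
  dataset
}
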
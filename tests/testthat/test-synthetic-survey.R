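test_that("generation is bit-reproducible and seed-sensitive", {
  cfg <- quick_config(seed = 11)
  g1 <- generate_survey(cfg)
  g2 <- generate_survey(cfg)
  expect_identical(g1$data, g2$data)
  expect_identical(g1$truth$cluster_norms, g2$truth$cluster_norms)
  g3 <- generate_survey(quick_config(seed = 12))
  expect_false(identical(g1$data, g3$data))
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_clusters = 0), class = "normgaps_config_error")
  bad <- zambia_shares()
  bad[1] <- bad[1] + 0.05
  expect_error(generator_config(gender_age_shares = bad),
               class = "normgaps_config_error")
  expect_error(generator_config(gender_age_shares = rep(1 / 4, 4)),
               class = "normgaps_config_error")
  expect_error(generator_config(baseline_hiv_risk = c(female = 0, male = 0.1)),
               class = "normgaps_config_error")
  expect_error(generator_config(missingness_scenario = 9),
               class = "normgaps_config_error")
})

test_that("realised gender-age distribution matches configured shares", {
  # ~10,000 respondents; chi-square goodness of fit should not reject
  cfg <- generator_config(n_clusters = 100L, households_per_cluster = 25L,
                          respondents_per_household = 4.3, seed = 21)
  g <- generate_survey(cfg)
  counts <- compute_distribution(g$data)$counts
  expect_gte(sum(counts), 10000)
  p <- suppressWarnings(stats::chisq.test(counts,
                                          p = cfg$gender_age_shares)$p.value)
  expect_gt(p, 0.001)
})

test_that("null-effect worlds show no discordance-prevalence association", {
  cfg <- generator_config(
    seed = 31, true_log_rr_per_10pp = c(ff = 0, fm = 0, mf = 0, mm = 0),
    covariate_effects = c(urban = 0))
  g <- generate_survey(cfg)
  adol <- g$data[g$data$age_group != "25-49" & !is.na(g$data$hiv_positive), ]
  prev <- tapply(as.numeric(adol$hiv_positive), adol$cluster_id, mean)
  disc <- g$truth$cluster_discordance[as.integer(names(prev)), "female"]
  r <- stats::cor(prev, disc)
  expect_lt(abs(r), 3 / sqrt(cfg$n_clusters))
})

test_that("risk exceeding 1 is rejected with the offending stratum named", {
  cfg <- generator_config(seed = 41,
                          baseline_hiv_risk = c(female = 0.5, male = 0.5),
                          true_log_rr_per_10pp = c(ff = log(3), fm = 0,
                                                   mf = 0, mm = log(3)))
  err <- tryCatch(generate_survey(cfg), error = function(e) e)
  expect_s3_class(err, "normgaps_param_error")
  expect_match(conditionMessage(err), "stratum [FM]")
})

test_that("correctly specified weighted fit recovers the generative slope", {
  # dual route: the package's IRLS-based fit must agree with a direct
  # numerical maximiser of the weighted Poisson log-likelihood, and its CI
  # must cover the true log RR of 1.27
  w <- prepared_world(generator_config(seed = 1))
  spec <- model_spec("female", "female")
  fit <- fit_weighted_poisson(w$data, spec)
  expect_true(fit$converged)
  frame <- normgaps:::prepare_analysis(w$data, spec)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(normgaps:::rhs_terms(spec),
                                       collapse = "+"))), frame)
  oracle <- oracle_poisson_ml(X, frame$y, frame$w, start = fit$coefficients)
  expect_equal(unname(oracle), unname(fit$coefficients), tolerance = 1e-6)
  se <- sqrt(fit$vcov["discordance", "discordance"])
  est <- fit$coefficients[["discordance"]]
  expect_lt(est - 1.96 * se, log(1.27))
  expect_gt(est + 1.96 * se, log(1.27))
})

test_that("builtin presets reproduce the printed distribution figures", {
  presets <- builtin_presets()
  expect_gte(nrow(presets), 5)
  row <- function(id) presets[presets$preset_id == id, ]
  expect_equal(row("ZAMBIA")$male_share_total, 0.453)
  expect_equal(row("MAI06")$male_share_total, 0.208)
  expect_equal(row("HAI12")$male_share_total, 0.412)
  expect_equal(row("SEN10")$adol_share_female, 0.050)
  expect_equal(row("LES09")$adol_share_male, 0.420)
  # six-stratum vectors are consistent with their marginals
  for (i in seq_len(nrow(presets))) {
    sh <- unlist(presets[i, ga_strata()$stratum])
    expect_equal(sum(sh), 1, tolerance = 1e-9)
    expect_equal(sum(sh[4:6]), presets$male_share_total[i], tolerance = 1e-9)
    expect_equal(sum(sh[1:2]) / sum(sh[1:3]), presets$adol_share_female[i],
                 tolerance = 1e-9)
  }
  expect_error(preset_shares("NOPE"), class = "normgaps_config_error")
})

test_that("missingness scenarios blank whole covariate columns, idempotently", {
  g <- generate_survey(quick_config(seed = 51))
  d1 <- apply_missingness_scenario(g$data, 1)
  expect_identical(d1, g$data)  # scenario 1: everything available
  d5 <- apply_missingness_scenario(g$data, 5)
  expect_true(all(is.na(d5$partner_age_diff_large)))
  expect_true(all(is.na(d5$alcohol_before_sex)))
  expect_false(any(is.na(d5$ipv_history)))
  expect_identical(d5$education, g$data$education)
  expect_identical(apply_missingness_scenario(d5, 5), d5)  # idempotent
  expect_error(normgaps:::as_scenario(7), class = "normgaps_config_error")
})

test_that("homogeneous worlds give comparable stratified slopes", {
  # with all effect modifiers zero, the discordance slope fitted within the
  # 15-19 and 20-24 strata should agree up to Monte-Carlo error
  w <- prepared_world(generator_config(
    seed = 61, households_per_cluster = 40L, respondents_per_household = 2,
    covariate_effects = c(urban = 0)))
  ests <- ses <- numeric(2)
  for (k in 1:2) {
    ag <- c("15-19", "20-24")[k]
    sub <- w$data[w$data$age_group != setdiff(c("15-19", "20-24"), ag), ]
    fit <- fit_weighted_poisson(sub, model_spec("female", "female",
                                                covariates = "residence"))
    ests[k] <- fit$coefficients[["discordance"]]
    ses[k] <- sqrt(fit$vcov["discordance", "discordance"])
  }
  expect_lt(abs(ests[1] - ests[2]) / sqrt(sum(ses^2)), 3)
})
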
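test_that("eligibility rules keep tested, sexually active adolescents and all adults", {
  # four adolescents: active+tested, active+tested, active+untested, inactive
  adol <- make_respondents(4, age_group = "15-19",
                           ever_had_sex = c(TRUE, TRUE, TRUE, FALSE),
                           hiv_tested = c(TRUE, TRUE, FALSE, TRUE))
  adults <- make_respondents(2, age_group = "25-49", ever_had_sex = FALSE,
                             hiv_tested = FALSE)
  adults$id <- adults$id + 10L
  out <- filter_eligible(rbind(adol, adults))
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$age_group == "15-19"), 2)
  log <- attr(out, "eligibility_log")
  expect_equal(log$removed_ever_sex, 1)
  expect_equal(log$removed_hiv_test, 1)
  expect_equal(log$n_in - log$n_out, log$removed_ever_sex + log$removed_hiv_test)

  # a missing HIV-test flag excludes under the HIV-test rule
  one <- make_respondents(1, age_group = "20-24", hiv_tested = NA)
  out1 <- suppressWarnings(filter_eligible(one))
  expect_equal(nrow(out1), 0)
  expect_equal(attr(out1, "eligibility_log")$removed_hiv_test, 1)

  # adults are always retained; the filter is idempotent
  expect_equal(nrow(suppressWarnings(filter_eligible(adults))), 2)
  expect_equal(as.data.frame(filter_eligible(out)), as.data.frame(out),
               ignore_attr = TRUE)
})

test_that("distributions count strata correctly and scale as expected", {
  d <- rbind(make_respondents(3, gender = "female", age_group = "15-19"),
             make_respondents(1, gender = "male", age_group = "25-49"))
  dist <- compute_distribution(d)
  expect_equal(unname(dist$proportions),
               c(0.75, 0, 0, 0, 0, 0.25))
  doubled <- compute_distribution(rbind(d, d))
  expect_equal(doubled$proportions, dist$proportions)
  expect_equal(doubled$counts, dist$counts * 2L)
  expect_error(compute_distribution(d[0, ]), class = "normgaps_data_error")
})

test_that("a survey generated from the MAI06 preset reproduces its male share", {
  cfg <- generator_config(n_clusters = 200L, households_per_cluster = 25L,
                          respondents_per_household = 4.2,
                          gender_age_shares = preset_shares("MAI06"),
                          true_log_rr_per_10pp = c(ff = 0, fm = 0, mf = 0, mm = 0),
                          seed = 71)
  g <- generate_survey(cfg)
  expect_gte(nrow(g$data), 20000)
  dist <- compute_distribution(g$data)
  male_share <- sum(dist$proportions[c("M15_19", "M20_24", "M25_49")])
  expect_lt(abs(male_share - 0.208), 0.01)
})

test_that("discordance implements the attitude-behaviour gap in 10-pp units", {
  # perfect concordance: everyone disapproves, none report the behaviour
  conc <- make_respondents(12, attitude = TRUE, behaviour = FALSE)
  t1 <- compute_discordance(conc, min_adults_per_cluster = 5)
  expect_equal(t1$discordance, 0)

  # hand-computed gap: 0.5 - (1 - 0.9) = 0.4 -> 4.0 in 10-pp units
  gap <- make_respondents(20, attitude = rep(c(TRUE, FALSE), c(18, 2)),
                          behaviour = rep(c(TRUE, FALSE), c(10, 10)))
  t2 <- compute_discordance(gap, min_adults_per_cluster = 5)
  expect_equal(t2$attitude_proportion, 0.9)
  expect_equal(t2$behaviour_proportion, 0.5)
  expect_equal(t2$discordance, 4.0)

  # invariant to rescaling all weights within a cluster
  gap2 <- gap
  gap2$design_weight <- gap2$design_weight * 7
  t3 <- compute_discordance(gap2, min_adults_per_cluster = 5)
  expect_equal(t3$discordance, t2$discordance)

  # minimum-adult threshold flags small cells; all-excluded errors
  small <- make_respondents(4, attitude = TRUE, behaviour = FALSE)
  t4 <- compute_discordance(rbind(gap, transform(small, cluster_id = 2L)),
                            min_adults_per_cluster = 10)
  expect_equal(t4$excluded, c(FALSE, TRUE))
  expect_error(compute_discordance(small, min_adults_per_cluster = 10),
               class = "normgaps_data_error")
})

test_that("survey screening applies the inclusion rules in order", {
  md <- data.frame(
    survey_id = c("ZMB07", "A", "B", "C", "D"),
    year = c(2007, 2008, 2010, 2004, 2010),
    male_share_total = c(0.453, 0.30, 0.30, 0.30, 0.35),
    gender_hiv_pr = c(2.5, 1.5, 2.5, 2.5, 2.5),
    has_individual_hiv = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    dhs_phase_post2005 = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- screen_surveys(md)
  expect_equal(res$classification,
               c("balanced_comparator", "excluded", "excluded", "excluded",
                 "imbalanced_included"))
  expect_match(res$reason[2], "low gender HIV PR")
  expect_match(res$reason[3], "no individual-level HIV")
  expect_match(res$reason[4], "pre-2005")
  # partition: exactly one classification per survey
  expect_equal(nrow(res), nrow(md))
  expect_true(all(res$classification %in%
                    c("balanced_comparator", "imbalanced_included", "excluded")))
  md$gender_hiv_pr[1] <- NA
  expect_error(screen_surveys(md), class = "normgaps_data_error")
  expect_error(screen_surveys(md[, -3]), class = "normgaps_data_error")
})

test_that("distribution dissimilarity flags >20% stratum differences", {
  a <- ga_distribution(c(F15_19 = 10L, F20_24 = 10L, F25_49 = 30L,
                         M15_19 = 10L, M20_24 = 10L, M25_49 = 30L))
  b <- ga_distribution(c(F15_19 = 10L, F20_24 = 10L, F25_49 = 30L,
                         M15_19 = 13L, M20_24 = 10L, M25_49 = 27L))
  self <- distribution_dissimilarity(a, a)
  expect_false(self$dissimilar)
  d <- distribution_dissimilarity(b, a)
  expect_true(d$dissimilar)
  expect_equal(unname(d$per_stratum[["M15_19"]]), 0.3)
})
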
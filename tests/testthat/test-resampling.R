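eligible_fixture <- function(seed = 81) {
  filter_eligible(generate_survey(quick_config(seed = seed))$data)
}

test_that("resampling matches the target distribution exactly", {
  e <- eligible_fixture()
  tg <- preset_target("SEN10", 2000L)
  res <- resample_to_distribution(e, tg, seed = 5)
  expect_equal(compute_distribution(res)$counts, tg$counts)
  # empty target stratum: no records from it
  tg0 <- tg$counts
  tg0["M15_19"] <- 0L
  res0 <- resample_to_distribution(e, ga_distribution(tg0), seed = 5)
  expect_equal(sum(res0$gender == "male" & res0$age_group == "15-19"), 0)
  # nonzero target from an empty source stratum errors with its name
  e2 <- e[!(e$gender == "male" & e$age_group == "15-19"), ]
  expect_error(resample_to_distribution(e2, tg, seed = 5), "M15_19",
               class = "normgaps_data_error")
})

test_that("selection weights invert resampling multiplicity: {2,3,5} example", {
  src <- make_respondents(3, age_group = "15-19", design_weight = c(2, 3, 5))
  tg <- ga_distribution(c(F15_19 = 6L, F20_24 = 0L, F25_49 = 0L,
                          M15_19 = 0L, M20_24 = 0L, M25_49 = 0L))
  res <- resample_to_distribution(src, tg, seed = 1,
                                  weight_method = "selection")
  # every drawn record carries w * (3/6)
  expect_equal(res$design_weight,
               src$design_weight[match(res$source_id, src$id)] * 0.5)
  # closed-form expectation of the realised stratum total is 10
  totals <- vapply(1:500, function(b) {
    sum(resample_to_distribution(src, tg, seed = b,
                                 weight_method = "selection")$design_weight)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 10) / 10, 0.02)
})

test_that("representative weights move stratum mass to the target shares", {
  e <- eligible_fixture()
  tg <- preset_target("MAI06", nrow(e))
  res <- resample_to_distribution(e, tg, seed = 3,
                                  weight_method = "representative")
  lab <- normgaps:::ga_label(res$gender, res$age_group)
  mass <- tapply(res$design_weight, factor(lab, ga_strata()$stratum), sum)
  # total mass matches the source total in expectation (single draw: 2%)
  expect_lt(abs(sum(mass) - sum(e$design_weight)) / sum(e$design_weight), 0.02)
  # weighted stratum shares track the target unweighted shares
  expect_lt(max(abs(mass / sum(mass) - tg$proportions)), 0.01)
})

test_that("merging appends the imbalance indicator and leaves weights alone", {
  e <- eligible_fixture()
  bal <- e[1:100, ]
  res <- resample_to_distribution(e, preset_target("HAI12", 80L), seed = 2)
  m <- make_merged(bal, res)
  expect_equal(nrow(m), 180)
  expect_equal(sum(m$imbalance == 0), 100)
  expect_setequal(unique(m$imbalance), c(0L, 1L))
  expect_equal(m$design_weight[m$imbalance == 0], bal$design_weight)
  expect_false(anyDuplicated(m$id) > 0)
  # a dataset merged with itself differs only through the indicator
  m2 <- make_merged(bal, bal)
  halves <- split(m2[setdiff(names(m2), c("id", "imbalance"))], m2$imbalance)
  expect_equal(halves[[1]], halves[[2]], ignore_attr = TRUE)
})

test_that("bootstrap sequences are deterministic, distinct, and exact", {
  e <- eligible_fixture()
  spec <- resample_spec(preset_target("MAI06", 1500L), n_bootstrap = 20L,
                        base_seed = 7)
  reps1 <- bootstrap_merged(e, spec)
  reps2 <- bootstrap_merged(e, spec)
  expect_identical(reps1, reps2)
  keys <- vapply(reps1, function(m)
    paste(m$source_id[m$imbalance == 1], collapse = ","), character(1))
  expect_equal(length(unique(keys)), 20L)
  for (m in reps1[1:3]) {
    expect_equal(compute_distribution(m[m$imbalance == 1, ])$counts,
                 spec$target$counts)
  }
  expect_error(resample_spec(preset_target("MAI06", 100L), n_bootstrap = 0),
               class = "normgaps_config_error")
})

test_that("draws are uniform within stratum across replicates", {
  # 20-record stratum, target 10: each record's selection count over 300
  # replicates stays within 4 SE of its expectation
  set.seed(1)
  src <- make_respondents(20, age_group = "15-19",
                          design_weight = runif(20, 0.5, 2))
  tg <- ga_distribution(c(F15_19 = 10L, F20_24 = 0L, F25_49 = 0L,
                          M15_19 = 0L, M20_24 = 0L, M25_49 = 0L))
  counts <- integer(20)
  R <- 300
  for (b in seq_len(R)) {
    res <- resample_to_distribution(src, tg, seed = 1000 + b)
    tabs <- table(factor(res$source_id, levels = src$id))
    counts <- counts + as.integer(tabs)
  }
  expected <- R * 10 / 20
  sd_one <- sqrt(R * 10 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) <= 4 * sd_one))
})
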
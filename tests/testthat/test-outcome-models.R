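# Adolescent table with a pre-attached binary exposure, for closed-form cases
two_group_data <- function(n1 = 100L, p1 = 0.2, n0 = 100L, p0 = 0.1,
                           weight = 1) {
  d <- make_respondents(n1 + n0, age_group = "15-19",
                        cluster_id = rep(1:20, length.out = n1 + n0),
                        design_weight = weight)
  d$disc_female <- rep(c(1, 0), c(n1, n0))
  d$hiv_positive <- c(rep(c(TRUE, FALSE), c(round(n1 * p1), n1 - round(n1 * p1))),
                      rep(c(TRUE, FALSE), c(round(n0 * p0), n0 - round(n0 * p0))))
  d
}

test_that("saturated two-group fit equals the closed-form log rate ratio", {
  d <- two_group_data()
  spec <- model_spec("female", "female", covariates = character(0))
  fit <- fit_weighted_poisson(d, spec)
  expect_equal(fit$coefficients[["discordance"]], log(2), tolerance = 1e-8)
  expect_equal(fit$coefficients[["(Intercept)"]], log(0.1), tolerance = 1e-8)
  # scaling every weight by 10 leaves the point estimates untouched
  d10 <- d
  d10$design_weight <- d10$design_weight * 10
  fit10 <- fit_weighted_poisson(d10, spec)
  expect_equal(fit10$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("grouped fit with integer weights equals the expanded-row maximiser", {
  d <- two_group_data(n1 = 40L, n0 = 40L)
  d$design_weight <- rep(c(1, 2, 3, 4), length.out = nrow(d))
  spec <- model_spec("female", "female", covariates = character(0))
  fit <- fit_weighted_poisson(d, spec)
  # independent oracle: replicate each row by its weight, maximise the plain
  # Poisson log-likelihood numerically
  idx <- rep(seq_len(nrow(d)), times = d$design_weight)
  X <- cbind(`(Intercept)` = 1, discordance = d$disc_female[idx])
  y <- as.numeric(d$hiv_positive[idx])
  oracle <- oracle_poisson_ml(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
})

test_that("sandwich variance tracks model-based variance with singleton clusters", {
  set.seed(91)
  n <- 8000L
  d <- make_respondents(n, age_group = "15-19", cluster_id = seq_len(n))
  d$disc_female <- rnorm(n)
  mu <- exp(log(0.05) + 0.2 * d$disc_female)
  d$hiv_positive <- runif(n) < mu
  fit <- fit_weighted_poisson(d, model_spec("female", "female",
                                            covariates = character(0)))
  frame <- normgaps:::prepare_analysis(d, model_spec("female", "female",
                                                     covariates = character(0)))
  X <- cbind(1, frame$discordance)
  muhat <- exp(drop(X %*% fit$coefficients))
  bread <- solve(crossprod(X, X * (frame$w * muhat)))
  ratio <- sqrt(fit$vcov[2, 2]) / sqrt(bread[2, 2])
  expect_lt(abs(ratio - 1), 0.2)
})

test_that("RR summaries format and flag like the study tables", {
  mk <- function(point, lo, hi, p = 0.5, rrb = list(point = 1.27,
                                                    lower = 1.25, upper = 1.29)) {
    structure(list(pathway = "ff",
                   terms = list(interaction = list(p = p)),
                   significant_interaction = p < 0.05,
                   rr_balanced = rrb,
                   rr_imbalanced = list(point = point, lower = lo, upper = hi),
                   rr_ci_disjoint_from_baseline = lo > rrb$point | hi < rrb$point),
              class = "interaction_summary")
  }
  row <- summarise_rr(mk(1.27, 1.25, 1.29))
  expect_equal(row$rr_balanced, "1.27 (1.25–1.29)")
  expect_false(row$biased_away)
  # null coefficient prints RR 1.00
  null_row <- summarise_rr(mk(1.00, 0.95, 1.05,
                              rrb = list(point = 1, lower = 1, upper = 1)))
  expect_match(null_row$rr_imbalanced, "^1\\.00 ")
  # imbalanced CI (1.30, 1.50) excludes balanced point 1.27
  expect_true(summarise_rr(mk(1.40, 1.30, 1.50))$biased_away)
})

test_that("exact-copy arms yield a null interaction", {
  e <- filter_eligible(generate_survey(quick_config(seed = 101))$data)
  d <- compute_discordance(e)
  e <- attach_cluster_exposures(e, d, items = normgaps:::NORM_ITEMS)
  copy <- e
  copy$source_id <- copy$id
  reps <- lapply(1:3, function(b) make_merged(e, copy))
  s <- interaction_test(reps, model_spec("female", "female"))
  expect_lt(abs(s$terms$interaction$mean), 1e-6)
  expect_false(s$significant_interaction)
  expect_equal(s$rr_imbalanced$point, s$rr_balanced$point, tolerance = 1e-6)
})

test_that("interaction machinery guards its inputs", {
  e <- filter_eligible(generate_survey(quick_config(seed = 102))$data)
  d <- compute_discordance(e)
  e <- attach_cluster_exposures(e, d, items = normgaps:::NORM_ITEMS)
  # a plain dataset has no imbalance indicator
  spec <- model_spec("female", "female", include_interaction = TRUE)
  expect_error(fit_weighted_poisson(e, spec), class = "normgaps_data_error")
  expect_error(interaction_test(list(), model_spec("female", "female")),
               class = "normgaps_data_error")
  # an entirely missing design column names the covariate
  e2 <- apply_missingness_scenario(e, 5)
  err <- tryCatch(fit_weighted_poisson(e2, model_spec("female", "female",
                                                      group_level = character(0))),
                  error = function(e) e)
  expect_s3_class(err, "normgaps_data_error")
  expect_match(conditionMessage(err), "partner_age_diff_large|alcohol_before_sex")
})
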
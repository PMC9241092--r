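# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's fitting code paths: direct numerical maximisation of the Poisson
# log-likelihood via optim(), and an eigendecomposition route for Wald
# quadratic forms.

# Direct numerical maximiser of the (optionally row-replicated) weighted
# Poisson log-likelihood with log link. X: design matrix incl. intercept.
oracle_poisson_ml <- function(X, y, w = rep(1, length(y)), start = NULL) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(w * (y * eta - exp(eta)))
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta))
    -drop(crossprod(X, w * (y - mu)))
  }
  if (is.null(start)) start <- c(log(max(mean(y), 1e-3)), rep(0, ncol(X) - 1))
  fit <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  stats::setNames(fit$par, colnames(X))
}

# Wald quadratic form via eigendecomposition (independent of solve())
oracle_wald_quadratic <- function(beta, V) {
  e <- eigen(V, symmetric = TRUE)
  z <- drop(crossprod(e$vectors, beta))
  sum(z^2 / e$values)
}

# Direct numerical maximiser of the Bernoulli (logistic) log-likelihood
# (BFGS start, Newton polish for tight agreement)
oracle_logit_ml <- function(x, y) {
  X <- cbind(1, x)
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  beta <- stats::optim(c(0, 0), negll, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))$par
  for (i in 1:25) {
    p <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - p))
    H <- crossprod(X, X * (p * (1 - p)))
    beta <- beta + solve(H, score)
    if (max(abs(score)) < 1e-12) break
  }
  beta
}

# A small but analysable synthetic world (fast enough for loops)
quick_config <- function(seed = 1L, ...) {
  generator_config(n_clusters = 100L, households_per_cluster = 20L,
                   respondents_per_household = 1.4, seed = seed, ...)
}

# Minimal hand-built respondent table; every column the package contracts on
make_respondents <- function(n, gender = "female", age_group = "25-49",
                             cluster_id = 1L, design_weight = 1,
                             ever_had_sex = TRUE, hiv_tested = TRUE,
                             hiv_positive = NA, attitude = NA, behaviour = NA) {
  age_lo <- c(`15-19` = 15L, `20-24` = 20L, `25-49` = 25L)
  df <- data.frame(
    id = seq_len(n), cluster_id = cluster_id, stratum_id = "rural",
    household_id = seq_len(n), gender = gender,
    age_years = age_lo[age_group] + 1L, age_group = age_group,
    ever_had_sex = ever_had_sex, hiv_tested = hiv_tested,
    hiv_positive = hiv_positive, design_weight = design_weight,
    education = "primary", marital = "never_formerly", residence = "rural",
    attitude_disapproves_premarital = attitude,
    behaviour_premarital = behaviour, stringsAsFactors = FALSE,
    row.names = NULL
  )
  for (it in c("ipv_history", "belief_fidelity", "belief_beating_justified",
               "partner_age_diff_large", "alcohol_before_sex")) {
    df[[it]] <- FALSE
  }
  df
}

# Eligible, exposure-attached dataset from a generated world
prepared_world <- function(config, min_adults = 10L) {
  g <- generate_valid_survey(config, max_tries = 25L)
  e <- filter_eligible(g$data)
  d <- compute_discordance(e, min_adults)
  list(data = attach_cluster_exposures(
    e, d, items = c("ipv_history", "belief_fidelity",
                    "belief_beating_justified", "partner_age_diff_large",
                    "alcohol_before_sex")),
    truth = g$truth, disc = d)
}

zero_modifiers <- function() {
  stats::setNames(rep(0, 6), c("F15_19", "F20_24", "F25_49",
                               "M15_19", "M20_24", "M25_49"))
}
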
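#' Enumerate the six covariate-availability scenarios
#'
#' Reads the scenario matrix shipped at
#' `inst/extdata/covariate_scenarios.csv` (editable; it mirrors the study's
#' availability table): six patterns of wholly unasked covariates observed
#' across 25 gender-age-imbalanced surveys (5, 9, 2, 5, 1 and 3 surveys
#' respectively). Unavailability is pathway-specific: the IPV and
#' partner-age-difference items feed the female-HIV models only, the
#' alcohol-before-sex item the male-HIV models only.
#'
#' @return List of six `covariate_scenario` objects, each with
#'   `scenario_id`, `n_surveys` and an `unavailable` data.frame
#'   (`covariate`, `affected_models`).
#' @export
enumerate_scenarios <- function() {
  path <- system.file("extdata", "covariate_scenarios.csv",
                      package = "normgaps", mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- m[m$covariate == "n_surveys", paste0("s", 1:6)]
  m <- m[m$covariate != "n_surveys", , drop = FALSE]
  lapply(1:6, function(i) {
    unavailable <- m[m[[paste0("s", i)]] == 0,
                     c("covariate", "affected_models"), drop = FALSE]
    rownames(unavailable) <- NULL
    structure(list(
      scenario_id = i,
      n_surveys = as.integer(counts[[paste0("s", i)]]),
      unavailable = unavailable
    ), class = "covariate_scenario")
  })
}

as_scenario <- function(x) {
  if (inherits(x, "covariate_scenario")) return(x)
  if (is.numeric(x) && length(x) == 1 && x %in% 1:6) {
    return(enumerate_scenarios()[[x]])
  }
  config_error("scenario must be an id in 1..6 or a covariate_scenario object")
}

#' @export
print.covariate_scenario <- function(x, ...) {
  cat(sprintf("Covariate scenario %d (N = %d surveys)\n", x$scenario_id,
              x$n_surveys))
  if (nrow(x$unavailable)) print(x$unavailable) else cat("  all covariates available\n")
  invisible(x)
}

# Covariates a scenario removes from the model of a given outcome gender
scenario_removed_covariates <- function(scenario, outcome_gender) {
  sel <- scenario$unavailable$affected_models %in%
    c("both", paste0(outcome_gender, "_hiv"))
  scenario$unavailable$covariate[sel]
}

wald_quadratic <- function(beta, V) {
  as.numeric(t(beta) %*% solve(V, beta))
}

#' Wald test of a fully adjusted model against a covariate-reduced model
#'
#' Tests the joint nullity of the coefficients that a covariate-availability
#' scenario removes from the pathway's fully adjusted model, using the full
#' model's cluster-robust covariance. Reported on the F scale
#' (`F = W / df`), with the p-value from the chi-square reference on
#' `W = F * df` (large survey n). When the scenario removes nothing relevant
#' to the pathway the defined no-op result is returned (`F = 0`, `p = 1`).
#'
#' @param dataset Respondent data.frame (typically the balanced survey).
#' @param spec A [model_spec()]; its covariates must include every term the
#'   scenario removes for this pathway.
#' @param scenario Scenario id (1..6) or `covariate_scenario`; alternatively
#'   pass `drop` directly.
#' @param drop Optional character vector of covariates to drop, overriding
#'   the scenario mapping.
#' @param min_adults_per_cluster Passed through to exposure construction.
#' @param fit Optional pre-computed full-model `normgaps_fit` (avoids
#'   refitting in replicate loops).
#' @return Object of class `wald_summary`: `pathway`, `scenario_id`,
#'   `F_statistic`, `df_numerator`, `reference`, `p_value`, `significant`.
#' @export
wald_full_vs_reduced <- function(dataset, spec, scenario = NULL, drop = NULL,
                                 min_adults_per_cluster = 10L, fit = NULL) {
  scenario_id <- NA_integer_
  if (is.null(drop)) {
    sc <- as_scenario(scenario)
    scenario_id <- sc$scenario_id
    drop <- scenario_removed_covariates(sc, spec$outcome_gender)
  }
  missing_cov <- setdiff(drop, spec$covariates)
  if (length(missing_cov)) {
    config_error(paste("removed covariate(s) absent from the full model spec:",
                       paste(missing_cov, collapse = ", ")))
  }
  if (!length(drop)) {
    return(structure(list(
      pathway = spec$pathway, scenario_id = scenario_id, F_statistic = 0,
      df_numerator = 0L, reference = "none", p_value = 1, significant = FALSE
    ), class = "wald_summary"))
  }
  if (is.null(fit)) fit <- fit_weighted_poisson(dataset, spec,
                                                min_adults_per_cluster)
  terms <- unlist(lapply(drop, covariate_terms, spec = spec))
  beta <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  W <- wald_quadratic(beta, V)
  df <- length(terms)
  structure(list(
    pathway = spec$pathway, scenario_id = scenario_id,
    F_statistic = W / df, df_numerator = df, reference = "chisq",
    p_value = stats::pchisq(W, df, lower.tail = FALSE),
    significant = stats::pchisq(W, df, lower.tail = FALSE) < 0.05
  ), class = "wald_summary")
}

#' @export
print.wald_summary <- function(x, ...) {
  cat(sprintf(
    "Wald full-vs-reduced (pathway %s%s): F = %.4f on %d df, p = %.4g%s\n",
    x$pathway,
    if (!is.na(x$scenario_id)) paste0(", scenario ", x$scenario_id) else "",
    x$F_statistic, x$df_numerator, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Joint effect of imbalanced sampling and covariate missingness
#'
#' Applies [wald_full_vs_reduced()] to the fully adjusted *interaction*
#' model on every merged replicate and reports the mean F statistic; the
#' p-value applies the same chi-square reference to `mean F * df`
#' (documented as approximate).
#'
#' @param replicates List of merged datasets from [bootstrap_merged()].
#' @param spec A [model_spec()]; `include_interaction` is forced on.
#' @param scenario Scenario id (1..6) or `covariate_scenario`.
#' @param min_adults_per_cluster Passed through.
#' @return A `wald_summary` with the mean F over converged replicates and
#'   `n_dropped` replicates excluded.
#' @export
joint_imbalance_missingness <- function(replicates, spec, scenario,
                                        min_adults_per_cluster = 10L) {
  if (length(replicates) < 2L) data_error("need at least 2 replicates")
  sc <- as_scenario(scenario)
  spec$include_interaction <- TRUE
  drop <- scenario_removed_covariates(sc, spec$outcome_gender)
  if (!length(drop)) {
    out <- wald_full_vs_reduced(NULL, spec, sc)
    out$n_dropped <- 0L
    return(out)
  }
  res <- lapply(replicates, function(rep) {
    tryCatch({
      fit <- fit_weighted_poisson(rep, spec, min_adults_per_cluster)
      if (!fit$converged) NULL else
        wald_full_vs_reduced(rep, spec, sc, min_adults_per_cluster =
                               min_adults_per_cluster, fit = fit)
    }, error = function(e) NULL)
  })
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) data_error("no replicate model converged")
  Fs <- vapply(res[ok], function(r) r$F_statistic, numeric(1))
  df <- res[ok][[1]]$df_numerator
  mF <- mean(Fs)
  p <- stats::pchisq(mF * df, df, lower.tail = FALSE)
  structure(list(
    pathway = spec$pathway, scenario_id = sc$scenario_id, F_statistic = mF,
    df_numerator = df, reference = "chisq", p_value = p,
    significant = p < 0.05, n_dropped = sum(!ok)
  ), class = "wald_summary")
}
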
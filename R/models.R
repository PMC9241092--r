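#' Model specification for one sex-stratified pathway
#'
#' Describes one of the four discordance-HIV pathways: the HIV outcome of
#' adolescents of `outcome_gender` regressed on the adult discordance of
#' `exposure_gender`, adjusted for individual-level demographics and
#' (by default) community-level proportions of the belief/behaviour items.
#'
#' @param outcome_gender,exposure_gender `"female"` or `"male"`.
#' @param covariates Covariates to adjust for, drawn from `age_group`,
#'   `education`, `marital`, `residence` and the five items
#'   `r paste(NORM_ITEMS, collapse = ", ")`.
#' @param include_interaction Include the imbalance indicator and the
#'   discordance-by-imbalance interaction (merged datasets only).
#' @param group_level Items entered as cluster-level weighted adult
#'   proportions (`cl_<item>` columns) rather than the respondent's own
#'   indicator.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome_gender, exposure_gender,
                       covariates = default_covariates(),
                       include_interaction = FALSE,
                       group_level = NORM_ITEMS) {
  outcome_gender <- match.arg(outcome_gender, GENDERS)
  exposure_gender <- match.arg(exposure_gender, GENDERS)
  known <- c("age_group", "education", "marital", "residence", NORM_ITEMS)
  bad <- setdiff(covariates, known)
  if (length(bad)) {
    config_error(paste("unknown covariate(s):", paste(bad, collapse = ", ")))
  }
  structure(list(
    outcome_gender = outcome_gender, exposure_gender = exposure_gender,
    pathway = paste0(substr(outcome_gender, 1, 1), substr(exposure_gender, 1, 1)),
    covariates = covariates, include_interaction = include_interaction,
    group_level = intersect(group_level, NORM_ITEMS)
  ), class = "model_spec")
}

default_covariates <- function() {
  c("age_group", "education", "marital", "residence", NORM_ITEMS)
}

#' The four canonical sex-stratified pathway specifications
#'
#' Enumerates adolescent female HIV ~ adult female discordance (`ff`),
#' female ~ male (`fm`), male ~ female (`mf`) and male ~ male (`mm`).
#'
#' @param ... Passed to [model_spec()] (e.g. `include_interaction`).
#' @return Named list of four `model_spec` objects.
#' @export
pathway_specs <- function(...) {
  list(
    ff = model_spec("female", "female", ...),
    fm = model_spec("female", "male", ...),
    mf = model_spec("male", "female", ...),
    mm = model_spec("male", "male", ...)
  )
}

# Map a model-spec covariate to the design-matrix column(s) it contributes.
covariate_terms <- function(spec, covariate) {
  switch(covariate,
    age_group = "age_20_24",
    education = c("educ_primary", "educ_secondary"),
    marital = "marital_currently",
    residence = "residence_urban",
    if (covariate %in% spec$group_level) paste0("cl_", covariate) else covariate
  )
}

# Build the adolescent analysis frame for one pathway: outcome, exposure,
# covariate dummies, weights and cluster ids. Cluster-level exposures are
# attached from the dataset's own adults when not already present.
prepare_analysis <- function(dataset, spec, min_adults_per_cluster = 10L) {
  disc_col <- paste0("disc_", spec$exposure_gender)
  need_cl <- paste0("cl_", intersect(spec$covariates, spec$group_level),
                    recycle0 = TRUE)
  if (!disc_col %in% names(dataset) || !all(need_cl %in% names(dataset))) {
    disc <- compute_discordance(dataset, min_adults_per_cluster)
    dataset <- attach_cluster_exposures(
      dataset, disc, items = intersect(spec$covariates, spec$group_level))
  }
  rows <- dataset$age_group %in% c("15-19", "20-24") &
    dataset$gender == spec$outcome_gender & !is.na(dataset$hiv_positive) &
    !is.na(dataset[[disc_col]])
  d <- dataset[rows, , drop = FALSE]
  if (!nrow(d)) {
    data_error(sprintf("no eligible %s adolescents with HIV status and exposure",
                       spec$outcome_gender))
  }
  frame <- data.frame(
    y = as.numeric(d$hiv_positive),
    discordance = d[[disc_col]],
    w = d$design_weight,
    cluster = d$cluster_id
  )
  if (spec$include_interaction) {
    if (is.null(d$imbalance)) {
      data_error("include_interaction requires a merged dataset with an imbalance indicator")
    }
    frame$imbalance <- as.numeric(d$imbalance)
  }
  for (cov in spec$covariates) {
    for (term in covariate_terms(spec, cov)) {
      val <- switch(term,
        age_20_24 = as.numeric(d$age_group == "20-24"),
        educ_primary = as.numeric(d$education == "primary"),
        educ_secondary = as.numeric(d$education == "secondary"),
        marital_currently = as.numeric(d$marital == "currently"),
        residence_urban = as.numeric(d$residence == "urban"),
        as.numeric(d[[term]])
      )
      if (all(is.na(val))) {
        data_error(sprintf("design column '%s' (covariate '%s') is entirely missing",
                           term, cov))
      }
      frame[[term]] <- val
    }
  }
  frame
}

rhs_terms <- function(spec) {
  terms <- "discordance"
  if (spec$include_interaction) {
    terms <- c(terms, "imbalance", "discordance:imbalance")
  }
  c(terms, unlist(lapply(spec$covariates, covariate_terms, spec = spec)))
}

#' Survey-weighted Poisson (log-link) fit with cluster-robust variance
#'
#' Fits a modified-Poisson prevalence-ratio model of binary adolescent HIV
#' status on the discordance exposure and covariates, maximising the
#' weight-multiplied Poisson log-likelihood (so point estimates are invariant
#' to rescaling all weights), with a sandwich covariance aggregated at the
#' cluster level (with a `G/(G-1)` small-sample factor).
#'
#' @param dataset Respondent data.frame (eligibility-filtered, and either
#'   already carrying `disc_*`/`cl_*` exposure columns or containing the
#'   adults from which they can be computed) or a `merged_dataset`.
#' @param spec A [model_spec()].
#' @param min_adults_per_cluster Passed to [compute_discordance()] when
#'   exposures must be computed.
#' @param vcov_type `"CR2"` (bias-reduced, default) or `"CR0"` cluster
#'   sandwich.
#' @return Object of class `normgaps_fit`: `coefficients`, `vcov`
#'   (cluster-robust), `n_obs`, `n_clusters`, `converged`, `loglik`.
#' @export
fit_weighted_poisson <- function(dataset, spec, min_adults_per_cluster = 10L,
                                 vcov_type = c("CR2", "CR0")) {
  frame <- prepare_analysis(dataset, spec, min_adults_per_cluster)
  fml <- stats::as.formula(paste("y ~", paste(rhs_terms(spec), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(
    fml, data = frame, weights = w,
    family = stats::quasipoisson(link = "log"),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- stats::coef(fit)
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  # aliased nuisance columns (e.g. a constant covariate in a small dataset)
  # are dropped; an aliased key term invalidates the fit
  aliased <- is.na(beta)
  key <- c("(Intercept)", "discordance", "imbalance", "discordance:imbalance")
  slopes <- setdiff(key, "(Intercept)")
  if (any(aliased[names(beta) %in% key])) {
    separated <- TRUE
    X <- X[, !aliased, drop = FALSE]
    beta <- beta[!aliased]
  } else {
    if (any(aliased)) {
      X <- X[, !aliased, drop = FALSE]
      beta <- beta[!aliased]
    }
    # separation heuristic on the exposure terms only; nuisance intercept or
    # group-proportion coefficients may legitimately be large in small fits
    separated <- any(abs(beta[names(beta) %in% slopes]) > 20) ||
      any(!is.finite(beta))
  }
  V <- cluster_robust_vcov(X, frame$w, frame$y, mu, frame$cluster,
                           type = match.arg(vcov_type))
  dimnames(V) <- list(names(beta), names(beta))
  ll <- sum(frame$w * (ifelse(frame$y > 0, frame$y * log(mu), 0) - mu -
                         lgamma(frame$y + 1)))
  structure(list(
    coefficients = beta, vcov = V, n_obs = nrow(frame),
    n_clusters = length(unique(frame$cluster)),
    converged = fit$converged && !separated, loglik = ll,
    spec = spec
  ), class = "normgaps_fit")
}

# Cluster-robust sandwich for the weighted Poisson score
# U_i = w_i (y_i - mu_i) x_i; bread = (X' diag(w mu) X)^{-1}.
# Default "CR2" applies the bias-reduced linearisation (per-cluster
# (I - H_gg)^{-1/2} residual adjustment in the working-WLS representation),
# which removes most of the downward bias of the plain estimator with
# moderate cluster counts; "CR0" is the plain estimator with a G/(G-1)
# factor.
cluster_robust_vcov <- function(X, w, y, mu, cluster, type = c("CR2", "CR0")) {
  type <- match.arg(type)
  omega <- w * mu
  bread <- solve(crossprod(X, X * omega))
  if (type == "CR0") {
    S <- rowsum(X * (w * (y - mu)), cluster)
    G <- nrow(S)
    adj <- if (G > 1) G / (G - 1) else 1
    return(bread %*% crossprod(S) %*% bread * adj)
  }
  sq <- sqrt(omega)
  Xt <- X * sq                       # working design
  eps <- (y - mu) * w / sq           # working residual: Xt' eps = X' w (y-mu)
  idx <- split(seq_along(y), cluster)
  S <- matrix(0, length(idx), ncol(X))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    Xg <- Xt[rows, , drop = FALSE]
    M <- diag(length(rows)) - Xg %*% bread %*% t(Xg)
    e <- eigen(M, symmetric = TRUE)
    vals <- e$values
    vals[vals < 1e-10] <- Inf        # pseudo-inverse square root
    Ag <- e$vectors %*% (t(e$vectors) / sqrt(vals))
    S[g, ] <- crossprod(Xg, Ag %*% eps[rows])
  }
  bread %*% crossprod(S) %*% bread
}

#' @export
print.normgaps_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tab <- data.frame(estimate = x$coefficients, robust_se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  cat(sprintf("Weighted Poisson fit (pathway %s): %d obs, %d clusters%s\n",
              x$spec$pathway, x$n_obs, x$n_clusters,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(tab, 5))
  invisible(x)
}

summarise_coef <- function(values, p_rule, level = 0.05, robust_se = NULL) {
  B <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  se <- switch(p_rule,
    # variance of the replicate mean: the per-replicate robust variance
    # (survey noise + resampling noise) minus the share of resampling noise
    # that averaging over B replicates removes; the across-replicate
    # variance s^2 estimates the resampling component. Floored at the pure
    # Monte-Carlo standard error.
    robust = sqrt(max(mean(robust_se^2) - s^2 * (1 - 1 / B), s^2 / B)),
    mc_se = s / sqrt(B),
    replicate_sd = s
  )
  z <- if (se > 0) m / se else 0
  # the variance estimate uses the B replicates, so a t reference with B - 1
  # degrees of freedom replaces the normal
  crit <- stats::qt(1 - level / 2, df = max(B - 1, 1))
  list(mean = m, sd = s, se = se, z = z,
       p = 2 * stats::pt(-abs(z), df = max(B - 1, 1)),
       lower = m - crit * se, upper = m + crit * se)
}

#' Bootstrap test for effect-measure interaction
#'
#' Fits the interaction model (discordance, imbalance, discordance-by-
#' imbalance, covariates) on each merged replicate, then aggregates the
#' replicate coefficients: means, SDs, a p-value per summary coefficient, and
#' the relative risk per 10-pp discordance with 95% CI for the balanced arm
#' (`exp(b_discordance)`) and the imbalanced arm
#' (`exp(b_discordance + b_interaction)`).
#'
#' Three summary p-value rules are provided (the study under-specifies its
#' rule). The default `"robust"` refers `mean(b) / sqrt(mean(robust SE^2))`
#' to a standard normal: the per-replicate cluster-robust SEs account for
#' the survey-sampling noise the two arms share, so this rule is calibrated
#' against the superpopulation null of no effect-measure interaction.
#' `"mc_se"` uses `mean / (SD/sqrt(B))` (the Monte-Carlo standard error):
#' it tests the *conditional* null that resampling leaves the estimand of
#' this particular source dataset unchanged — exact under mass-conserving
#' (`"selection"`) weights but anti-conservative under `"representative"`
#' weights, where reweighting a finite sample shifts the estimand by
#' Op(1/sqrt(n)) even without effect modification. `"replicate_sd"` uses
#' `mean / SD` (the rule the across-replicate presentation suggests); it is
#' severely conservative because the replicate mean concentrates while the
#' SD does not shrink. See the methods vignette.
#'
#' @param replicates List of merged datasets from [bootstrap_merged()].
#' @param spec A [model_spec()]; `include_interaction` is forced on.
#' @param level Significance cut-off (default 0.05).
#' @param p_rule `"robust"`, `"mc_se"` or `"replicate_sd"`.
#' @param min_adults_per_cluster Passed through to exposure construction.
#' @return Object of class `interaction_summary`.
#' @export
interaction_test <- function(replicates, spec, level = 0.05,
                             p_rule = c("robust", "mc_se", "replicate_sd"),
                             min_adults_per_cluster = 10L) {
  p_rule <- match.arg(p_rule)
  if (length(replicates) < 2L) data_error("need at least 2 replicates")
  spec$include_interaction <- TRUE
  fits <- lapply(replicates, function(rep) {
    tryCatch(fit_weighted_poisson(rep, spec, min_adults_per_cluster),
             error = function(e) NULL)
  })
  usable <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  n_dropped <- sum(!usable)
  if (!any(usable)) data_error("no replicate model converged")
  if (sum(usable) < 2L) data_error("fewer than 2 replicates converged")
  keep <- c("discordance", "imbalance", "discordance:imbalance")
  coefs <- t(vapply(fits[usable], function(f) f$coefficients[keep],
                    numeric(3)))
  ses <- t(vapply(fits[usable], function(f) {
    V <- f$vcov[keep, keep]
    c(sqrt(pmax(diag(V), 0)),  # per-term robust SEs
      sqrt(max(V[1, 1] + V[3, 3] + 2 * V[1, 3], 0)))  # SE of disc+interaction
  }, numeric(4)))
  colnames(coefs) <- c("discordance", "imbalance", "interaction")
  colnames(ses) <- c("discordance", "imbalance", "interaction", "imb_arm")
  terms <- lapply(colnames(coefs), function(nm)
    summarise_coef(coefs[, nm], p_rule = p_rule, level = level,
                   robust_se = ses[, nm]))
  names(terms) <- colnames(coefs)
  imb_arm <- summarise_coef(coefs[, "discordance"] + coefs[, "interaction"],
                            p_rule = p_rule, level = level,
                            robust_se = ses[, "imb_arm"])
  rr <- function(s) list(point = exp(s$mean), lower = exp(s$lower),
                         upper = exp(s$upper))
  rr_bal <- rr(terms$discordance)
  rr_imb <- rr(imb_arm)
  structure(list(
    pathway = spec$pathway, B = sum(usable), n_dropped = n_dropped,
    unreliable = n_dropped > 0.1 * length(replicates),
    level = level, p_rule = p_rule, terms = terms,
    imbalanced_arm = imb_arm, rr_balanced = rr_bal, rr_imbalanced = rr_imb,
    significant_interaction = terms$interaction$p < level,
    rr_ci_disjoint_from_baseline =
      rr_imb$lower > rr_bal$point || rr_imb$upper < rr_bal$point
  ), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("Interaction test, pathway %s (B = %d%s, p-rule %s)\n",
              x$pathway, x$B,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else "",
              x$p_rule))
  tab <- do.call(rbind, lapply(x$terms, function(s)
    data.frame(mean = s$mean, sd = s$sd, p = s$p)))
  print(round(tab, 5))
  print(summarise_rr(x))
  invisible(x)
}

#' Format relative risks the way the study tables present them
#'
#' Formats the per-10-pp discordance RR with 95% CI for the balanced and
#' imbalanced arms (e.g. `"1.27 (1.25-1.29)"` with an en dash) and flags
#' whether the imbalanced-arm CI excludes the balanced-arm point estimate
#' ("biased away from baseline") and whether the interaction is significant.
#'
#' @param summary An `interaction_summary`.
#' @return One-row data.frame: `pathway`, `rr_balanced`, `rr_imbalanced`
#'   (formatted strings), `interaction_p`, `significant_interaction`,
#'   `biased_away`.
#' @export
summarise_rr <- function(summary) {
  fmt <- function(rr) sprintf("%.2f (%.2f–%.2f)", rr$point, rr$lower,
                              rr$upper)
  data.frame(
    pathway = summary$pathway,
    rr_balanced = fmt(summary$rr_balanced),
    rr_imbalanced = fmt(summary$rr_imbalanced),
    interaction_p = summary$terms$interaction$p,
    significant_interaction = summary$significant_interaction,
    biased_away = summary$rr_ci_disjoint_from_baseline,
    stringsAsFactors = FALSE
  )
}
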
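#' Inter-survey records from interaction summaries
#'
#' Builds the per-(survey, pathway) record table consumed by the
#' inter-survey meta-analyses: gender-age sampling predictors of the target
#' distribution and the interaction-test outcomes.
#'
#' @param targets Named list of [ga_distribution()] targets (names = survey
#'   ids).
#' @param summaries data.frame with columns `target`, `pathway`,
#'   `significant_interaction`, `interaction_mean`, `rr_imbalanced`.
#' @return data.frame of `intersurvey_record` rows: `survey_id`, `pathway`,
#'   predictors `male_share_total`, `adol_share_female`, `adol_share_male`
#'   (within-gender adolescent proportions), and the outcomes.
#' @export
intersurvey_records <- function(targets, summaries) {
  preds <- do.call(rbind, lapply(names(targets), function(id) {
    p <- targets[[id]]$proportions
    f <- sum(p[c("F15_19", "F20_24", "F25_49")])
    m <- sum(p[c("M15_19", "M20_24", "M25_49")])
    data.frame(
      survey_id = id, male_share_total = m,
      adol_share_female = sum(p[c("F15_19", "F20_24")]) / f,
      adol_share_male = sum(p[c("M15_19", "M20_24")]) / m,
      stringsAsFactors = FALSE
    )
  }))
  out <- merge(summaries, preds, by.x = "target", by.y = "survey_id")
  names(out)[names(out) == "target"] <- "survey_id"
  out
}

check_records <- function(records, outcome_cols) {
  needed <- c("survey_id", "pathway", outcome_cols)
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    data_error(paste("records missing column(s):", paste(miss, collapse = ", ")))
  }
  if (nrow(records) < 2L) data_error("need at least 2 records")
  n_per <- table(records$pathway)
  if (any(n_per < 10L)) {
    warning("fewer than 10 records for pathway(s): ",
            paste(names(n_per)[n_per < 10L], collapse = ", "),
            "; estimates will be unstable", call. = FALSE)
  }
  invisible(records)
}

#' Logistic meta-analysis: does sampling distribution predict significance?
#'
#' Per pathway and per predictor (entered one at a time; 25 surveys cannot
#' support a joint model), fits a logistic regression of whether the test
#' for interaction was significant on the gender-age sampling share. Odds
#' ratios are reported per 1-percentage-point increase of the share.
#' Constant outcomes are flagged `inestimable`; separation is detected and
#' flagged rather than trusted.
#'
#' @param records data.frame from [intersurvey_records()] (or equivalent),
#'   with logical/0-1 column `significant_interaction`.
#' @param predictors Share columns to use.
#' @return data.frame: `pathway`, `predictor`, `log_or_per_pp`, `or_per_pp`,
#'   `or_lower`, `or_upper`, `p_value`, `n`, `inestimable`, `separation`.
#' @export
fit_significance_logit <- function(records,
                                   predictors = c("adol_share_female",
                                                  "adol_share_male",
                                                  "male_share_total")) {
  check_records(records, "significant_interaction")
  rows <- list()
  for (pw in unique(records$pathway)) {
    sub <- records[records$pathway == pw, , drop = FALSE]
    y <- as.numeric(sub$significant_interaction)
    for (pred in predictors) {
      x_pp <- 100 * sub[[pred]]  # percentage points
      if (length(unique(y)) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, predictor = pred, log_or_per_pp = NA_real_,
          or_per_pp = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
          p_value = NA_real_, n = length(y), inestimable = TRUE,
          separation = FALSE, stringsAsFactors = FALSE)
        next
      }
      sep_warned <- FALSE
      fit <- withCallingHandlers(
        stats::glm(y ~ x_pp, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
            sep_warned <<- TRUE
          }
          invokeRestart("muffleWarning")
        })
      est <- stats::coef(fit)[["x_pp"]]
      se <- sqrt(diag(stats::vcov(fit)))[["x_pp"]]
      separation <- sep_warned || abs(est) > 10 || se > 50
      z <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, predictor = pred, log_or_per_pp = est,
        or_per_pp = exp(est), or_lower = exp(est - 1.96 * se),
        or_upper = exp(est + 1.96 * se),
        p_value = 2 * stats::pnorm(-abs(z)), n = length(y),
        inestimable = FALSE, separation = separation,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("intersurvey_summary", "data.frame")
  out
}

#' Linear meta-analysis: sampling distribution vs outcome magnitude
#'
#' Per pathway, predictor and outcome (interaction coefficient mean and
#' estimated RR), fits an ordinary least-squares regression of the outcome
#' on the share (proportion scale) and reports the slope with 95% CI.
#'
#' @param records data.frame with numeric outcome columns.
#' @param predictors Share columns (proportions in \[0, 1\]).
#' @param outcomes Outcome columns; defaults to `interaction_mean` and `rr`.
#' @return data.frame: `pathway`, `predictor`, `outcome`, `slope`,
#'   `slope_lower`, `slope_upper`, `p_value`, `n`.
#' @export
fit_outcome_linear <- function(records,
                               predictors = c("adol_share_female",
                                              "adol_share_male",
                                              "male_share_total"),
                               outcomes = c("interaction_mean", "rr")) {
  outcomes <- intersect(outcomes, names(records))
  if (!length(outcomes)) data_error("no outcome columns present in records")
  check_records(records, outcomes)
  rows <- list()
  for (pw in unique(records$pathway)) {
    sub <- records[records$pathway == pw, , drop = FALSE]
    for (pred in predictors) {
      x <- sub[[pred]]
      if (stats::var(x) == 0) {
        data_error(sprintf("predictor '%s' has zero variance", pred))
      }
      for (oc in outcomes) {
        fit <- stats::lm(sub[[oc]] ~ x)
        est <- stats::coef(fit)[["x"]]
        sm <- suppressWarnings(summary(fit)$coefficients)
        se <- sm["x", "Std. Error"]
        p <- sm["x", "Pr(>|t|)"]
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, predictor = pred, outcome = oc, slope = est,
          slope_lower = est - 1.96 * se, slope_upper = est + 1.96 * se,
          p_value = p, n = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("intersurvey_summary", "data.frame")
  out
}
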
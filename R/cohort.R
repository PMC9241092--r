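#' Gender-age distribution object
#'
#' Unweighted counts over the six gender-age strata, with derived proportions.
#'
#' @param counts Named (by [ga_labels()]) non-negative integer counts.
#' @return Object of class `ga_distribution`: list with `counts`,
#'   `proportions`, `n`.
#' @export
ga_distribution <- function(counts) {
  counts <- stats::setNames(as.vector(counts), names(counts))
  counts <- normalise_named(counts, ga_labels(), "counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    config_error("counts must be non-negative integers")
  }
  n <- sum(counts)
  counts <- stats::setNames(as.integer(counts), ga_labels())
  structure(list(
    counts = counts,
    proportions = if (n > 0) counts / n else counts * NA_real_,
    n = as.integer(n)
  ), class = "ga_distribution")
}

#' @export
print.ga_distribution <- function(x, ...) {
  cat("Gender-age distribution (n =", x$n, ")\n")
  print(rbind(count = x$counts, proportion = round(x$proportions, 4)))
  invisible(x)
}

#' Apply the eligibility rules
#'
#' Retains adolescents (15-24 years) who report ever having had sex *and*
#' have an HIV test result, and all adults (25-49 years). Respondents with a
#' missing value on a rule are excluded under that rule. The attrition
#' bookkeeping is attached as attribute `eligibility_log`.
#'
#' @param dataset Respondent data.frame.
#' @return Filtered dataset; `attr(, "eligibility_log")` has counts
#'   `removed_ever_sex`, `removed_hiv_test`, `n_in`, `n_out`.
#' @export
filter_eligible <- function(dataset) {
  adol <- dataset$age_group %in% c("15-19", "20-24")
  sex_ok <- !is.na(dataset$ever_had_sex) & dataset$ever_had_sex
  test_ok <- !is.na(dataset$hiv_tested) & dataset$hiv_tested
  removed_sex <- adol & !sex_ok
  removed_test <- adol & sex_ok & !test_ok
  keep <- !adol | (sex_ok & test_ok)
  out <- dataset[keep, , drop = FALSE]
  if (!any(out$age_group %in% c("15-19", "20-24"))) {
    warning("no adolescents survive the eligibility rules; outcome models ",
            "for this dataset will fail", call. = FALSE)
  }
  meta <- attr(dataset, "normgaps_meta")
  attr(out, "normgaps_meta") <- meta
  attr(out, "eligibility_log") <- list(
    n_in = nrow(dataset), n_out = nrow(out),
    removed_ever_sex = sum(removed_sex), removed_hiv_test = sum(removed_test)
  )
  out
}

#' Unweighted gender-age distribution of a dataset
#'
#' @param dataset Respondent data.frame (normally eligibility-filtered).
#' @return A [ga_distribution()].
#' @export
compute_distribution <- function(dataset) {
  if (!nrow(dataset)) data_error("cannot compute a distribution of an empty dataset")
  lab <- factor(ga_label(dataset$gender, dataset$age_group),
                levels = ga_labels())
  ga_distribution(table(lab))
}

#' Cluster-level discordance definition: the attitude-behaviour gap
#'
#' Default discordance measure: the apparent pre-marital-sex behaviour
#' proportion minus the professed approval proportion
#' (`behaviour - (1 - attitude_disapproving)`), expressed in units of 10
#' percentage points so that a fitted coefficient exponentiates directly to a
#' relative risk per 10-pp discordance. Swappable via the `definition`
#' argument of [compute_discordance()].
#'
#' @param attitude_proportion Weighted share of adults disapproving of
#'   pre-marital sex.
#' @param behaviour_proportion Weighted share of adults with evidence of
#'   pre-marital sex.
#' @return Discordance in 10-percentage-point units, in \[-10, 10\].
#' @export
discordance_gap <- function(attitude_proportion, behaviour_proportion) {
  10 * (behaviour_proportion - (1 - attitude_proportion))
}

#' Community discordance table
#'
#' Computes, per (cluster, gender), the design-weighted adult (25-49 years)
#' attitude and behaviour proportions and the derived discordance exposure.
#' Proportions are invariant to rescaling all weights within a cluster.
#' Clusters contributing fewer than `min_adults_per_cluster` adults (with
#' non-missing indicators) for a gender are flagged `excluded` and should not
#' enter modelling.
#'
#' @param dataset Respondent data.frame containing adults with
#'   `attitude_disapproves_premarital` and `behaviour_premarital`.
#' @param min_adults_per_cluster Minimum adults per (cluster, gender) cell.
#' @param definition Function of (attitude, behaviour) proportions returning
#'   discordance in 10-pp units; default [discordance_gap()].
#' @return A `discordance_table` data.frame: `cluster_id`, `gender`,
#'   `attitude_proportion`, `behaviour_proportion`, `discordance`,
#'   `n_adults`, `excluded`.
#' @export
compute_discordance <- function(dataset, min_adults_per_cluster = 10L,
                                definition = discordance_gap) {
  adults <- dataset[dataset$age_group == "25-49", , drop = FALSE]
  ok <- !is.na(adults$attitude_disapproves_premarital) &
    !is.na(adults$behaviour_premarital)
  adults <- adults[ok, , drop = FALSE]
  if (!nrow(adults)) {
    data_error("no adults with attitude and behaviour indicators")
  }
  key <- paste(adults$cluster_id, adults$gender, sep = "\r")
  w <- adults$design_weight
  sw <- rowsum(w, key)
  att <- rowsum(w * as.numeric(adults$attitude_disapproves_premarital),
                key)[, 1] / sw[, 1]
  beh <- rowsum(w * as.numeric(adults$behaviour_premarital), key)[, 1] / sw[, 1]
  n_ad <- rowsum(rep(1L, nrow(adults)), key)[, 1]
  idx <- match(rownames(sw), key)
  out <- data.frame(
    cluster_id = adults$cluster_id[idx],
    gender = as.character(adults$gender[idx]),
    attitude_proportion = as.vector(att),
    behaviour_proportion = as.vector(beh),
    stringsAsFactors = FALSE
  )
  out$discordance <- definition(out$attitude_proportion,
                                out$behaviour_proportion)
  out$n_adults <- as.integer(n_ad)
  out$excluded <- out$n_adults < min_adults_per_cluster
  out <- out[order(out$cluster_id, out$gender), , drop = FALSE]
  rownames(out) <- NULL
  if (all(out$excluded)) {
    data_error(sprintf(
      "all (cluster, gender) cells fall below min_adults_per_cluster = %d",
      min_adults_per_cluster))
  }
  class(out) <- c("discordance_table", "data.frame")
  out
}

#' Attach cluster-level exposures and group covariates to respondents
#'
#' Merges the per-cluster female and male discordance (columns `disc_female`,
#' `disc_male`; `NA` for excluded clusters) and, optionally, cluster-level
#' weighted adult proportions of item covariates (columns `cl_<item>`) onto
#' every respondent row. Exposures computed once from a source dataset are
#' thereby carried by resampled copies of its rows.
#'
#' @param dataset Respondent data.frame.
#' @param disc_table A [compute_discordance()] table.
#' @param items Optional character vector of item covariates to aggregate as
#'   cluster-level proportions from `dataset`'s adults.
#' @return `dataset` with the exposure columns appended.
#' @export
attach_cluster_exposures <- function(dataset, disc_table, items = NULL) {
  for (g in GENDERS) {
    sub <- disc_table[disc_table$gender == g & !disc_table$excluded, ]
    dataset[[paste0("disc_", g)]] <-
      sub$discordance[match(dataset$cluster_id, sub$cluster_id)]
  }
  for (it in items %||% character()) {
    v <- cluster_item_proportion(dataset, it)
    dataset[[paste0("cl_", it)]] <- v[dataset$cluster_id]
  }
  dataset
}

#' Screen survey metadata by the inclusion criteria
#'
#' Classifies each survey as the balanced comparator (male share > 40%),
#' an included imbalanced survey (male share <= 40%), or excluded, applying
#' the criteria in order: gender balance, gender HIV prevalence ratio
#' (women/men PR >= 2.0), individual-level HIV data, post-2005 survey phase.
#' The exclusion reason is the first failing rule.
#'
#' @param metadata data.frame with columns `survey_id`, `year`,
#'   `male_share_total`, `gender_hiv_pr`, `has_individual_hiv`,
#'   `dhs_phase_post2005`.
#' @return data.frame with `survey_id`, `classification` (one of
#'   `balanced_comparator`, `imbalanced_included`, `excluded`) and `reason`.
#' @export
screen_surveys <- function(metadata) {
  required <- c("survey_id", "male_share_total", "gender_hiv_pr",
                "has_individual_hiv", "dhs_phase_post2005")
  miss <- setdiff(required, names(metadata))
  if (length(miss)) {
    data_error(paste("metadata missing field(s):", paste(miss, collapse = ", ")))
  }
  classify <- function(i) {
    row <- metadata[i, ]
    for (f in required) {
      if (is.na(row[[f]])) {
        data_error(sprintf("survey '%s': missing value for field '%s'",
                           row$survey_id, f))
      }
    }
    if (row$gender_hiv_pr <= 0) {
      data_error(sprintf("survey '%s': gender_hiv_pr must be > 0", row$survey_id))
    }
    if (row$gender_hiv_pr < 2.0) {
      return(c("excluded", "low gender HIV PR (women/men PR < 2.0)"))
    }
    if (!row$has_individual_hiv) {
      return(c("excluded", "no individual-level HIV data"))
    }
    if (!row$dhs_phase_post2005) {
      return(c("excluded", "pre-2005 survey phase"))
    }
    if (row$male_share_total > 0.40) {
      c("balanced_comparator", "")
    } else {
      c("imbalanced_included", "")
    }
  }
  res <- t(vapply(seq_len(nrow(metadata)), classify, character(2)))
  data.frame(survey_id = metadata$survey_id, classification = res[, 1],
             reason = res[, 2], stringsAsFactors = FALSE)
}

#' Dissimilarity between two gender-age distributions
#'
#' Maximum absolute relative difference in stratum proportions; two
#' distributions are "dissimilar" when at least one stratum differs by more
#' than `threshold` (default 20%) in relative terms.
#'
#' @param a,b [ga_distribution()] objects (`b` is the reference).
#' @param threshold Relative-difference threshold.
#' @return List with `per_stratum` relative differences, `max`, and
#'   `dissimilar` flag.
#' @export
distribution_dissimilarity <- function(a, b, threshold = 0.20) {
  rel <- abs(a$proportions - b$proportions) / ifelse(b$proportions > 0,
                                                     b$proportions, NA_real_)
  list(per_stratum = rel, max = max(rel, na.rm = TRUE),
       dissimilar = any(rel > threshold, na.rm = TRUE))
}
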
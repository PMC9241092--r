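#' Resampling specification
#'
#' @param target A [ga_distribution()] of target counts.
#' @param n_bootstrap Number of bootstrap replicates (study default 100).
#' @param base_seed Integer master seed; replicate `b` draws its own seed
#'   deterministically via [derive_seed()] so replicates are reproducible
#'   individually and in parallel.
#' @param weight_method Weight recalculation rule, see [recalc_factor()].
#' @return Object of class `resample_spec`.
#' @export
resample_spec <- function(target, n_bootstrap = 100L, base_seed = 1L,
                          weight_method = c("representative", "selection")) {
  if (!inherits(target, "ga_distribution")) target <- ga_distribution(target)
  n_bootstrap <- as.integer(n_bootstrap)
  if (is.na(n_bootstrap) || n_bootstrap < 1L) {
    config_error("n_bootstrap must be >= 1")
  }
  structure(list(target = target, n_bootstrap = n_bootstrap,
                 base_seed = as.integer(base_seed),
                 weight_method = match.arg(weight_method)),
            class = "resample_spec")
}

#' Per-stratum weight recalculation factor
#'
#' Two rules for recalculating design weights after stratified resampling
#' with replacement, both constant within a stratum:
#'
#' * `"selection"`: `N_s / m_s` (source count over target draw count).
#'   Inverts each record's expected resampling multiplicity, so the expected
#'   recalculated weight total of every stratum equals its source weighted
#'   total — the resampled dataset still represents the *source* gender-age
#'   mixture in weighted analyses.
#' * `"representative"` (default in the pipeline): `W * N_s / (M * W_s)`
#'   with `W`/`W_s` the total/stratum source weight mass and `M` the total
#'   target count. Total weight mass is conserved in expectation, but stratum
#'   weighted shares follow the *target* unweighted distribution, so weighted
#'   analyses of the resampled data see the imbalanced gender-age mixture —
#'   the behaviour required for imbalanced sampling to be able to shift
#'   weighted estimates at all (see the methods vignette).
#'
#' @param n_source Named source counts per stratum.
#' @param m_target Named target counts per stratum.
#' @param w_source Named source weighted totals per stratum.
#' @param method `"selection"` or `"representative"`.
#' @return Named per-stratum multiplicative factor (`NA` where the target
#'   count is zero).
#' @export
recalc_factor <- function(n_source, m_target, w_source,
                          method = c("representative", "selection")) {
  method <- match.arg(method)
  f <- switch(method,
    selection = n_source / m_target,
    representative = sum(w_source) * n_source / (sum(m_target) * w_source)
  )
  f[m_target == 0] <- NA_real_
  f
}

#' Resample a dataset to match a target gender-age distribution
#'
#' Draws, uniformly with replacement within each of the six gender-age
#' strata, exactly the target number of records, and recalculates design
#' weights by the per-stratum [recalc_factor()]. Cluster, stratum and
#' household identifiers are preserved from the source records (duplicated
#' draws are distinct rows of the same cluster); fresh unique record ids are
#' assigned with the source id kept in `source_id`.
#'
#' @param balanced Eligibility-filtered source data.frame.
#' @param target [ga_distribution()] of target counts.
#' @param seed Integer seed for the draw.
#' @param weight_method Passed to [recalc_factor()].
#' @return Resampled data.frame whose unweighted stratum counts equal the
#'   target exactly; attribute `recalc_factors` records the per-stratum
#'   weight factors.
#' @export
resample_to_distribution <- function(balanced, target, seed = 1L,
                                     weight_method = c("representative",
                                                       "selection")) {
  weight_method <- match.arg(weight_method)
  if (!inherits(target, "ga_distribution")) target <- ga_distribution(target)
  lab <- ga_label(balanced$gender, balanced$age_group)
  n_source <- vapply(ga_labels(), function(s) sum(lab == s), numeric(1))
  w_source <- vapply(ga_labels(), function(s)
    sum(balanced$design_weight[lab == s]), numeric(1))
  m_target <- target$counts
  empty <- m_target > 0 & n_source == 0
  if (any(empty)) {
    data_error(sprintf(
      "target requires records from empty source stratum(s): %s",
      paste(names(m_target)[empty], collapse = ", ")))
  }
  factors <- recalc_factor(n_source, m_target, w_source, weight_method)
  with_seed(seed, {
    rows <- unlist(lapply(ga_labels(), function(s) {
      if (m_target[[s]] == 0L) return(integer())
      idx <- which(lab == s)
      idx[sample.int(length(idx), m_target[[s]], replace = TRUE)]
    }))
  })
  out <- balanced[rows, , drop = FALSE]
  out$design_weight <- out$design_weight *
    factors[ga_label(out$gender, out$age_group)]
  out$source_id <- out$id
  out$id <- paste0("r", seq_len(nrow(out)))
  rownames(out) <- NULL
  meta <- attr(balanced, "normgaps_meta") %||% list()
  meta$source <- "simulated_imbalanced"
  attr(out, "normgaps_meta") <- meta
  attr(out, "recalc_factors") <- factors
  attr(out, "weight_method") <- weight_method
  out
}

#' Merge a balanced dataset with one resampled dataset
#'
#' Appends the resampled records to the balanced copy after introducing the
#' binary `imbalance` indicator (0 = balanced origin, 1 = resampled origin).
#' Balanced weights are untouched; record ids are disambiguated by arm.
#'
#' @param balanced,resampled Eligibility-filtered data.frames.
#' @return A `merged_dataset` data.frame with `n_balanced + n_resampled` rows.
#' @export
make_merged <- function(balanced, resampled) {
  bal <- balanced
  bal$source_id <- bal$id
  bal$id <- paste0("b", seq_len(nrow(bal)))
  bal$imbalance <- 0L
  res <- resampled
  if (is.null(res$source_id)) res$source_id <- res$id
  res$id <- paste0("r", seq_len(nrow(res)))
  res$imbalance <- 1L
  common <- intersect(names(bal), names(res))
  if (anyDuplicated(c(bal$id, res$id))) {
    data_error("record ids overlap after disambiguation")
  }
  out <- rbind(bal[common], res[common])
  rownames(out) <- NULL
  attr(out, "normgaps_meta") <- list(provenance = "merged", source = "merged")
  attr(out, "recalc_factors") <- attr(resampled, "recalc_factors")
  class(out) <- c("merged_dataset", "data.frame")
  out
}

#' Bootstrap sequence of merged balanced/imbalanced datasets
#'
#' Repeats [resample_to_distribution()] + [make_merged()] `n_bootstrap`
#' times; replicate `b` is seeded as `derive_seed(base_seed, "resample", b)`,
#' so the whole sequence is reproducible and replicates are independent.
#'
#' @param balanced Eligibility-filtered source data.frame.
#' @param spec A [resample_spec()].
#' @return List of `merged_dataset` objects of length `spec$n_bootstrap`.
#' @export
bootstrap_merged <- function(balanced, spec) {
  stopifnot(inherits(spec, "resample_spec"))
  lapply(seq_len(spec$n_bootstrap), function(b) {
    res <- resample_to_distribution(
      balanced, spec$target, seed = derive_seed(spec$base_seed, "resample", b),
      weight_method = spec$weight_method)
    make_merged(balanced, res)
  })
}
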
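#' Packaged gender-age distribution presets
#'
#' Target gender-age distributions keyed by survey. The three marginals
#' (male share of all respondents and within-gender adolescent shares) match
#' the printed descriptive figures for the surveys where those are available:
#' the balanced Zambia 2007 comparator (45.3% male), the male-share extremes
#' Mali 2006 (20.8%) and Haiti 2012 (41.2%), the female adolescent-share
#' minimum Senegal 2010 (5.0%) and the male adolescent-share extremes Lesotho
#' 2009 (42.0%) and Mali 2012 (13.0%). Marginals not printed per survey are
#' filled with the cross-survey averages (29.6% male, 16.8% / 26.8%
#' within-gender adolescent) and flagged `*_illustrative` in the shipped CSV
#' (`inst/extdata/distribution_presets.csv`), which users may edit. The
#' 15-19 / 20-24 split within the adolescent block is taken as equal.
#'
#' @return A data.frame with one row per preset: the marginals, illustrative
#'   flags, and the derived six stratum share columns (`F15_19` ... `M25_49`)
#'   summing to 1.
#' @export
builtin_presets <- function() {
  path <- system.file("extdata", "distribution_presets.csv",
                      package = "normgaps", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  shares <- t(mapply(shares_from_marginals, raw$male_share_total,
                     raw$adol_share_female, raw$adol_share_male))
  colnames(shares) <- ga_labels()
  cbind(raw, as.data.frame(shares))
}

#' Stratum shares of one preset
#'
#' @param preset_id Preset key, e.g. `"ZAMBIA"`, `"MAI06"`.
#' @return Named length-6 share vector over [ga_strata()].
#' @export
preset_shares <- function(preset_id) {
  presets <- builtin_presets()
  row <- presets[presets$preset_id == preset_id, , drop = FALSE]
  if (!nrow(row)) {
    config_error(sprintf("unknown preset id '%s' (available: %s)", preset_id,
                         paste(presets$preset_id, collapse = ", ")))
  }
  unlist(row[1, ga_labels()])
}

#' Integer target distribution from a preset or share vector
#'
#' Converts stratum shares into integer target counts summing exactly to `n`
#' (largest-remainder rounding).
#'
#' @param preset Preset id or named length-6 share vector.
#' @param n Total target count.
#' @return A [ga_distribution()] of counts.
#' @export
preset_target <- function(preset, n) {
  shares <- if (is.character(preset)) preset_shares(preset) else
    normalise_named(preset, ga_labels(), "shares")
  raw <- shares / sum(shares) * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    bump <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  ga_distribution(stats::setNames(as.integer(counts), ga_labels()))
}
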
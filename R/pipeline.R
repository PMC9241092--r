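#' Full experiment configuration
#'
#' @param generator A [generator_config()] (or argument list) for the
#'   balanced source survey, or `NULL` with `dataset_path` pointing at a CSV.
#' @param dataset_path Optional path to a respondent CSV to load instead of
#'   generating.
#' @param targets Character vector of preset ids (see [builtin_presets()])
#'   and/or a named list of [ga_distribution()] objects.
#' @param pathways Subset of `c("ff", "fm", "mf", "mm")`.
#' @param scenarios Covariate scenario ids to evaluate (subset of 1..6).
#' @param B Bootstrap replicates per target.
#' @param base_seed Master seed; all stages derive named sub-streams from it.
#' @param out_dir Output directory for the results bundle.
#' @param level Significance cut-off in (0, 1).
#' @param weight_method,p_rule Passed to the resampler and interaction test.
#' @param min_adults_per_cluster Minimum adults per (cluster, gender).
#' @return Object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(), dataset_path = NULL,
                       targets = c("MAI06", "HAI12"),
                       pathways = c("ff", "fm", "mf", "mm"),
                       scenarios = 1:6, B = 100L, base_seed = 1L,
                       out_dir = "normgaps-results", level = 0.05,
                       weight_method = "representative", p_rule = "robust",
                       min_adults_per_cluster = 10L) {
  if (level <= 0 || level >= 1) config_error("level must lie in (0, 1)")
  if (B < 1) config_error("B must be >= 1")
  bad <- setdiff(pathways, c("ff", "fm", "mf", "mm"))
  if (length(bad)) config_error(paste("unknown pathway(s):",
                                      paste(bad, collapse = ", ")))
  if (length(scenarios) && !all(scenarios %in% 1:6)) {
    config_error("scenarios must be ids in 1..6")
  }
  if (is.character(targets)) {
    known <- builtin_presets()$preset_id
    bad <- setdiff(targets, known)
    if (length(bad)) {
      config_error(paste("unknown preset id(s):", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(dataset_path) && !file.exists(dataset_path)) {
    config_error(paste("dataset_path does not exist:", dataset_path))
  }
  structure(list(
    generator = generator, dataset_path = dataset_path, targets = targets,
    pathways = pathways, scenarios = scenarios, B = as.integer(B),
    base_seed = as.integer(base_seed), out_dir = out_dir, level = level,
    weight_method = weight_method, p_rule = p_rule,
    min_adults_per_cluster = as.integer(min_adults_per_cluster)
  ), class = "run_config")
}

# FNV-style rolling hash of a string (config fingerprint for the manifest);
# kept within 2^50 so double arithmetic is exact
fnv1a <- function(s) {
  h <- 2166136261 %% 2^26
  for (b in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^26
  }
  sprintf("%07x", as.integer(h))
}

config_json <- function(config) {
  ser <- rapply(unclass(config), function(x) x, how = "replace")
  as.character(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop_normgaps(sprintf("[stage %s] %s", name, conditionMessage(e)),
                  "normgaps_stage_error")
  })
}

#' Run the full imbalance/missingness experiment
#'
#' Sequences generation (or loading), eligibility filtering, discordance and
#' group-covariate construction, per-target bootstrap resampling, interaction
#' tests, missingness Wald tests (alone on the balanced data, and jointly on
#' the merged replicates), and the inter-survey meta-analysis. Writes a
#' manifest (`manifest.json`), tidy CSVs with fixed column order and
#' 6-significant-digit formatting, and a plain-text report to
#' `config$out_dir`. Two runs from an identical config produce byte-identical
#' tidy outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) the results bundle: a list with `config`,
#'   `interaction` (tidy data.frame), `wald_missingness`, `wald_joint`,
#'   `intersurvey_logit`, `intersurvey_linear`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(config$out_dir, "INCOMPLETE")
  file.create(incomplete)

  source_data <- stage("generate", {
    if (!is.null(config$dataset_path)) {
      utils::read.csv(config$dataset_path, stringsAsFactors = FALSE)
    } else {
      gen <- config$generator
      if (!inherits(gen, "normgaps_config")) gen <- do.call(generator_config, gen)
      gen$seed <- derive_seed(config$base_seed, "generator", 0L)
      generate_survey(gen)$data
    }
  })
  eligible <- stage("eligibility", filter_eligible(source_data))
  eligible <- stage("discordance", {
    disc <- compute_discordance(eligible, config$min_adults_per_cluster)
    attach_cluster_exposures(eligible, disc, items = NORM_ITEMS)
  })

  targets <- stage("targets", {
    if (is.character(config$targets)) {
      tg <- lapply(config$targets, function(id)
        preset_target(id, n = nrow(eligible)))
      names(tg) <- config$targets
      tg
    } else config$targets
  })
  specs <- pathway_specs()[config$pathways]

  interaction_rows <- list()
  joint_rows <- list()
  recalc_log <- list()
  for (ti in seq_along(targets)) {
    tname <- names(targets)[ti]
    reps <- stage(paste0("resample:", tname), bootstrap_merged(
      eligible, resample_spec(targets[[ti]], n_bootstrap = config$B,
                              base_seed = derive_seed(config$base_seed,
                                                      "resample", ti * 100000L),
                              weight_method = config$weight_method)))
    recalc_log[[tname]] <- as.list(attr(reps[[1]], "recalc_factors"))
    for (spec in specs) {
      s <- stage(paste0("interaction:", tname, ":", spec$pathway),
                 interaction_test(reps, spec, level = config$level,
                                  p_rule = config$p_rule,
                                  min_adults_per_cluster =
                                    config$min_adults_per_cluster))
      interaction_rows[[length(interaction_rows) + 1L]] <- data.frame(
        target = tname, pathway = spec$pathway, B = s$B,
        discordance_mean = s$terms$discordance$mean,
        discordance_sd = s$terms$discordance$sd,
        imbalance_mean = s$terms$imbalance$mean,
        imbalance_sd = s$terms$imbalance$sd,
        interaction_mean = s$terms$interaction$mean,
        interaction_sd = s$terms$interaction$sd,
        interaction_p = s$terms$interaction$p,
        rr_balanced = s$rr_balanced$point,
        rr_balanced_lower = s$rr_balanced$lower,
        rr_balanced_upper = s$rr_balanced$upper,
        rr_imbalanced = s$rr_imbalanced$point,
        rr_imbalanced_lower = s$rr_imbalanced$lower,
        rr_imbalanced_upper = s$rr_imbalanced$upper,
        significant_interaction = s$significant_interaction,
        biased_away = s$rr_ci_disjoint_from_baseline,
        unreliable = s$unreliable, stringsAsFactors = FALSE)
      for (sc in config$scenarios) {
        w <- stage(paste0("joint-wald:", tname, ":", spec$pathway, ":", sc),
                   joint_imbalance_missingness(
                     reps, spec, sc,
                     min_adults_per_cluster = config$min_adults_per_cluster))
        joint_rows[[length(joint_rows) + 1L]] <- data.frame(
          target = tname, pathway = spec$pathway, scenario_id = sc,
          mean_F = w$F_statistic, df = w$df_numerator, p_value = w$p_value,
          significant = w$significant, stringsAsFactors = FALSE)
      }
    }
  }
  interaction <- do.call(rbind, interaction_rows)
  wald_joint <- if (length(joint_rows)) do.call(rbind, joint_rows) else NULL

  wald_missingness <- stage("missingness-wald", {
    rows <- list()
    for (spec in specs) {
      for (sc in config$scenarios) {
        w <- wald_full_vs_reduced(eligible, spec, sc,
                                  min_adults_per_cluster =
                                    config$min_adults_per_cluster)
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = spec$pathway, scenario_id = sc, F_statistic = w$F_statistic,
          df = w$df_numerator, p_value = w$p_value,
          significant = w$significant, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  meta <- stage("intersurvey", {
    summaries <- interaction[, c("target", "pathway",
                                 "significant_interaction",
                                 "interaction_mean", "rr_imbalanced")]
    names(summaries)[names(summaries) == "rr_imbalanced"] <- "rr"
    records <- suppressWarnings(intersurvey_records(targets, summaries))
    logit <- tryCatch(suppressWarnings(fit_significance_logit(records)),
                      error = function(e) NULL)
    linear <- tryCatch(suppressWarnings(fit_outcome_linear(records)),
                       error = function(e) NULL)
    list(records = records, logit = logit, linear = linear)
  })

  paths <- stage("write", {
    cj <- config_json(config)
    manifest <- list(
      package = "normgaps",
      version = as.character(utils::packageVersion("normgaps")),
      config_hash = fnv1a(cj),
      config = jsonlite::fromJSON(cj),
      base_seed = config$base_seed,
      seed_streams = list(
        generator = derive_seed(config$base_seed, "generator", 0L),
        resample_targets = vapply(seq_along(targets), function(ti)
          derive_seed(config$base_seed, "resample", ti * 100000L), integer(1))
      ),
      targets = lapply(targets, function(t) as.list(t$counts)),
      recalc_factors = recalc_log,
      n_eligible = nrow(eligible)
    )
    p <- list(manifest = file.path(config$out_dir, "manifest.json"),
              interaction = file.path(config$out_dir, "interaction_summary.csv"),
              wald_missingness = file.path(config$out_dir, "wald_missingness.csv"),
              wald_joint = file.path(config$out_dir, "wald_joint.csv"),
              intersurvey_logit = file.path(config$out_dir, "intersurvey_logit.csv"),
              intersurvey_linear = file.path(config$out_dir, "intersurvey_linear.csv"),
              report = file.path(config$out_dir, "report.txt"))
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    write_tidy_csv(interaction, p$interaction)
    write_tidy_csv(wald_missingness, p$wald_missingness)
    if (!is.null(wald_joint)) write_tidy_csv(wald_joint, p$wald_joint)
    if (!is.null(meta$logit)) write_tidy_csv(meta$logit, p$intersurvey_logit)
    if (!is.null(meta$linear)) write_tidy_csv(meta$linear, p$intersurvey_linear)
    p
  })

  bundle <- list(config = config, interaction = interaction,
                 wald_missingness = wald_missingness, wald_joint = wald_joint,
                 intersurvey_logit = meta$logit,
                 intersurvey_linear = meta$linear, paths = paths)
  writeLines(render_report(bundle), paths$report)
  unlink(incomplete)
  invisible(bundle)
}

#' Render a plain-text report of a results bundle
#'
#' Per pathway: how many target scenarios yielded a significant interaction,
#' how many biased the RR away from the balanced baseline, the missingness
#' Wald summary, and the inter-survey slopes/ORs. Regeneration from the same
#' bundle is idempotent. An incomplete bundle yields a partial report with
#' warnings embedded in the text.
#'
#' @param bundle A results bundle from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  lines <- c("normgaps experiment report",
             "==========================", "")
  it <- bundle$interaction
  if (is.null(it)) {
    lines <- c(lines, "WARNING: interaction results missing (incomplete bundle)")
  } else {
    lines <- c(lines, "Interaction tests (imbalanced sampling):")
    for (pw in unique(it$pathway)) {
      sub <- it[it$pathway == pw, ]
      lines <- c(lines, sprintf(
        "  pathway %s: significant interaction in %d/%d targets; RR CI excluded balanced baseline in %d/%d",
        pw, sum(sub$significant_interaction), nrow(sub),
        sum(sub$biased_away), nrow(sub)))
    }
  }
  wm <- bundle$wald_missingness
  lines <- c(lines, "", "Missing-covariate Wald tests (balanced data):")
  if (is.null(wm)) {
    lines <- c(lines, "  WARNING: missingness results absent")
  } else {
    for (pw in unique(wm$pathway)) {
      sub <- wm[wm$pathway == pw, ]
      lines <- c(lines, sprintf(
        "  pathway %s: model fit significantly changed in %d/%d scenarios",
        pw, sum(sub$significant), nrow(sub)))
    }
  }
  wj <- bundle$wald_joint
  if (!is.null(wj)) {
    lines <- c(lines, "", "Joint imbalance x missingness Wald tests:")
    for (pw in unique(wj$pathway)) {
      sub <- wj[wj$pathway == pw, ]
      lines <- c(lines, sprintf(
        "  pathway %s: significant in %d/%d target-scenarios",
        pw, sum(sub$significant), nrow(sub)))
    }
  }
  lg <- bundle$intersurvey_logit
  if (!is.null(lg)) {
    lines <- c(lines, "", "Inter-survey logistic meta-analysis (OR per 1 pp share):")
    est <- ifelse(lg$inestimable, "inestimable (constant outcome)",
                  sprintf("OR %.3f (%.3f-%.3f)%s", lg$or_per_pp, lg$or_lower,
                          lg$or_upper,
                          ifelse(lg$separation, " [separation]", "")))
    lines <- c(lines, sprintf("  %s ~ %s: %s", lg$pathway, lg$predictor, est))
  }
  ln <- bundle$intersurvey_linear
  if (!is.null(ln)) {
    lines <- c(lines, "", "Inter-survey linear meta-analysis (slope per unit share):")
    lines <- c(lines, sprintf("  %s: %s ~ %s: slope %.4f (%.4f-%.4f)",
                              ln$pathway, ln$outcome, ln$predictor, ln$slope,
                              ln$slope_lower, ln$slope_upper))
  }
  lines
}
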
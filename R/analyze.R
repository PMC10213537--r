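#' Analysis configuration
#'
#' Collects every tunable of the full pipeline with its default: the SD
#' imputation CV (0.10), the CI method (parametric, i.e. +/- 1.96 SE),
#' the effects model (fixed, weights exactly 1/v), the random-forest
#' parameters (500 trees, `mtry = ceiling(p/3)`), and the seed recorded in
#' every output.
#'
#' @param cv_imputation CV for missing-SD imputation.
#' @param sd_policy `"fixed-cv"` or `"average-cv"`.
#' @param ci_method `"parametric"` or `"bootstrap"`.
#' @param boot_reps Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param effects_model `"fixed"` or `"random"`.
#' @param crops,outcomes Optional filters.
#' @param var_floor Minimum admissible sampling variance.
#' @param low_n Reporting floor for flagging small bins.
#' @param rf_trees,rf_mtry Random-forest size parameters.
#' @param top_moderators Number of top-ranked moderators fitted as
#'   response curves per outcome.
#' @param curve_form Curve form passed to [fit_response_curve()].
#' @param seed Integer seed governing every stochastic step.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cv_imputation = 0.10,
                            sd_policy = c("fixed-cv", "average-cv"),
                            ci_method = c("parametric", "bootstrap"),
                            boot_reps = 4999,
                            effects_model = c("fixed", "random"),
                            crops = NULL, outcomes = NULL,
                            var_floor = 1e-6, low_n = 3,
                            rf_trees = 500, rf_mtry = NULL,
                            top_moderators = 3,
                            curve_form = "auto", seed = 1) {
  sd_policy <- match.arg(sd_policy)
  ci_method <- match.arg(ci_method)
  effects_model <- match.arg(effects_model)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the complete synthesis on a database
#'
#' The one-call driver: validates nothing itself (feed it the output of
#' [read_database()] or [generate_database()]), then computes effect
#' sizes, the overall and subgroup pooled effects for every crop-outcome
#' stratum, the random-forest moderator importance per outcome, and
#' dose-response curves (with optimum and upward zero crossing) for the
#' top-ranked continuous moderators. Deterministic for a fixed database
#' and config.
#'
#' @param records Validated comparison records.
#' @param config An [analysis_config()].
#' @return A `meta_report` list: `effects`, `pooled` (long subgroup
#'   table), `importance` (per outcome), `curves` (list of
#'   `response_curve`), `optima` (summary tibble) and `manifest`.
#' @examples
#' rep <- analyze_database(make_fixture("tiny")$database)
#' rep$pooled[rep$pooled$variable == "overall", ]
#' @export
analyze_database <- function(records, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (nrow(records) == 0) stop("empty database", call. = FALSE)
  eff <- effect_sizes(records, cv = config$cv_imputation,
                      policy = config$sd_policy,
                      var_floor = config$var_floor)
  pooled <- run_full_analysis(records, cv = config$cv_imputation,
                              policy = config$sd_policy,
                              var_floor = config$var_floor,
                              crops = config$crops,
                              outcomes = config$outcomes,
                              low_n = config$low_n,
                              model = config$effects_model,
                              ci_method = config$ci_method,
                              boot_reps = config$boot_reps,
                              seed = config$seed)

  continuous <- setdiff(names(moderator_schemes()),
                        c("crop", "climate_type"))
  outcomes <- intersect(outcome_levels, unique(eff$outcome))
  importance <- list(); curves <- list(); optima <- NULL
  for (oc in outcomes) {
    sub <- eff[eff$outcome == oc, ]
    imp <- tryCatch(
      rf_importance(sub, n_trees = config$rf_trees, mtry = config$rf_mtry,
                    seed = config$seed),
      error = function(e) NULL)
    importance[[oc]] <- imp
    if (is.null(imp)) next
    top <- intersect(imp$moderator, continuous)
    top <- utils::head(top, config$top_moderators)
    for (m in top) {
      cur <- tryCatch(
        fit_response_curve(sub, m, form = config$curve_form),
        error = function(e) NULL)
      if (is.null(cur)) next
      curves[[paste(oc, m, sep = ".")]] <- cur
      optima <- dplyr::bind_rows(optima, dplyr::mutate(
        glance(cur), outcome = oc, moderator = m, .before = 1))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("manuremeta")),
    config = unclass(config), seed = config$seed,
    n_records = nrow(records), n_effects = nrow(eff),
    crops = unique(records$crop), outcomes = outcomes
  )
  structure(list(effects = eff, pooled = pooled, importance = importance,
                 curves = curves, optima = optima, manifest = manifest),
            class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  cat("<meta_report> ", x$manifest$n_effects, " comparisons, crops: ",
      paste(x$manifest$crops, collapse = "/"), ", outcomes: ",
      paste(x$manifest$outcomes, collapse = "/"), ", seed ",
      x$manifest$seed, "\n", sep = "")
  ov <- x$pooled[x$pooled$variable == "overall", ]
  cat("Overall pooled effects (percent change, 95% CI):\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-6s %-6s %+5.1f%% (%+.1f, %+.1f) k=%d%s\n",
                ov$crop[i], ov$outcome[i], ov$pct_change[i],
                ov$pct_ci_low[i], ov$pct_ci_high[i], ov$k[i],
                ifelse(ov$significant[i], " *", "")))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Exports a [analyze_database()] result as plain-text files: the effect
#' table, the pooled subgroup table (CSV and Markdown), one importance CSV
#' per outcome, the curve summary, and a run manifest (package version,
#' configuration, seed, row counts).
#'
#' @param report A `meta_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "meta_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_effect_sizes(report$effects, file.path(dir, "effect_sizes.csv"))
  write_report(report$pooled, file.path(dir, "pooled_effects.csv"))
  write_report(report$pooled, file.path(dir, "pooled_effects.md"))
  for (oc in names(report$importance)) {
    imp <- report$importance[[oc]]
    if (!is.null(imp)) {
      readr::write_csv(tibble::as_tibble(imp),
                       file.path(dir, paste0("importance_", oc, ".csv")),
                       progress = FALSE)
    }
  }
  if (!is.null(report$optima)) {
    readr::write_csv(report$optima, file.path(dir, "response_curves.csv"),
                     progress = FALSE)
  }
  manifest <- report$manifest
  manifest$config <- manifest$config[!vapply(manifest$config, is.null,
                                             logical(1))]
  lines <- c("# run manifest",
             paste0("package_version: ", manifest$package_version),
             paste0("seed: ", manifest$seed),
             paste0("n_records: ", manifest$n_records),
             paste0("crops: ", paste(manifest$crops, collapse = ",")),
             paste0("outcomes: ", paste(manifest$outcomes, collapse = ",")),
             "config:",
             paste0("  ", names(manifest$config), ": ",
                    vapply(manifest$config, function(v) {
                      paste(format(unlist(v)), collapse = ",")
                    }, character(1))))
  writeLines(lines, file.path(dir, "manifest.yml"))
  invisible(dir)
}
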
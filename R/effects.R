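#' Log response ratio of a paired comparison
#'
#' The effect size used throughout the package: the natural logarithm of
#' the treatment-to-control ratio of outcome means,
#' `RR = ln(mean_NPKM / mean_NPK)`. A positive value means manure
#' substitution increased the outcome; `(exp(RR) - 1) * 100` is the percent
#' change relative to the NPK control.
#'
#' @param mean_npk,mean_npkm Strictly positive arm means.
#' @return Numeric vector of log response ratios.
#' @examples
#' log_response_ratio(5.21, 5.38)
#' @export
log_response_ratio <- function(mean_npk, mean_npkm) {
  if (any(!(mean_npk > 0) | !(mean_npkm > 0), na.rm = FALSE)) {
    stop("arm means must be strictly positive for a log response ratio",
         call. = FALSE)
  }
  log(mean_npkm / mean_npk)
}

#' Sampling variance of a log response ratio
#'
#' Delta-method variance of `ln(mean_NPKM / mean_NPK)` from the arm
#' summaries:
#' `v = SD_NPKM^2 / (n_NPKM * mean_NPKM^2) + SD_NPK^2 / (n_NPK * mean_NPK^2)`.
#' Each term is the squared relative standard error of one arm, so `v`
#' depends on the data only through CV^2 / n per arm. When both arms report
#' an SD of zero the variance is replaced by `var_floor` (a zero variance
#' would give that single comparison infinite weight).
#'
#' @param mean_npk,sd_npk,n_npk Control arm mean, SD and replicate count.
#' @param mean_npkm,sd_npkm,n_npkm Treatment arm summaries.
#' @param var_floor Minimum admissible variance; default `1e-6`.
#' @return Numeric vector of sampling variances, floored at `var_floor`.
#' @examples
#' sampling_variance(5, 0.5, 3, 5, 0.5, 3)
#' @export
sampling_variance <- function(mean_npk, sd_npk, n_npk,
                              mean_npkm, sd_npkm, n_npkm,
                              var_floor = 1e-6) {
  v <- sd_npkm^2 / (n_npkm * mean_npkm^2) + sd_npk^2 / (n_npk * mean_npk^2)
  pmax(v, var_floor)
}

#' Impute missing arm standard deviations
#'
#' Studies that do not report arm SDs would otherwise drop out of the
#' inverse-variance synthesis. The default policy replaces a missing SD by
#' `cv * mean` of its arm with a fixed coefficient of variation (default
#' 0.10, common practice in ecological meta-analysis). The `"average-cv"`
#' policy instead uses the mean observed CV of SD-complete records in the
#' same crop-outcome stratum, falling back to the fixed `cv` (with a
#' warning) when a stratum has no complete records. Imputed rows are
#' flagged in `sd_imputed`.
#'
#' @param records Tibble of validated comparison records.
#' @param cv Fixed coefficient of variation used by the `"fixed-cv"` policy
#'   and as fallback; must be positive.
#' @param policy `"fixed-cv"` (default) or `"average-cv"`.
#' @return `records` with missing SDs filled and a logical `sd_imputed`
#'   column.
#' @export
impute_missing_sd <- function(records, cv = 0.10,
                              policy = c("fixed-cv", "average-cv")) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(cv), cv > 0)
  records <- tibble::as_tibble(records)
  missing_sd <- is.na(records$sd_npk) | is.na(records$sd_npkm)
  records$sd_imputed <- missing_sd
  if (!any(missing_sd)) return(records)

  if (policy == "fixed-cv") {
    records$cv_used <- cv
  } else {
    complete <- records[!missing_sd, ]
    stratum_cv <- dplyr::summarise(
      dplyr::group_by(complete, .data$crop, .data$outcome),
      cv_used = mean(c(.data$sd_npk / .data$mean_npk,
                       .data$sd_npkm / .data$mean_npkm)),
      .groups = "drop"
    )
    records <- dplyr::left_join(records, stratum_cv,
                                by = c("crop", "outcome"))
    if (any(is.na(records$cv_used) & missing_sd)) {
      warning("no SD-complete records in some crop-outcome strata; ",
              "falling back to fixed cv = ", cv, call. = FALSE)
    }
    records$cv_used[is.na(records$cv_used)] <- cv
  }
  records$sd_npk <- ifelse(is.na(records$sd_npk),
                           records$cv_used * records$mean_npk,
                           records$sd_npk)
  records$sd_npkm <- ifelse(is.na(records$sd_npkm),
                            records$cv_used * records$mean_npkm,
                            records$sd_npkm)
  records$cv_used <- NULL
  records
}

#' Per-comparison effect sizes, variances and weights
#'
#' Computes, for every validated comparison record, the log response ratio
#' [log_response_ratio()], its sampling variance [sampling_variance()] and
#' the inverse-variance weight `w = 1/v`, after filling missing SDs with
#' [impute_missing_sd()]. This is the table every downstream stage (pooling,
#' subgroup analysis, moderator models) consumes.
#'
#' @param records Tibble of validated comparison records.
#' @inheritParams impute_missing_sd
#' @inheritParams sampling_variance
#' @return The input tibble with columns `rr`, `variance`, `weight`,
#'   `sd_imputed` and `var_floored` appended.
#' @examples
#' db <- make_fixture("tiny")$database
#' effect_sizes(db)[, c("crop", "outcome", "rr", "variance", "weight")]
#' @export
effect_sizes <- function(records, cv = 0.10,
                         policy = c("fixed-cv", "average-cv"),
                         var_floor = 1e-6) {
  records <- impute_missing_sd(records, cv = cv, policy = policy)
  raw_v <- sampling_variance(records$mean_npk, records$sd_npk, records$n_npk,
                             records$mean_npkm, records$sd_npkm,
                             records$n_npkm, var_floor = 0)
  dplyr::mutate(records,
                rr = log_response_ratio(.data$mean_npk, .data$mean_npkm),
                variance = pmax(raw_v, var_floor),
                weight = 1 / .data$variance,
                var_floored = raw_v < var_floor)
}

#' Export the effect-size table
#'
#' Writes the per-comparison effect sizes in a compact CSV layout
#' (`study_id`, `crop`, `outcome`, `rr`, `variance`, `weight`,
#' `sd_imputed`).
#'
#' @param effects Output of [effect_sizes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(effects, path) {
  cols <- c("study_id", "crop", "outcome", "rr", "variance", "weight",
            "sd_imputed")
  readr::write_csv(effects[, intersect(cols, names(effects))], path,
                   progress = FALSE)
  invisible(path)
}
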
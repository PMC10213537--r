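#' Percent change implied by a pooled log response ratio
#'
#' Back-transforms a (pooled) log response ratio to the percent change of
#' the manure-substitution treatment relative to the NPK control:
#' `(exp(rr) - 1) * 100`. `pct_to_log_ratio()` is its exact inverse.
#'
#' @param rr_pp Log response ratio (pooled or per-comparison).
#' @return Percent change.
#' @examples
#' percent_change(log(1.10))  # 10
#' @export
percent_change <- function(rr_pp) (exp(rr_pp) - 1) * 100

#' @rdname percent_change
#' @param pct Percent change.
#' @export
pct_to_log_ratio <- function(pct) log(1 + pct / 100)

# DerSimonian-Laird method-of-moments between-study variance
dl_tau2 <- function(rr, v) {
  k <- length(rr)
  if (k < 2) return(0)
  w <- 1 / v
  mu <- sum(w * rr) / sum(w)
  q <- sum(w * (rr - mu)^2)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Pool effect sizes by inverse-variance weighting
#'
#' The weighted mean log response ratio over a group of comparisons,
#' `RR++ = sum(w * rr) / sum(w)` with `w = 1/v`, its standard error
#' `SE = sqrt(1 / sum(w))`, and the 95% confidence interval
#' `RR++ +/- 1.96 SE`. The effect is classed significant when the CI
#' excludes zero. Percent change is the back-transform
#' `(exp(RR++) - 1) * 100`, with CI bounds transformed the same way.
#'
#' With `model = "random"`, a DerSimonian-Laird method-of-moments
#' between-study variance is added to every sampling variance before
#' weighting. With `ci_method = "bootstrap"`, a bias-corrected percentile
#' bootstrap over comparisons (default 4999 resamples) replaces the
#' parametric CI; the point estimate and SE are unchanged.
#'
#' @param effects Tibble with columns `rr` and `variance` (e.g. from
#'   [effect_sizes()]).
#' @param model `"fixed"` (default, weights exactly `1/v`) or `"random"`.
#' @param ci_method `"parametric"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row tibble: `k`, `rr_pp`, `se`, `ci_low`, `ci_high`,
#'   `pct_change`, `pct_ci_low`, `pct_ci_high`, `significant`, `tau2`.
#' @examples
#' eff <- tibble::tibble(rr = c(0.02, 0.04), variance = c(0.001, 0.002))
#' pool_effects(eff)
#' @export
pool_effects <- function(effects, model = c("fixed", "random"),
                         ci_method = c("parametric", "bootstrap"),
                         boot_reps = 4999, seed = NULL) {
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  rr <- effects$rr
  v <- effects$variance
  if (length(rr) == 0) stop("no comparisons in group", call. = FALSE)
  stopifnot(all(is.finite(rr)), all(v > 0))

  tau2 <- if (model == "random") dl_tau2(rr, v) else 0
  w <- 1 / (v + tau2)
  rr_pp <- sum(w * rr) / sum(w)
  se <- 1 / sqrt(sum(w))
  ci <- rr_pp + c(-1, 1) * 1.96 * se

  if (ci_method == "bootstrap" && length(rr) >= 2) {
    boot_one <- function(idx) {
      wb <- w[idx]
      sum(wb * rr[idx]) / sum(wb)
    }
    draw <- function() {
      stats <- vapply(seq_len(boot_reps), function(i) {
        boot_one(sample.int(length(rr), replace = TRUE))
      }, numeric(1))
      # bias-corrected percentile bounds
      z0 <- stats::qnorm(mean(stats < rr_pp))
      probs <- stats::pnorm(2 * z0 + c(-1.96, 1.96))
      stats::quantile(stats, probs, names = FALSE, type = 7)
    }
    ci <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }

  tibble::tibble(
    k = length(rr), rr_pp = rr_pp, se = se,
    ci_low = ci[1], ci_high = ci[2],
    pct_change = percent_change(rr_pp),
    pct_ci_low = percent_change(ci[1]),
    pct_ci_high = percent_change(ci[2]),
    significant = ci[1] > 0 | ci[2] < 0,
    tau2 = tau2
  )
}

#' Subgroup analysis of one moderator
#'
#' Splits the per-comparison effect sizes of one crop-outcome stratum into
#' the bins of a moderator's [grouping_scheme()] and pools each bin with
#' [pool_effects()], alongside an overall (all-bins) row. Comparisons with
#' a missing moderator value are excluded from the bins (their count is
#' reported in the `"n_unknown"` attribute) but still contribute to the
#' overall row. Bins with no comparisons appear with `k = 0` and no
#' estimate; bins with fewer comparisons than `low_n` are estimated but
#' flagged `low_n = TRUE`. No multiplicity adjustment is applied across
#' bins or moderators.
#'
#' @param effects Output of [effect_sizes()].
#' @param variable Moderator column name (must be in [moderator_schemes()]
#'   unless `scheme` is given).
#' @param scheme Optional [grouping_scheme()] overriding the standard one.
#' @param crop,outcome Optional filters applied before binning.
#' @param low_n Reporting floor below which a bin is flagged; default 3.
#' @inheritParams pool_effects
#' @return A `subgroup_report` tibble: one row per bin plus the overall
#'   row, columns `variable`, `bin`, `k`, `low_n` and the [pool_effects()]
#'   columns.
#' @examples
#' eff <- effect_sizes(make_fixture("null")$database)
#' subgroup_analysis(eff, "substitution_rate", outcome = "yield")
#' @export
subgroup_analysis <- function(effects, variable, scheme = NULL,
                              crop = NULL, outcome = NULL, low_n = 3,
                              model = c("fixed", "random"),
                              ci_method = c("parametric", "bootstrap"),
                              boot_reps = 4999, seed = NULL) {
  if (is.null(scheme)) {
    schemes <- moderator_schemes()
    if (!variable %in% names(schemes)) {
      stop("no grouping scheme for variable '", variable, "'", call. = FALSE)
    }
    scheme <- schemes[[variable]]
  }
  if (!variable %in% names(effects)) {
    stop("variable '", variable, "' absent from the effect table",
         call. = FALSE)
  }
  dat <- effects
  if (!is.null(crop)) dat <- dat[dat$crop %in% crop, ]
  if (!is.null(outcome)) dat <- dat[dat$outcome %in% outcome, ]
  if (nrow(dat) == 0) stop("no comparisons in group", call. = FALSE)

  dat$.bin <- assign_bin(dat[[variable]], scheme)
  pool_or_na <- function(sub) {
    if (nrow(sub) == 0) {
      tibble::tibble(k = 0L, rr_pp = NA_real_, se = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     pct_change = NA_real_, pct_ci_low = NA_real_,
                     pct_ci_high = NA_real_, significant = NA, tau2 = NA_real_)
    } else {
      pool_effects(sub, model = model, ci_method = ci_method,
                   boot_reps = boot_reps, seed = seed)
    }
  }
  rows <- purrr::map(scheme$labels, function(lab) {
    dplyr::mutate(pool_or_na(dat[dat$.bin == lab, ]), bin = lab)
  })
  overall <- dplyr::mutate(pool_or_na(dat), bin = "overall")
  out <- dplyr::bind_rows(c(list(overall), rows))
  out <- dplyr::mutate(out,
                       variable = variable,
                       low_n = .data$k < low_n,
                       .before = 1)
  out <- dplyr::relocate(out, "bin", .after = "variable")
  attr(out, "n_unknown") <- sum(dat$.bin == "unknown")
  class(out) <- c("subgroup_report", class(out))
  out
}

#' Run the full subgroup synthesis over a database
#'
#' For every crop-outcome stratum present in the database, pools the
#' overall effect and every moderator subgroup in [moderator_schemes()].
#' This is the table behind the forest-plot style summaries of the
#' synthesis: percent change with 95% CI per bin, with sample sizes.
#'
#' @param records Validated comparison records (see [read_database()]).
#' @param cv,policy,var_floor Passed to [effect_sizes()].
#' @param crops,outcomes Optional filters; default all present.
#' @inheritParams subgroup_analysis
#' @return Long tibble with columns `crop`, `outcome`, `variable`, `bin`
#'   and the pooled-effect columns; `variable = "overall"` rows carry the
#'   stratum-wide pooled effect.
#' @export
run_full_analysis <- function(records, cv = 0.10,
                              policy = c("fixed-cv", "average-cv"),
                              var_floor = 1e-6, crops = NULL,
                              outcomes = NULL, low_n = 3,
                              model = c("fixed", "random"),
                              ci_method = c("parametric", "bootstrap"),
                              boot_reps = 4999, seed = NULL) {
  if (nrow(records) == 0) stop("empty database", call. = FALSE)
  eff <- effect_sizes(records, cv = cv, policy = policy,
                      var_floor = var_floor)
  crops <- crops %||% intersect(crop_levels, unique(eff$crop))
  outcomes <- outcomes %||% intersect(outcome_levels, unique(eff$outcome))
  grid <- tidyr::expand_grid(crop = crops, outcome = outcomes)
  full <- tidyr::expand_grid(crop = crop_levels, outcome = outcome_levels)
  absent <- dplyr::anti_join(full, grid, by = c("crop", "outcome"))
  if (nrow(absent) > 0) {
    message("no comparisons for ",
            paste(absent$crop, absent$outcome, sep = "/", collapse = ", "),
            "; strata skipped")
  }

  purrr::pmap_dfr(grid, function(crop, outcome) {
    sub <- eff[eff$crop == crop & eff$outcome == outcome, ]
    if (nrow(sub) == 0) {
      message("no ", crop, "/", outcome, " comparisons; stratum skipped")
      return(NULL)
    }
    overall <- dplyr::mutate(
      pool_effects(sub, model = model, ci_method = ci_method,
                   boot_reps = boot_reps, seed = seed),
      variable = "overall", bin = "overall", low_n = .data$k < low_n,
      .before = 1)
    per_var <- purrr::map(names(moderator_schemes()), function(v) {
      subgroup_analysis(sub, v, low_n = low_n, model = model,
                        ci_method = ci_method, boot_reps = boot_reps,
                        seed = seed)
    })
    res <- dplyr::bind_rows(c(list(overall), per_var))
    dplyr::mutate(res, crop = crop, outcome = outcome, .before = 1)
  })
}

#' Export a subgroup report
#'
#' Writes a subgroup (or full-analysis) table as CSV and, optionally, as a
#' Markdown table on the percent-change scale.
#'
#' @param report Tibble from [subgroup_analysis()] or [run_full_analysis()].
#' @param path Output path; `.md` extension selects Markdown.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.md$", path)) {
    cols <- intersect(c("crop", "outcome", "variable", "bin", "k",
                        "pct_change", "pct_ci_low", "pct_ci_high",
                        "significant"), names(report))
    tab <- report[, cols]
    num <- vapply(tab, is.numeric, logical(1)) &
      !vapply(tab, is.integer, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.2f", x))
    lines <- c(
      "No multiplicity adjustment is applied across subgroup tests.",
      "",
      paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
    writeLines(lines, path)
  } else {
    readr::write_csv(tibble::as_tibble(report), path, progress = FALSE)
  }
  invisible(path)
}
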
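#' Random-forest permutation importance of moderators
#'
#' Fits a regression random forest of per-comparison log response ratios on
#' the moderator variables and reports each moderator's permutation
#' importance as the percent increase in out-of-bag mean squared error
#' (%IncMSE): the raw OOB MSE increase after permuting the moderator,
#' averaged over trees, expressed as a percentage of the baseline OOB MSE.
#' A larger value marks a moderator whose information the forest relies on
#' more. Categorical moderators enter as integer-coded levels by default
#' (`encode = "integer"`) or as one-hot dummies (`encode = "onehot"`).
#'
#' Rows with a missing value in any retained moderator are dropped
#' (complete-case analysis); a moderator missing in more than half of the
#' rows is excluded beforehand with a warning. Results are reproducible
#' bit-wise for a fixed `seed` and row order.
#'
#' @param effects Output of [effect_sizes()] (needs `rr` plus moderator
#'   columns).
#' @param outcome Optional filter, `"yield"` or `"NUE"`.
#' @param moderators Character vector of moderator columns; defaults to
#'   all fourteen standard moderators present in the data (crop is only
#'   used when more than one crop is present).
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried at each split; default `ceiling(p / 3)`.
#' @param seed Integer seed for the forest.
#' @param encode `"integer"` or `"onehot"` coding of categorical
#'   moderators.
#' @return An `rf_importance` object: tibble of `(moderator, pct_inc_mse,
#'   rank)` sorted by decreasing importance, with the fitted parameters,
#'   dropped moderators and sample size as attributes.
#' @examples
#' eff <- effect_sizes(make_fixture("importance")$database)
#' head(tidy(rf_importance(eff, outcome = "yield", seed = 1)))
#' @export
rf_importance <- function(effects, outcome = NULL, moderators = NULL,
                          n_trees = 500, mtry = NULL, seed = 1,
                          encode = c("integer", "onehot")) {
  encode <- match.arg(encode)
  dat <- tibble::as_tibble(effects)
  if (!is.null(outcome)) dat <- dat[dat$outcome %in% outcome, ]
  if (is.null(moderators)) {
    moderators <- intersect(names(moderator_schemes()), names(dat))
    if (length(unique(dat$crop)) < 2) {
      moderators <- setdiff(moderators, "crop")
    }
  }
  missing_frac <- vapply(dat[moderators],
                         function(x) mean(is.na(x)), numeric(1))
  dropped <- moderators[missing_frac > 0.5]
  if (length(dropped) > 0) {
    warning("excluding moderators missing in > 50% of rows: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  moderators <- setdiff(moderators, dropped)

  x <- dat[moderators]
  for (m in moderators) {
    if (!is.numeric(x[[m]])) {
      sch <- moderator_schemes()[[m]]
      lev <- if (!is.null(sch) && sch$type == "categorical") sch$levels else
        sort(unique(stats::na.omit(x[[m]])))
      x[[m]] <- factor(x[[m]], levels = lev)
    }
  }
  keep <- stats::complete.cases(x) & is.finite(dat$rr)
  x <- x[keep, ]
  y <- dat$rr[keep]
  if (length(y) < 30) {
    stop("need at least 30 complete-case observations; have ", length(y),
         call. = FALSE)
  }
  if (encode == "onehot") {
    x <- as.data.frame(stats::model.matrix(~ . - 1, data = x))
  } else {
    x[] <- lapply(x, function(col) if (is.factor(col)) as.integer(col)
                  else col)
  }
  p <- ncol(x)
  mtry <- mtry %||% ceiling(p / 3)

  fit <- withr::with_seed(seed, {
    randomForest::randomForest(x = as.data.frame(x), y = y,
                               ntree = n_trees, mtry = mtry,
                               importance = TRUE)
  })
  # raw OOB MSE increase, as a percentage of the baseline OOB MSE
  raw_inc <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  baseline <- fit$mse[length(fit$mse)]
  # a (near-)constant response has no MSE to increase: importance is zero
  pct <- if (baseline > .Machine$double.eps) 100 * raw_inc / baseline
         else raw_inc * 0
  entries <- tibble::tibble(
    moderator = names(raw_inc),
    pct_inc_mse = pct
  )
  entries <- dplyr::arrange(entries, dplyr::desc(.data$pct_inc_mse))
  entries$rank <- seq_len(nrow(entries))
  structure(entries,
            class = c("rf_importance", class(entries)),
            rf_params = list(n_trees = n_trees, mtry = mtry, seed = seed,
                             encode = encode,
                             importance_scale =
                               "raw OOB MSE increase / baseline OOB MSE x 100"),
            dropped = dropped, n_obs = length(y),
            outcome = outcome %||% "all")
}

#' @export
print.rf_importance <- function(x, ...) {
  p <- attr(x, "rf_params")
  cat("Random-forest moderator importance (", attr(x, "outcome"),
      "; n = ", attr(x, "n_obs"), ", trees = ", p$n_trees,
      ", mtry = ", p$mtry, ", seed = ", p$seed, ")\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rf_importance <- function(x, ...) tibble::as_tibble(x)

#' Fit a dose-response curve of effect size against a moderator
#'
#' Ordinary least squares fit of per-comparison log response ratios against
#' one continuous moderator, as a straight line (`y = a + b x`), a
#' quadratic (`y = a + b x + c x^2`), or whichever of the two has the
#' smaller AIC (`form = "auto"`). Reports the coefficient of determination
#' and the model F-test p-value; curves are conventionally called
#' significant at p < 0.01. The fitted optimum (vertex of a concave
#' quadratic) and the smallest upward zero crossing within the observed
#' moderator range are extracted with [extract_optimum()] and
#' [extract_zero_crossing()].
#'
#' @param data Tibble with the effect sizes (e.g. from [effect_sizes()]).
#' @param x,y Column names (strings) of the moderator and the response;
#'   `y` defaults to `"rr"`.
#' @param form `"auto"` (default), `"linear"` or `"quadratic"`.
#' @param crop,outcome Optional filters applied first.
#' @return A `response_curve` object with the fitted `stats::lm` model,
#'   coefficients, `r_squared`, `p_value`, `optimum_x`, `zero_crossing_x`,
#'   `n_obs` and the observed `x_range`.
#' @examples
#' d <- tibble::tibble(sr = seq(0, 90, 2),
#'                     rr = 0.056 - 1e-4 * (sr - 44)^2)
#' fit_response_curve(d, "sr", form = "quadratic")
#' @export
fit_response_curve <- function(data, x, y = "rr",
                               form = c("auto", "linear", "quadratic"),
                               crop = NULL, outcome = NULL) {
  form <- match.arg(form)
  dat <- tibble::as_tibble(data)
  if (!is.null(crop)) dat <- dat[dat$crop %in% crop, ]
  if (!is.null(outcome)) dat <- dat[dat$outcome %in% outcome, ]
  d <- tibble::tibble(x = as.numeric(dat[[x]]), y = as.numeric(dat[[y]]))
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10) {
    stop("need at least 10 paired observations; have ", nrow(d),
         call. = FALSE)
  }
  fits <- list(linear = stats::lm(y ~ x, data = d),
               quadratic = stats::lm(y ~ x + I(x^2), data = d))
  if (form == "auto") {
    # parsimony margin: the extra curvature term must earn its keep
    # (AIC differences below 2 are indistinguishable)
    if (suppressWarnings(summary(fits$linear))$r.squared >= 1 - 1e-12) {
      # both fits are numerically perfect; AIC on round-off residuals is
      # meaningless, so take the simpler model
      form <- "linear"
    } else {
      aic <- vapply(fits, stats::AIC, numeric(1))
      form <- if (aic["quadratic"] < aic["linear"] - 2) "quadratic"
              else "linear"
    }
  }
  fit <- fits[[form]]
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit note
  fstat <- sm$fstatistic
  p_value <- unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE))
  out <- structure(list(
    model = fit, model_form = form,
    coefficients = unname(stats::coef(fit)),
    r_squared = sm$r.squared, p_value = p_value,
    significant = p_value < 0.01,
    n_obs = nrow(d), x_range = range(d$x),
    x_name = x, y_name = y
  ), class = "response_curve")
  # quiet during construction; call the extractors directly for diagnostics
  out$optimum_x <- suppressMessages(extract_optimum(out))
  out$zero_crossing_x <- suppressWarnings(extract_zero_crossing(out))
  out
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve> ", x$y_name, " ~ ", x$model_form, "(", x$x_name,
      "), n = ", x$n_obs, "\n", sep = "")
  cat(sprintf("  R^2 = %.3f, p = %.3g%s\n", x$r_squared, x$p_value,
              if (x$significant) " (significant at 0.01)" else ""))
  if (!is.na(x$optimum_x)) cat(sprintf("  optimum at %s = %.2f\n",
                                       x$x_name, x$optimum_x))
  if (!is.na(x$zero_crossing_x)) {
    cat(sprintf("  upward zero crossing at %s = %.2f\n",
                x$x_name, x$zero_crossing_x))
  }
  invisible(x)
}

#' @export
tidy.response_curve <- function(x, ...) {
  cf <- stats::coef(x$model)
  tibble::tibble(term = names(cf), estimate = unname(cf),
                 std.error =
                   suppressWarnings(summary(x$model))$coefficients[, 2])
}

#' @export
glance.response_curve <- function(x, ...) {
  tibble::tibble(model_form = x$model_form, r.squared = x$r_squared,
                 p.value = x$p_value, significant = x$significant,
                 optimum_x = x$optimum_x,
                 zero_crossing_x = x$zero_crossing_x, n_obs = x$n_obs,
                 AIC = stats::AIC(x$model))
}

#' Evaluate a fitted response curve
#'
#' @param curve A `response_curve`.
#' @param x Moderator values.
#' @return Predicted effect sizes.
#' @export
predict_curve <- function(curve, x) {
  cf <- curve$coefficients
  if (curve$model_form == "linear") cf[1] + cf[2] * x
  else cf[1] + cf[2] * x + cf[3] * x^2
}

#' Optimum of a fitted dose-response curve
#'
#' The moderator value maximising the fitted effect: the vertex `-b/(2c)`
#' of a concave quadratic (`c < 0`). Linear or convex fits have no interior
#' optimum and return `NA`. A vertex outside `x_range` is reported as `NA`
#' with a boundary message, since the fit carries no information there.
#'
#' @param curve A `response_curve`.
#' @param x_range Interval in which the optimum is admissible; defaults to
#'   the observed moderator range.
#' @return The optimum, or `NA`.
#' @export
extract_optimum <- function(curve, x_range = NULL) {
  x_range <- x_range %||% curve$x_range
  if (curve$model_form != "quadratic") return(NA_real_)
  cf <- curve$coefficients
  if (!(cf[3] < 0)) return(NA_real_)
  vertex <- -cf[2] / (2 * cf[3])
  if (vertex < x_range[1] || vertex > x_range[2]) {
    message("fitted optimum ", format(vertex), " lies at/beyond the ",
            "boundary of the admissible range; not reported")
    return(NA_real_)
  }
  vertex
}

#' Upward zero crossing of a fitted dose-response curve
#'
#' The smallest moderator value in `x_range` at which the fitted curve
#' crosses from non-positive to positive — e.g. the minimum total N rate
#' above which manure substitution has a positive effect. Returns `NA`
#' when the curve does not change sign upward within the range; warns when
#' several upward crossings exist (only the smallest is returned).
#'
#' @inheritParams extract_optimum
#' @return The smallest upward zero crossing, or `NA`.
#' @export
extract_zero_crossing <- function(curve, x_range = NULL) {
  x_range <- x_range %||% curve$x_range
  cf <- curve$coefficients
  roots <- if (curve$model_form == "linear") {
    if (cf[2] == 0) numeric(0) else -cf[1] / cf[2]
  } else {
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (disc < 0 || cf[3] == 0) numeric(0)
    else (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
  }
  roots <- sort(roots[roots >= x_range[1] & roots <= x_range[2]])
  if (length(roots) == 0) return(NA_real_)
  if (length(roots) > 1) {
    warning("fitted curve changes sign more than once in range; ",
            "returning the smallest upward crossing", call. = FALSE)
  }
  eps <- 1e-8 * max(1, diff(x_range))
  upward <- roots[vapply(roots, function(r) {
    predict_curve(curve, min(r + eps, x_range[2])) >
      predict_curve(curve, max(r - eps, x_range[1]))
  }, logical(1))]
  if (length(upward) == 0) return(NA_real_)
  upward[1]
}
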
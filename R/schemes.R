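#' Grouping schemes for moderator variables
#'
#' A grouping scheme maps a moderator (management, climate or soil variable)
#' onto the ordered set of bins used for subgroup analysis. Numeric schemes
#' are defined by interval breaks with the lower-open/upper-closed convention
#' `(a, b]`, so a value sitting exactly on a boundary belongs to the
#' lower-labelled bin (e.g. an N rate of exactly 120 kg/ha falls in
#' `"<=120"`). Categorical schemes are a fixed set of level labels.
#'
#' @param variable Name of the database column the scheme applies to.
#' @param breaks For a numeric scheme, an increasing vector of interior
#'   break points (the outer bounds are -Inf/Inf).
#' @param levels For a categorical scheme, the admissible level labels.
#' @param labels Optional bin labels; defaults to `"<=b1"`, `"b1-b2"`, ...,
#'   `">bk"` for numeric schemes and to `levels` for categorical ones.
#'
#' @return An object of class `grouping_scheme`.
#' @examples
#' sch <- grouping_scheme("n_rate_total", breaks = c(120, 240, 360))
#' assign_bin(c(120, 120.5, 400), sch)
#' @export
grouping_scheme <- function(variable, breaks = NULL, levels = NULL,
                            labels = NULL) {
  if (is.null(breaks) == is.null(levels)) {
    stop("supply exactly one of `breaks` (numeric scheme) or `levels` ",
         "(categorical scheme)", call. = FALSE)
  }
  if (!is.null(breaks)) {
    breaks <- as.numeric(breaks)
    if (is.unsorted(breaks, strictly = TRUE)) {
      stop("`breaks` must be strictly increasing", call. = FALSE)
    }
    if (is.null(labels)) {
      k <- length(breaks)
      labels <- c(
        paste0("<=", format(breaks[1], trim = TRUE)),
        if (k > 1) paste0(format(breaks[-k], trim = TRUE), "-",
                          format(breaks[-1], trim = TRUE)),
        paste0(">", format(breaks[k], trim = TRUE))
      )
    }
    stopifnot(length(labels) == length(breaks) + 1)
    out <- list(variable = variable, type = "numeric",
                breaks = breaks, labels = labels)
  } else {
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicate levels", call. = FALSE)
    if (is.null(labels)) labels <- levels
    out <- list(variable = variable, type = "categorical",
                levels = levels, labels = labels)
  }
  structure(out, class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat("<grouping_scheme> ", x$variable, " (", x$type, "): ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign values to subgroup bins
#'
#' Maps each value to the unique bin label of a [grouping_scheme()].
#' Boundary values follow the `(a, b]` convention: `assign_bin(120, nr)`
#' is `"<=120"` while `assign_bin(120.5, nr)` is `"120-240"`. Missing
#' values map to `"unknown"`, which marks the record for exclusion from
#' that subgroup analysis only.
#'
#' @param value Numeric (or character, for categorical schemes) vector.
#' @param scheme A [grouping_scheme()].
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(value, scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  if (scheme$type == "numeric") {
    # left.open gives the (a, b] convention: a value on a break stays below it
    idx <- findInterval(as.numeric(value), scheme$breaks, left.open = TRUE) + 1L
    out <- scheme$labels[idx]
  } else {
    out <- scheme$labels[match(as.character(value), scheme$levels)]
  }
  out[is.na(value) | is.na(out)] <- "unknown"
  out
}

#' Moderator grouping schemes used throughout the package
#'
#' The standard set of fourteen grouping schemes: crop type, N application
#' rate (kg N/ha), manure substitution rate (%), climate type, average
#' annual rainfall (mm), mean annual temperature (deg C), annual sunshine
#' duration (h), frost-free period (days), soil organic matter (g/kg),
#' soil total N (g/kg), alkali-hydrolysable N (mg/kg), available P (mg/kg),
#' available K (mg/kg) and soil pH. Soil-nutrient bins follow the Chinese
#' second soil survey classification; pH bins are the conventional strongly
#' acidic / acidic / neutral / alkaline split.
#'
#' @return Named list of [grouping_scheme()] objects, keyed by database
#'   column name.
#' @examples
#' names(moderator_schemes())
#' assign_bin(7.6, moderator_schemes()$ph)
#' @export
moderator_schemes <- function() {
  list(
    crop = grouping_scheme("crop", levels = c("wheat", "maize", "rice")),
    n_rate_total = grouping_scheme("n_rate_total",
                                   breaks = c(120, 240, 360)),
    substitution_rate = grouping_scheme("substitution_rate",
                                        breaks = c(30, 60)),
    climate_type = grouping_scheme("climate_type",
                                   levels = c("NTM", "NTC", "STM")),
    aar_mm = grouping_scheme("aar_mm", breaks = c(600, 1200)),
    mat_c = grouping_scheme("mat_c", breaks = c(12, 16)),
    asd_h = grouping_scheme("asd_h", breaks = c(2200, 2600)),
    ffp_days = grouping_scheme("ffp_days", breaks = c(175, 250)),
    som_gkg = grouping_scheme("som_gkg", breaks = c(20, 30)),
    tn_gkg = grouping_scheme("tn_gkg", breaks = c(1, 1.5)),
    an_mgkg = grouping_scheme("an_mgkg", breaks = c(60, 120)),
    ap_mgkg = grouping_scheme("ap_mgkg", breaks = c(10, 20)),
    ak_mgkg = grouping_scheme("ak_mgkg", breaks = c(175, 250)),
    ph = grouping_scheme("ph", breaks = c(5.5, 6.5, 7.5))
  )
}
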
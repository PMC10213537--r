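#' Column dictionary of the comparison database
#'
#' One row of the database is a single paired comparison between a control
#' receiving only synthetic N fertilizer (NPK, with adequate P and K) and a
#' treatment in which manure replaces part or all of the synthetic N at
#' equal total N input (NPKM). Columns:
#'
#' * `study_id` — identifier of the source study (several comparisons may
#'   share one study).
#' * `crop` — `"wheat"`, `"maize"` or `"rice"`.
#' * `outcome` — `"yield"` (t/ha) or `"NUE"` (%, apparent N recovery).
#' * `mean_npk`, `sd_npk`, `n_npk` — control arm mean, SD and replicate
#'   count; `mean_npkm`, `sd_npkm`, `n_npkm` — treatment arm.
#' * `n_rate_total` — total N input (kg N/ha); `substitution_rate` — share
#'   of total N supplied as manure N (%).
#' * `climate_type` (`NTM`/`NTC`/`STM`), `aar_mm`, `mat_c`, `asd_h`,
#'   `ffp_days` — climate moderators.
#' * `som_gkg`, `tn_gkg`, `an_mgkg`, `ap_mgkg`, `ak_mgkg`, `ph` — topsoil
#'   (0-20 cm) properties.
#'
#' @return Tibble with columns `column`, `type`, `required`, `description`.
#' @export
db_schema <- function() {
  tibble::tribble(
    ~column,             ~type,      ~required, ~description,
    "study_id",          "character", TRUE,  "source study identifier",
    "crop",              "character", TRUE,  "wheat, maize or rice",
    "outcome",           "character", TRUE,  "yield or NUE",
    "mean_npk",          "numeric",   TRUE,  "control mean (t/ha or %)",
    "sd_npk",            "numeric",   FALSE, "control SD (may be missing)",
    "n_npk",             "integer",   TRUE,  "control replicates (>= 3)",
    "mean_npkm",         "numeric",   TRUE,  "treatment mean",
    "sd_npkm",           "numeric",   FALSE, "treatment SD (may be missing)",
    "n_npkm",            "integer",   TRUE,  "treatment replicates (>= 3)",
    "n_rate_total",      "numeric",   TRUE,  "total N input (kg N/ha)",
    "substitution_rate", "numeric",   TRUE,  "manure N share of total N (%)",
    "climate_type",      "character", FALSE, "NTM, NTC or STM",
    "aar_mm",            "numeric",   FALSE, "average annual rainfall (mm)",
    "mat_c",             "numeric",   FALSE, "mean annual temperature (C)",
    "asd_h",             "numeric",   FALSE, "annual sunshine duration (h)",
    "ffp_days",          "numeric",   FALSE, "frost-free period (days)",
    "som_gkg",           "numeric",   FALSE, "soil organic matter (g/kg)",
    "tn_gkg",            "numeric",   FALSE, "soil total N (g/kg)",
    "an_mgkg",           "numeric",   FALSE, "alkali-hydrolysable N (mg/kg)",
    "ap_mgkg",           "numeric",   FALSE, "available P (mg/kg)",
    "ak_mgkg",           "numeric",   FALSE, "available K (mg/kg)",
    "ph",                "numeric",   FALSE, "soil pH"
  )
}

crop_levels <- c("wheat", "maize", "rice")
outcome_levels <- c("yield", "NUE")
climate_levels <- c("NTM", "NTC", "STM")

#' Validate a comparison database
#'
#' Checks every row against the database invariants: at least three
#' replicates per arm, strictly positive arm means (the log ratio must be
#' defined), non-negative SDs where present, a substitution rate in
#' (0, 100] (a rate of 0 is the NPK control, not a valid NPKM treatment),
#' and recognised crop/outcome/climate codes. Rows failing any rule are
#' moved to a rejection table with a reason code, never silently dropped.
#'
#' @param db Data frame with the columns of [db_schema()].
#' @return A list with elements `records` (tibble of accepted rows),
#'   `rejected` (tibble of rejected rows plus a `reason` column) and
#'   `n_accepted`/`n_rejected`.
#' @examples
#' db <- make_fixture("tiny")$database
#' validate_comparisons(db)$n_accepted
#' @export
validate_comparisons <- function(db) {
  db <- tibble::as_tibble(db)
  schema <- db_schema()
  missing_cols <- setdiff(schema$column[schema$required], names(db))
  if (length(missing_cols) > 0) {
    stop("database is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(schema$column, names(db))) db[[col]] <- NA
  num <- function(x) suppressWarnings(as.numeric(x))

  reasons <- rep(NA_character_, nrow(db))
  note <- function(bad, why) {
    bad[is.na(bad)] <- TRUE   # NA in a required check is itself a failure
    ifelse(is.na(reasons) & bad, why, reasons)
  }
  reasons <- note(is.na(db$study_id) | !nzchar(as.character(db$study_id)),
                  "missing study_id")
  reasons <- note(!(db$crop %in% crop_levels), "unknown crop")
  reasons <- note(!(db$outcome %in% outcome_levels), "unknown outcome")
  reasons <- note(num(db$n_npk) < 3 | num(db$n_npkm) < 3, "replicates < 3")
  reasons <- note(!(num(db$mean_npk) > 0) | !(num(db$mean_npkm) > 0),
                  "non-positive mean")
  sd_bad <- (!is.na(db$sd_npk) & num(db$sd_npk) < 0) |
    (!is.na(db$sd_npkm) & num(db$sd_npkm) < 0)
  sd_bad[is.na(sd_bad)] <- FALSE
  reasons <- ifelse(is.na(reasons) & sd_bad, "negative SD", reasons)
  reasons <- note(!(num(db$substitution_rate) > 0 &
                      num(db$substitution_rate) <= 100),
                  "substitution rate outside (0, 100]")
  clim_bad <- !is.na(db$climate_type) & !(db$climate_type %in% climate_levels)
  reasons <- ifelse(is.na(reasons) & clim_bad, "unknown climate type", reasons)

  keep <- is.na(reasons)
  records <- db[keep, schema$column]
  for (col in schema$column[schema$type == "numeric"]) {
    records[[col]] <- num(records[[col]])
  }
  records$n_npk <- as.integer(records$n_npk)
  records$n_npkm <- as.integer(records$n_npkm)
  rejected <- dplyr::mutate(db[!keep, ], reason = reasons[!keep])
  list(records = records, rejected = rejected,
       n_accepted = sum(keep), n_rejected = sum(!keep))
}

#' Read a comparison database from CSV
#'
#' Reads a UTF-8 comma-separated file with the header of [db_schema()],
#' warns about unrecognised columns, validates every row with
#' [validate_comparisons()] and reports the accepted/rejected counts.
#' Rejected rows are attached as the `"rejected"` attribute of the result
#' and can be exported with [write_rejects()].
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the acceptance summary message.
#' @return Tibble of validated comparison records.
#' @export
read_database <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read database: no file at '", path,
                               "'", call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(raw), db_schema()$column)
  if (length(extra) > 0) {
    warning("ignoring unrecognised columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  res <- validate_comparisons(raw)
  if (!quiet) {
    message("read ", nrow(raw), " rows: ", res$n_accepted, " accepted, ",
            res$n_rejected, " rejected")
    if (res$n_rejected > 0) {
      tab <- table(res$rejected$reason)
      message(paste0("  ", names(tab), ": ", tab, collapse = "\n"))
    }
  }
  out <- res$records
  attr(out, "rejected") <- res$rejected
  out
}

#' Write a comparison database (or its rejects) to CSV
#'
#' `write_database()` writes records in the canonical column order so that
#' a read/write/read cycle round-trips exactly. `write_rejects()` writes
#' the rejection table produced by [read_database()] or
#' [validate_comparisons()], including reason codes.
#'
#' @param db Tibble of comparison records (or, for `write_rejects()`, the
#'   validated tibble carrying a `"rejected"` attribute, or a rejection
#'   tibble itself).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  cols <- intersect(db_schema()$column, names(db))
  readr::write_csv(db[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
write_rejects <- function(db, path) {
  rej <- if (!is.null(attr(db, "rejected"))) attr(db, "rejected") else db
  readr::write_csv(tibble::as_tibble(rej), path, progress = FALSE)
  invisible(path)
}

#' Nitrogen use efficiency from aboveground N uptake
#'
#' Apparent N recovery efficiency: the fertilizer-attributable share of
#' aboveground N uptake relative to the total N input,
#' `NUE = (N_t - N_0) / F_t x 100%`, where `N_t` and `N_0` are total
#' aboveground N uptake (kg N/ha) with and without N input and `F_t` is the
#' total N input (kg N/ha). Used to derive NUE for studies that report N
#' uptake but not NUE itself. Negative values (uptake lower under
#' fertilization) are retained and flagged with a warning rather than
#' rejected, since dropping them would bias pooled NUE upward.
#'
#' @param n_uptake_fert Aboveground N uptake with N input, kg N/ha.
#' @param n_uptake_zero Aboveground N uptake without N input, kg N/ha.
#' @param n_input_total Total N input, kg N/ha; must be positive.
#' @return Numeric vector of NUE values in percent.
#' @examples
#' compute_nue(120, 60, 200)  # 30
#' @export
compute_nue <- function(n_uptake_fert, n_uptake_zero, n_input_total) {
  if (any(!is.finite(n_input_total) | n_input_total <= 0)) {
    stop("invalid N input: `n_input_total` must be positive", call. = FALSE)
  }
  nue <- (n_uptake_fert - n_uptake_zero) / n_input_total * 100
  if (any(nue < 0, na.rm = TRUE)) {
    warning(sum(nue < 0, na.rm = TRUE),
            " negative NUE value(s): uptake lower with fertilization ",
            "than without; retained", call. = FALSE)
  }
  nue
}
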
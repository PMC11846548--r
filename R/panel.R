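#' @title Region-by-year health-workforce panels
#' @description
#' A panel is a long-format table with one row per (region, year, stratum)
#' holding the resident population, land area and four resource counts
#' (registered nurses, practicing/assistant doctors, health technicians,
#' hospital beds). Panels are the common input of the equity and forecasting
#' stages.
#' @name panel
NULL

PANEL_COLUMNS <- c("region_id", "year", "stratum", "population", "area_km2",
                   "nurses", "doctors", "health_technicians", "beds")
PANEL_STRATA <- c("urban", "county", "whole")
COUNT_COLUMNS <- c("nurses", "doctors", "health_technicians", "beds")

new_panel <- function(df, provenance = "unspecified") {
  df <- as.data.frame(df)[, PANEL_COLUMNS]
  df <- df[order(df$region_id, df$stratum, df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("equicast_panel", "data.frame"))
}

#' Validate a panel table
#'
#' Checks every structural invariant a panel must satisfy: positive
#' population and area, non-negative integer counts, nurses being a subset
#' of health technicians, uniqueness of (region, year, stratum), and year
#' contiguity within each region/stratum (gaps are reported, never filled).
#'
#' @param df data frame with the panel columns.
#' @param strict logical; if `TRUE` (default) any violation is an error,
#'   otherwise violations are collected and returned.
#' @return Invisibly, a data frame of problems (zero rows when clean) with
#'   columns `row`, `column`, `reason`.
#' @export
validate_panel <- function(df, strict = TRUE) {
  problems <- list()
  note <- function(row, column, reason) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, column = column, reason = reason, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_stratum <- which(!df$stratum %in% PANEL_STRATA)
  for (i in bad_stratum) note(i, "stratum", paste0("unknown stratum '", df$stratum[i], "'"))
  for (col in c("population", "area_km2")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    for (i in bad) note(i, col, "must be a finite positive number")
  }
  for (col in COUNT_COLUMNS) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8)
    for (i in bad) note(i, col, "must be a non-negative integer")
  }
  sub <- which(is.finite(df$nurses) & is.finite(df$health_technicians) &
                 df$nurses > df$health_technicians)
  for (i in sub) note(i, "nurses", "nurses exceed health_technicians (nurses are a subset)")
  key <- paste(df$region_id, df$year, df$stratum, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) note(i, "region_id/year/stratum", "duplicate (region, year, stratum) key")
  # year contiguity: gaps are surfaced, not fatal even in strict mode
  gaps <- character(0)
  for (grp in split(df, paste(df$region_id, df$stratum, sep = "\r"))) {
    yrs <- sort(unique(grp$year))
    if (length(yrs) > 1 && any(diff(yrs) != 1)) {
      gaps <- c(gaps, sprintf("region '%s' stratum '%s' has year gaps (%s)",
                              grp$region_id[1], grp$stratum[1],
                              paste(yrs, collapse = ",")))
    }
  }
  if (length(gaps)) warning(paste(gaps, collapse = "; "), call. = FALSE)
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(0), column = character(0), reason = character(0))
  if (strict && nrow(problems)) {
    stop("panel validation failed:\n",
         paste(sprintf("  row %d [%s]: %s", problems$row, problems$column,
                       problems$reason), collapse = "\n"), call. = FALSE)
  }
  invisible(problems)
}

#' Read a region-by-year panel from delimited text
#'
#' Expects a header row and the columns `region_id, year, stratum,
#' population, area_km2, nurses, doctors, health_technicians, beds`
#' (UTF-8; comma-delimited by default, tab accepted). Column names that
#' differ from the canonical schema can be mapped via `col_map`, which
#' tolerates yearbook-export variants.
#'
#' @param path path to the delimited file.
#' @param delimiter field separator, `","` (default) or `"\t"`.
#' @param col_map optional named character vector mapping canonical names
#'   to the names used in the file, e.g. `c(area_km2 = "area")`.
#' @param strict logical; abort on any invariant violation (default) or
#'   keep offending rows and attach the problem report.
#' @param provenance free-text source tag stored on the panel.
#' @return An `equicast_panel` (a data frame) sorted by region, stratum, year.
#' @export
read_panel <- function(path, delimiter = ",", col_map = NULL, strict = TRUE,
                       provenance = path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "", fill = FALSE,
                          colClasses = NA, encoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("input lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("panel file has a header but no rows: ", path, call. = FALSE)
    return(new_panel(df, provenance))
  }
  # coerce numerics row-safely so a single bad cell is reported with its line
  numeric_cols <- c("year", "population", "area_km2", COUNT_COLUMNS)
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      msg <- sprintf("line %d: non-numeric value '%s' in column '%s'",
                     bad + 1L, as.character(df[[col]][bad]), col)
      if (strict) stop(paste(msg, collapse = "\n"), call. = FALSE)
      warning(paste(msg, collapse = "\n"), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$region_id <- as.character(df$region_id)
  df$stratum <- as.character(df$stratum)
  validate_panel(df, strict = strict)
  new_panel(df, provenance)
}

#' Write a panel back to delimited text
#'
#' Inverse of [read_panel()]: numeric fields round-trip exactly (written at
#' full precision with `format(..., digits = 17)` semantics of `write.csv`).
#'
#' @param panel an `equicast_panel`.
#' @param path output file path.
#' @param delimiter field separator.
#' @export
write_panel <- function(panel, path, delimiter = ",") {
  utils::write.table(as.data.frame(panel)[, PANEL_COLUMNS], path,
                     sep = delimiter, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive per-record allocation indicators
#'
#' For every panel row computes the field-standard indicators: nurses per
#' 1,000 population, nurses per square kilometre, nurses per doctor (the
#' "x" of the conventional "1:x" doctor-to-nurse ratio), nurses per bed,
#' and the nurse share of health technicians. Ratios with a zero
#' denominator are `NA`, never 0.
#'
#' @param panel an `equicast_panel` or compatible data frame.
#' @return Data frame with one row per input record: `region_id`, `year`,
#'   `stratum`, `nurses_per_1000`, `nurses_per_km2`, `nurses_per_doctor`,
#'   `nurses_per_bed`, `nurse_share`.
#' @export
derive_indicators <- function(panel) {
  df <- as.data.frame(panel)
  if (any(df$population <= 0) || any(df$area_km2 <= 0)) {
    stop("population and area must be strictly positive for indicator derivation",
         call. = FALSE)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    region_id = df$region_id,
    year = df$year,
    stratum = df$stratum,
    nurses_per_1000 = 1000 * df$nurses / df$population,
    nurses_per_km2 = df$nurses / df$area_km2,
    nurses_per_doctor = ratio(df$nurses, df$doctors),
    nurses_per_bed = ratio(df$nurses, df$beds),
    nurse_share = ratio(df$nurses, df$health_technicians),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Average annual growth rate
#'
#' The compound (geometric) annual growth rate `(a_n/a_0)^(1/n) - 1` over
#' `n_years` years, returned as a fraction per year; rendering as a
#' percentage is left to the presentation layer.
#'
#' @param a0 count in the initial year, strictly positive.
#' @param an count in the final year, non-negative.
#' @param n_years number of elapsed years (integer >= 1).
#' @return Growth rate as a fraction per year (vectorised).
#' @examples
#' average_annual_growth_rate(100, 200, 10)  # ~0.0718, i.e. 7.18%/yr
#' @export
average_annual_growth_rate <- function(a0, an, n_years) {
  if (any(a0 <= 0)) stop("initial count a0 must be > 0", call. = FALSE)
  if (any(an < 0)) stop("final count an must be >= 0", call. = FALSE)
  if (any(n_years < 1 | n_years != round(n_years))) {
    stop("n_years must be an integer >= 1", call. = FALSE)
  }
  (an / a0)^(1 / n_years) - 1
}

#' Render a "per one" ratio in the conventional "1:x" form
#'
#' @param x nurses-per-denominator ratio (e.g. 1.27 nurses per doctor).
#' @param digits decimal places (default 2, matching yearbook style).
#' @return Character vector like `"1:1.27"`; `NA` stays `NA`.
#' @export
format_one_to <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_, sprintf("1:%.*f", digits, x))
}

#' @export
print.equicast_panel <- function(x, ...) {
  cat(sprintf("<equicast_panel> %d records | %d regions | years %s-%s | source: %s\n",
              nrow(x), length(unique(x$region_id)),
              min(x$year), max(x$year), attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
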
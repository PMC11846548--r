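#' @title Full-analysis pipeline and report bundle
#' @description
#' Orchestrates the whole analysis — indicator derivation, per-year equity
#' statistics on both bases, and dual-model (grey + ARIMA) five-year
#' forecasting with grade-based gating of the grey extrapolation — and
#' collects everything into a report bundle with a run manifest.
#' @name cli_report
NULL

#' Pipeline run configuration
#'
#' @param panel an `equicast_panel`, or `NULL` to generate one from
#'   `synthetic`.
#' @param synthetic a [synthetic_config()] used when `panel` is `NULL`.
#' @param bases equity bases to compute (default both).
#' @param theil_groups named vector region_id -> group label, or `NULL`
#'   for a single group (between-group component is then 0).
#' @param horizon forecast horizon in years (default 5).
#' @param resource panel column to analyse and forecast (default
#'   `"nurses"`).
#' @param stratum stratum to analyse (default `"whole"`).
#' @param grey_lambda GM(1,1) background-value coefficient.
#' @param arima_max_p,arima_max_q ARIMA grid maxima.
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV and the manifest as JSON.
#' @return List of class `run_config`.
#' @export
run_config <- function(panel = NULL, synthetic = synthetic_config(),
                       bases = c("population", "area"), theil_groups = NULL,
                       horizon = 5, resource = "nurses", stratum = "whole",
                       grey_lambda = 0.5, arima_max_p = 3, arima_max_q = 3,
                       out_dir = NULL) {
  stopifnot(horizon >= 1)
  bases <- match.arg(bases, c("population", "area"), several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full equity-and-forecasting pipeline
#'
#' Stages: (1) load or generate the panel; (2) derive allocation
#' indicators; (3) per-year Gini (each basis, with fairness labels) and
#' Theil decomposition — skipped with an explanation when the panel has a
#' single region; (4) aggregate the province-total resource series and
#' forecast it `horizon` years ahead with both GM(1,1) (graded, and
#' flagged "unreliable" whenever the grade exceeds 2) and ARIMA
#' (automatic d and (p, q) selection). A grade-4 grey model is a warning,
#' never a failure — the forecast is still reported, gated.
#'
#' @param config a [run_config()].
#' @return List of class `report_bundle`: `panel`, `indicators`, `gini`
#'   (long table over bases), `theil`, `equity_skipped` (reason or
#'   `NULL`), `totals` (year, total), `grey` (list: fit, diagnostics,
#'   forecast, gate_status), `arima` (list: d, order, forecast), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  panel <- if (is.null(config$panel)) generate_panel(config$synthetic) else config$panel
  df <- as.data.frame(panel)
  df <- df[df$stratum == config$stratum, , drop = FALSE]
  if (nrow(df) == 0) stop("no records in stratum '", config$stratum, "'", call. = FALSE)
  message(sprintf("[panel] %d records, %d regions, years %d-%d",
                  nrow(df), length(unique(df$region_id)), min(df$year), max(df$year)))

  indicators <- derive_indicators(df)
  message(sprintf("[indicators] %d rows derived", nrow(indicators)))

  n_regions <- length(unique(df$region_id))
  equity_skipped <- NULL
  gini_tab <- NULL
  theil_tab <- NULL
  if (n_regions < 2) {
    equity_skipped <- "equity statistics need >= 2 regions; stage skipped"
    message("[equity] ", equity_skipped)
  } else {
    gini_tab <- do.call(rbind, lapply(config$bases, function(b)
      panel_gini(panel, basis = b, resource = config$resource,
                 stratum = config$stratum)))
    rownames(gini_tab) <- NULL
    theil_tab <- panel_theil(panel, groups = config$theil_groups,
                             resource = config$resource,
                             stratum = config$stratum)
    message(sprintf("[equity] Gini over %d year(s) x %d basis/bases; Theil over %d year(s)",
                    length(unique(gini_tab$year)), length(config$bases),
                    nrow(theil_tab)))
  }

  totals <- stats::aggregate(df[[config$resource]],
                             by = list(year = df$year), FUN = sum)
  names(totals)[2] <- "total"
  totals <- totals[order(totals$year), ]
  series <- totals$total
  first_fc_year <- max(totals$year) + 1L

  grey_fit <- fit_gm11(series, lambda = config$grey_lambda)
  grey_diag <- gm11_diagnose(grey_fit)
  grey_fc <- gm11_forecast(grey_fit, config$horizon, start_year = first_fc_year)
  gate_status <- if (grey_diag$extrapolation_allowed) "qualified" else "unqualified"
  grey_fc$reliability <- if (grey_diag$extrapolation_allowed) "ok" else "unreliable"
  if (!grey_diag$extrapolation_allowed) {
    message(sprintf("[grey] grade %d (%s): extrapolation unreliable, forecast reported with caveat",
                    grey_diag$grade, grey_diag$grade_label))
  } else {
    message(sprintf("[grey] grade %d (%s): extrapolation allowed",
                    grey_diag$grade, grey_diag$grade_label))
  }

  d <- select_difference_order(series)
  ord <- auto_select_order(series, d, max_p = config$arima_max_p,
                           max_q = config$arima_max_q)
  arima_fc <- fit_and_forecast(series, ord, horizon = config$horizon,
                               start_year = first_fc_year)
  message(sprintf("[arima] ARIMA(%d,%d,%d) forecast for %d year(s)",
                  ord$p, ord$d, ord$q, config$horizon))

  manifest <- list(
    package = "equicast",
    version = as.character(utils::packageVersion("equicast")),
    r_version = as.character(getRversion()),
    resource = config$resource, stratum = config$stratum,
    bases = config$bases, horizon = config$horizon,
    n_regions = n_regions, years = range(df$year),
    seed = if (is.null(config$panel)) config$synthetic$seed else NA,
    provenance = attr(panel, "provenance"))

  bundle <- structure(list(
    panel = panel, indicators = indicators, gini = gini_tab,
    theil = theil_tab, equity_skipped = equity_skipped, totals = totals,
    grey = list(fit = grey_fit, diagnostics = grey_diag,
                forecast = grey_fc, gate_status = gate_status),
    arima = list(d = d, order = ord, forecast = arima_fc$forecast,
                 fit = arima_fc),
    manifest = manifest), class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits CSV tables (indicators, Gini, Theil, totals, both forecast
#' tables) and the manifest as JSON into `out_dir`. Forecast points are
#' written at full precision, with an extra presentation column rounded
#' to hundreds (rounding never feeds back into any computation).
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) utils::write.csv(as.data.frame(x),
                                      file.path(out_dir, name),
                                      row.names = FALSE)
  }
  wr(bundle$indicators, "indicators.csv")
  wr(bundle$gini, "gini.csv")
  wr(bundle$theil, "theil.csv")
  wr(bundle$totals, "totals.csv")
  grey_fc <- as.data.frame(bundle$grey$forecast)
  grey_fc$point_rounded_hundreds <- round(grey_fc$point, -2)
  wr(grey_fc, "forecast_grey.csv")
  ar_fc <- as.data.frame(bundle$arima$forecast)
  ar_fc$point_rounded_hundreds <- round(ar_fc$point, -2)
  wr(ar_fc, "forecast_arima.csv")
  jsonlite::write_json(
    c(bundle$manifest,
      list(grey = list(a = bundle$grey$fit$a, u = bundle$grey$fit$u,
                       C = bundle$grey$diagnostics$C,
                       P = bundle$grey$diagnostics$P,
                       grade = bundle$grey$diagnostics$grade,
                       gate_status = bundle$grey$gate_status),
           arima = list(order = as.list(bundle$arima$fit$order),
                        aicc = bundle$arima$fit$aicc))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarise a yearly equity-statistic series
#'
#' Min, max, first, last and direction of change for each statistic
#' column of a per-year table (e.g. [panel_gini()] or [panel_theil()]
#' output).
#'
#' @param tab data frame with a `year` column and numeric statistic
#'   columns.
#' @param tol absolute tolerance below which the series counts as flat.
#' @return Data frame: `statistic`, `min`, `max`, `first`, `last`,
#'   `direction` (`"increasing"`, `"decreasing"`, `"flat"`, or
#'   `"non-monotone"`).
#' @export
summarize_equity_trend <- function(tab, tol = 1e-12) {
  stopifnot("year" %in% names(tab), nrow(tab) >= 2)
  tab <- tab[order(tab$year), ]
  stat_cols <- names(tab)[vapply(tab, is.numeric, TRUE) & names(tab) != "year"]
  out <- lapply(stat_cols, function(cn) {
    v <- tab[[cn]]
    dv <- diff(v)
    dir <- if (all(abs(dv) <= tol)) "flat"
      else if (all(dv >= -tol)) "increasing"
      else if (all(dv <= tol)) "decreasing"
      else if (v[length(v)] > v[1] + tol) "increasing"
      else if (v[length(v)] < v[1] - tol) "decreasing"
      else "non-monotone"
    data.frame(statistic = cn, min = min(v), max = max(v),
               first = v[1], last = v[length(v)], direction = dir)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<report_bundle> %s | %d regions, years %d-%d, horizon %d\n",
              m$provenance, m$n_regions, m$years[1], m$years[2], m$horizon))
  if (!is.null(x$gini)) {
    last <- x$gini[x$gini$year == max(x$gini$year), ]
    for (i in seq_len(nrow(last))) {
      cat(sprintf("  Gini (%s, %d): %.3f [%s]\n", last$basis[i], last$year[i],
                  last$gini[i], last$fairness[i]))
    }
  }
  if (!is.null(x$theil)) {
    cat(sprintf("  Theil total range: %.3f - %.3f\n",
                min(x$theil$total), max(x$theil$total)))
  }
  cat(sprintf("  GM(1,1): grade %d (%s), gate %s; %d-step forecast ends at %.0f\n",
              x$grey$diagnostics$grade, x$grey$diagnostics$grade_label,
              x$grey$gate_status, nrow(x$grey$forecast),
              x$grey$forecast$point[nrow(x$grey$forecast)]))
  cat(sprintf("  ARIMA(%d,%d,%d): %d-step forecast ends at %.0f\n",
              x$arima$fit$order["p"], x$arima$fit$order["d"],
              x$arima$fit$order["q"], nrow(x$arima$forecast),
              x$arima$forecast$point[nrow(x$arima$forecast)]))
  invisible(x)
}
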
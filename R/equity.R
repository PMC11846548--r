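#' @title Equity statistics for regional resource allocation
#' @description
#' Lorenz curves, Gini coefficients (with the fairness banding standard in
#' the health-resource-allocation literature) and the additively
#' decomposable Theil index. The basis of a Lorenz/Gini analysis is either
#' resident population or land area: regions are ranked ascending by
#' resource density (resource per unit of basis) and cumulative shares are
#' accumulated in that order.
#' @name equity
NULL

#' Build a Lorenz curve
#'
#' Regions are sorted ascending by density `resource / basis_weight` (ties
#' broken by region label for reproducibility); cumulative basis shares
#' (x) and cumulative resource shares (y) are computed and `(0,0)`
#' prepended. The final point is `(1,1)` by construction.
#'
#' @param basis_weight positive weights per region (population or area).
#' @param resource non-negative resource counts per region (e.g. nurses).
#' @param basis label for the weighting basis, `"population"` or `"area"`.
#' @param labels optional region labels (default `R1..Rn`).
#' @return An object of class `lorenz_curve`: list with `points` (data
#'   frame `cum_basis_share`, `cum_resource_share`), `basis`,
#'   `region_order`, and the per-region shares `W` (basis), `Y` (resource)
#'   and cumulative resource shares `V` in ranked order.
#' @export
build_lorenz <- function(basis_weight, resource,
                         basis = c("population", "area"), labels = NULL) {
  basis <- match.arg(basis)
  n <- length(basis_weight)
  if (length(resource) != n) stop("basis_weight and resource lengths differ", call. = FALSE)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(!is.finite(basis_weight) | basis_weight <= 0)) {
    stop("all basis weights must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(resource) | resource < 0)) {
    stop("resource counts must be finite and >= 0", call. = FALSE)
  }
  if (sum(resource) <= 0) stop("total resource is zero: Lorenz curve undefined", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("R%d", seq_len(n))
  density <- resource / basis_weight
  ord <- order(density, labels)           # stable, label-tie-broken ranking
  W <- basis_weight[ord] / sum(basis_weight)
  Y <- resource[ord] / sum(resource)
  V <- cumsum(Y)
  points <- data.frame(cum_basis_share = c(0, cumsum(W)),
                       cum_resource_share = c(0, V))
  structure(list(points = points, basis = basis,
                 region_order = labels[ord], W = W, Y = Y, V = V),
            class = "lorenz_curve")
}

#' Gini coefficient by the ranked-share summation formula
#'
#' Computes `G = 1 - sum_i W_i (2 V_i - Y_i)` where, with regions ranked
#' ascending by density, `W_i` is region i's basis share, `Y_i` its
#' resource share and `V_i` the cumulative resource share up to and
#' including i.
#'
#' @param curve a [build_lorenz()] result.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_paper <- function(curve) {
  stopifnot(inherits(curve, "lorenz_curve"))
  1 - sum(curve$W * (2 * curve$V - curve$Y))
}

#' Gini coefficient by trapezoid integration of the Lorenz polyline
#'
#' The geometric definition `G = A / (A + B)` with `A` the area between
#' the diagonal and the curve and `B` the area under the curve; since
#' `A + B = 1/2`, `G = 1 - 2B` with `B` obtained by the trapezoid rule.
#' Serves as the independent cross-check of [gini_paper()]; the two agree
#' to machine precision because `2 V_i - Y_i = V_i + V_{i-1}`.
#'
#' @inheritParams gini_paper
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "lorenz_curve"))
  p <- curve$points
  x <- p$cum_basis_share
  y <- p$cum_resource_share
  B <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  1 - 2 * B
}

#' Fairness band of a Gini coefficient
#'
#' Bands conventional in health-resource equity work: `[0, 0.2)` absolute
#' fairness, `[0.2, 0.3)` moderate fairness, `[0.3, 0.4)` relative
#' fairness, `[0.4, 0.6]` warning of inequality, `(0.6, 1)` high
#' inequality. Printed band edges in the literature overlap ("<0.2",
#' "0.2-0.3", ">0.4", ">0.6"); the half-open convention here covers
#' `[0, 1)` exactly once.
#'
#' @param g Gini coefficient(s) in `[0, 1)`.
#' @return Factor with levels `absolute_fairness`, `moderate_fairness`,
#'   `relative_fairness`, `inequality_warning`, `high_inequality`.
#' @export
classify_gini <- function(g) {
  if (any(!is.finite(g) | g < 0 | g >= 1)) {
    stop("Gini coefficient must lie in [0, 1)", call. = FALSE)
  }
  lev <- c("absolute_fairness", "moderate_fairness", "relative_fairness",
           "inequality_warning", "high_inequality")
  idx <- ifelse(g < 0.2, 1L,
         ifelse(g < 0.3, 2L,
         ifelse(g < 0.4, 3L,
         ifelse(g <= 0.6, 4L, 5L))))
  factor(lev[idx], levels = lev)
}

#' Theil index of a set of regional counts
#'
#' The entropy-based inequality index `T = (1/n) sum_i (Y_i / ybar)
#' ln(Y_i / ybar)` over the `n` regional counts `Y_i` with mean `ybar`
#' (the unweighted city-count form). Zero counts contribute 0 via the
#' limit `x ln x -> 0`. An optional weighting vector (e.g. population
#' shares) switches to the weighted form
#' `T = sum_i w_i (y_i/mu) ln(y_i/mu)` with `y_i = Y_i / w_i` densities
#' and `mu` the weighted mean; the unweighted default matches how the
#' index is usually reported for city counts.
#'
#' @param counts non-negative resource counts per region.
#' @param weights optional positive weights summing to anything (they are
#'   normalised); `NULL` (default) selects the unweighted city form.
#' @return Theil index, `>= 0`.
#' @export
theil_total <- function(counts, weights = NULL) {
  if (length(counts) < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(!is.finite(counts) | counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (sum(counts) <= 0) stop("all counts are zero: Theil index undefined", call. = FALSE)
  if (is.null(weights)) {
    w <- rep(1 / length(counts), length(counts))
    y <- counts
  } else {
    if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
    w <- weights / sum(weights)
    y <- counts / weights
  }
  mu <- sum(w * y)
  r <- y / mu
  sum(w * ifelse(r > 0, r * log(r), 0))
}

#' Theil index with within/between group decomposition
#'
#' Splits the total Theil index across a grouping of the regions into a
#' between-group component `T_B = sum_p S_p ln(S_p / P_p)` and a
#' within-group component `T_w = sum_p S_p T_p`, where `S_p` is group p's
#' resource share, `P_p = n_p / n` its size share and `T_p` its internal
#' Theil index. The identity `T = T_w + T_B` holds to machine precision.
#'
#' @param counts non-negative resource counts per region.
#' @param groups group label per region (same length as `counts`).
#' @return An object of class `theil_result`: list with `total`, `within`,
#'   `between`, `contribution_within`, `contribution_between` (both `NA`
#'   when `total == 0`), and `per_group` (data frame: `group`,
#'   `n_regions`, `resource_share`, `theil`).
#' @export
theil_decompose <- function(counts, groups) {
  if (length(groups) != length(counts)) {
    stop("groups must assign every region exactly once", call. = FALSE)
  }
  if (any(is.na(groups))) stop("unassigned region in grouping", call. = FALSE)
  total <- theil_total(counts)
  n <- length(counts)
  split_counts <- split(counts, groups)
  glab <- names(split_counts)
  S <- vapply(split_counts, sum, 0) / sum(counts)
  P <- vapply(split_counts, length, 0L) / n
  Tp <- vapply(split_counts, function(cc) {
    if (length(cc) < 2 || sum(cc) <= 0) return(0)
    theil_total(cc)
  }, 0)
  between <- sum(ifelse(S > 0, S * log(S / P), 0))
  within <- sum(S * Tp)
  structure(list(
    total = total, within = within, between = between,
    contribution_within = if (total > 0) within / total else NA_real_,
    contribution_between = if (total > 0) between / total else NA_real_,
    per_group = data.frame(group = glab,
                           n_regions = vapply(split_counts, length, 0L),
                           resource_share = S, theil = Tp,
                           row.names = NULL)),
    class = "theil_result")
}

#' @export
print.theil_result <- function(x, ...) {
  cat(sprintf("Theil index: total %.5f = within %.5f + between %.5f\n",
              x$total, x$within, x$between))
  if (!is.na(x$contribution_within)) {
    cat(sprintf("contribution: within %.1f%% | between %.1f%%\n",
                100 * x$contribution_within, 100 * x$contribution_between))
  }
  invisible(x)
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("<lorenz_curve> basis = %s, %d regions, Gini = %.4f\n",
              x$basis, length(x$W), gini_paper(x)))
  invisible(x)
}

#' Per-year Gini coefficients of a panel
#'
#' Convenience wrapper: for each year (one stratum) builds the Lorenz curve
#' over regions and returns the Gini coefficient with its fairness label,
#' for a chosen basis.
#'
#' @param panel an `equicast_panel`.
#' @param basis `"population"` or `"area"`.
#' @param resource panel column used as the resource (default `"nurses"`).
#' @param stratum stratum to analyse (default `"whole"`).
#' @return Data frame: `year`, `basis`, `gini`, `fairness`.
#' @export
panel_gini <- function(panel, basis = c("population", "area"),
                       resource = "nurses", stratum = "whole") {
  basis <- match.arg(basis)
  df <- as.data.frame(panel)
  df <- df[df$stratum == stratum, , drop = FALSE]
  wcol <- if (basis == "population") "population" else "area_km2"
  out <- lapply(split(df, df$year), function(yr) {
    curve <- build_lorenz(yr[[wcol]], yr[[resource]], basis = basis,
                          labels = yr$region_id)
    g <- gini_paper(curve)
    data.frame(year = yr$year[1], basis = basis, gini = g,
               fairness = as.character(classify_gini(g)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$year), ]
}

#' Per-year Theil decomposition of a panel
#'
#' @param panel an `equicast_panel`.
#' @param groups named vector mapping `region_id` to a group label; if
#'   `NULL` all regions form one group (between-group component 0).
#' @param resource panel column used as the resource.
#' @param stratum stratum to analyse.
#' @return Data frame: `year`, `total`, `within`, `between`,
#'   `contribution_within`, `contribution_between`.
#' @export
panel_theil <- function(panel, groups = NULL, resource = "nurses",
                        stratum = "whole") {
  df <- as.data.frame(panel)
  df <- df[df$stratum == stratum, , drop = FALSE]
  out <- lapply(split(df, df$year), function(yr) {
    g <- if (is.null(groups)) rep("all", nrow(yr)) else {
      if (!all(yr$region_id %in% names(groups))) {
        stop("grouping does not cover region(s): ",
             paste(setdiff(yr$region_id, names(groups)), collapse = ", "),
             call. = FALSE)
      }
      unname(groups[yr$region_id])
    }
    td <- theil_decompose(yr[[resource]], g)
    data.frame(year = yr$year[1], total = td$total, within = td$within,
               between = td$between,
               contribution_within = td$contribution_within,
               contribution_between = td$contribution_between)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$year), ]
}
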
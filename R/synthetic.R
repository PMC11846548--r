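#' @title Synthetic yearbook-like panels with known ground truth
#' @description
#' Generators that emulate a provincial statistical-yearbook panel — a
#' small number of prefecture-level regions observed annually over two
#' decades, with near-exponential nurse growth, heterogeneous populations
#' and land areas, and configurable between-region inequality — plus exact
#' oracle fixtures for the equity and grey-model estimators. Everything is
#' deterministic given the seed.
#' @name synthetic_data
NULL

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the headline profile of a mid-sized Chinese province:
#' 11 prefecture-level regions over 2003-2022, mean nurse-count growth of
#' 7.8%/yr, a baseline density of about 1 nurse per 1,000 population in
#' the first year, and region populations/areas drawn log-normally around
#' 3.5 million persons and 15,000 km2.
#'
#' @param n_regions number of regions (default 11).
#' @param years calendar years covered (default 2003:2022).
#' @param growth_mean mean annual nurse growth rate (fraction/yr, default
#'   0.078).
#' @param growth_sd between-region s.d. of the growth rate (default 0.01).
#' @param density_log_mean log of the baseline per-capita nurse density
#'   (nurses per person) in the first year (default `log(1e-3)`, i.e. 1
#'   per 1,000).
#' @param density_sigma s.d. of log per-capita nurse density across
#'   regions (default 0.3); 0 makes every region equally dense.
#' @param pop_log_median,pop_log_sd log-normal parameters of region
#'   population (defaults: median 3.5e6, sdlog 0.5).
#' @param area_log_median,area_log_sd log-normal parameters of region
#'   area in km2 (defaults: median 1.5e4, sdlog 0.4).
#' @param nurses_per_doctor_path length-2 vector: nurses-per-doctor ratio
#'   in the first and last year, interpolated linearly (default
#'   `c(0.70, 1.27)`).
#' @param nurses_per_bed_path nurses-per-bed ratio path (default
#'   `c(0.41, 0.46)`).
#' @param nurse_share_path nurse share of health technicians path
#'   (default `c(0.28, 0.45)`).
#' @param noise_sd s.d. of multiplicative log-normal noise on yearly
#'   nurse counts (default 0.02).
#' @param round_counts round all counts to integers as yearbooks publish
#'   them (default `TRUE`).
#' @param seed mandatory integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 11, years = 2003:2022,
                             growth_mean = 0.078, growth_sd = 0.01,
                             density_log_mean = log(1e-3),
                             density_sigma = 0.3,
                             pop_log_median = log(3.5e6), pop_log_sd = 0.5,
                             area_log_median = log(1.5e4), area_log_sd = 0.4,
                             nurses_per_doctor_path = c(0.70, 1.27),
                             nurses_per_bed_path = c(0.41, 0.46),
                             nurse_share_path = c(0.28, 0.45),
                             noise_sd = 0.02, round_counts = TRUE,
                             seed = 1) {
  stopifnot(n_regions >= 2, length(years) >= 2, all(diff(years) == 1),
            growth_sd >= 0, density_sigma >= 0, noise_sd >= 0,
            pop_log_sd > 0, area_log_sd > 0,
            all(nurse_share_path > 0), all(nurse_share_path < 1),
            all(nurses_per_doctor_path > 0), all(nurses_per_bed_path > 0))
  if (is.null(seed) || !is.finite(seed)) stop("seed is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

# Per-region substream: adding a region never perturbs the draws of the
# others. Seeds stay below 2^31.
region_seed <- function(seed, r) (as.integer(seed) %% 99991L) * 20011L + r

#' Generate a synthetic region-by-year panel
#'
#' Nurse counts follow `count_r(t) = count_r(t0) * (1 + g_r)^t` with
#' region-specific growth `g_r ~ N(growth_mean, growth_sd)` and
#' multiplicative log-normal noise; doctors, beds and health technicians
#' are derived from the configured ratio trajectories. The result passes
#' strict panel validation.
#'
#' @param config a [synthetic_config()].
#' @return An `equicast_panel` with one `"whole"`-stratum record per
#'   region and year.
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_years <- length(cfg$years)
  t_frac <- (seq_len(n_years) - 1) / (n_years - 1)
  npd <- cfg$nurses_per_doctor_path[1] +
    t_frac * diff(cfg$nurses_per_doctor_path)
  npb <- cfg$nurses_per_bed_path[1] + t_frac * diff(cfg$nurses_per_bed_path)
  share <- cfg$nurse_share_path[1] + t_frac * diff(cfg$nurse_share_path)
  rows <- vector("list", cfg$n_regions)
  for (r in seq_len(cfg$n_regions)) {
    set.seed(region_seed(cfg$seed, r))
    pop <- stats::rlnorm(1, cfg$pop_log_median, cfg$pop_log_sd)
    area <- stats::rlnorm(1, cfg$area_log_median, cfg$area_log_sd)
    dens0 <- exp(cfg$density_log_mean +
                   if (cfg$density_sigma > 0) stats::rnorm(1, 0, cfg$density_sigma) else 0)
    g <- cfg$growth_mean + if (cfg$growth_sd > 0) stats::rnorm(1, 0, cfg$growth_sd) else 0
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n_years, 0, cfg$noise_sd) else
      rep(0, n_years)
    nurses <- pop * dens0 * (1 + g)^(seq_len(n_years) - 1) * exp(noise)
    tech <- nurses / share
    doctors <- nurses / npd
    beds <- nurses / npb
    if (cfg$round_counts) {
      pop_i <- round(pop); area_i <- round(area, 1)
      nurses <- round(nurses); doctors <- round(doctors); beds <- round(beds)
      tech <- pmax(round(tech), nurses)   # rounding must not break the subset rule
    } else {
      pop_i <- pop; area_i <- area
    }
    rows[[r]] <- data.frame(
      region_id = sprintf("region_%02d", r), year = cfg$years,
      stratum = "whole", population = pop_i, area_km2 = area_i,
      nurses = nurses, doctors = doctors, health_technicians = tech,
      beds = beds, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (cfg$round_counts) validate_panel(df, strict = TRUE)
  new_panel(df, provenance = sprintf("synthetic (seed %s)", cfg$seed))
}

#' Exact two-region Gini fixture
#'
#' Constructs two aggregate regions whose Lorenz curve is exactly
#' `(0,0), (w, s), (1,1)` — the poorer group holds basis share `w` but
#' only resource share `s <= w` — so the Gini coefficient is `w - s` in
#' closed form, independent of any estimator under test.
#'
#' @param w poorer-group basis share in (0, 1).
#' @param s poorer-group resource share in `[0, w]`.
#' @param total_basis,total_resource overall totals (defaults 1e6 and
#'   1e4; the Gini is scale-free).
#' @return List: `basis_weight`, `resource` (length-2 vectors, poorer
#'   region first), `expected_gini = w - s`.
#' @export
make_two_point_fixture <- function(w, s, total_basis = 1e6,
                                   total_resource = 1e4) {
  if (w <= 0 || w >= 1) stop("w must lie in (0, 1)", call. = FALSE)
  if (s < 0 || s > w) {
    stop("s must lie in [0, w]: regions are ranked ascending by density",
         call. = FALSE)
  }
  list(basis_weight = c(w, 1 - w) * total_basis,
       resource = c(s, 1 - s) * total_resource,
       expected_gini = w - s)
}

#' Grey-consistent series generator
#'
#' Produces a series that satisfies the GM(1,1) grey difference equation
#' `x0(k) + a * z1(k) = u` exactly (with background coefficient 1/2), by
#' forward recursion `x0(k) = (u - a * x1(k-1)) / (1 + a/2)`. Fitting
#' such a series must recover `(a, u)` to machine precision with zero
#' residuals.
#'
#' @param a development coefficient, `|a| > 1e-8` and `a != -2`.
#' @param u grey action quantity.
#' @param x1_init first value `x0(1)`.
#' @param N series length, `>= 4`.
#' @return Numeric series of length N, all values > 0.
#' @export
make_grey_consistent_series <- function(a, u, x1_init, N) {
  if (N < 4) stop("N must be >= 4", call. = FALSE)
  if (abs(a) < 1e-8) stop("a ~ 0 is degenerate for GM(1,1)", call. = FALSE)
  if (abs(2 + a) < 1e-8) stop("a = -2 makes the recursion singular", call. = FALSE)
  x0 <- numeric(N)
  x0[1] <- x1_init
  x1_prev <- x1_init
  for (k in 2:N) {
    x0[k] <- (u - a * x1_prev) / (1 + a / 2)
    x1_prev <- x1_prev + x0[k]
  }
  if (any(x0 <= 0)) {
    stop("parameter combination produces non-positive values", call. = FALSE)
  }
  x0
}

#' A pure noise series for grading fixtures
#'
#' I.i.d. positive noise with no trend: a GM(1,1) fit on it should grade
#' poorly (levels 3-4) and block extrapolation.
#'
#' @param n length (default 12).
#' @param seed integer seed.
#' @return Positive numeric series.
#' @export
make_noise_series <- function(n = 12, seed = 1) {
  set.seed(seed)
  exp(stats::rnorm(n, mean = log(100), sd = 0.5))
}
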
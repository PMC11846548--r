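# Shared fixtures: a small hand-written panel and random-panel draws for
# property tests. All randomness is seeded by the caller.

toy_panel_df <- function() {
  data.frame(
    region_id = rep(c("A", "B"), each = 2),
    year = rep(2020:2021, 2),
    stratum = "whole",
    population = rep(c(1e6, 2e6), each = 2),
    area_km2 = rep(c(1e4, 3e4), each = 2),
    nurses = c(3190, 3400, 5000, 5400),
    doctors = c(2500, 2700, 4200, 4500),
    health_technicians = c(8000, 8500, 12000, 12800),
    beds = c(7000, 7400, 11000, 11700),
    stringsAsFactors = FALSE)
}

write_toy_panel <- function(df = toy_panel_df(), delimiter = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE)
  path
}

# Random region sets with log-normal densities, the stated world of the
# equity property tests: 2-50 regions, weights and densities heterogeneous.
random_regions <- function() {
  n <- sample(2:50, 1)
  w <- rlnorm(n, log(1e5), 0.8)
  dens <- rlnorm(n, log(2e-3), 0.6)
  list(weights = w, resource = round(w * dens))
}
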
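# Synthetic reef-grid generator: determinism, planted covariate effects,
# spatial clustering and the survival/DHW processes.

test_that("same config and seed reproduce the grid bit-for-bit", {
  cfg <- sim_config(n_localities = 200, seed = 5)
  g1 <- generate_grid(cfg)
  g2 <- generate_grid(cfg)
  expect_identical(g1$localities, g2$localities)
  expect_identical(g1$alerts_l1, g2$alerts_l1)
  expect_identical(g1$dhw, g2$dhw)
  r1 <- generate_records(g1)
  r2 <- generate_records(g2)
  expect_identical(r1, r2)
  g3 <- generate_grid(sim_config(n_localities = 200, seed = 6))
  expect_false(identical(g1$localities, g3$localities))
})

test_that("grid respects its invariants and degenerate fractions", {
  g <- generate_grid(sim_config(n_localities = 300, seed = 2))
  loc <- g$localities
  expect_false(any(duplicated(loc[, c("lon", "lat")])))
  expect_true(all(loc$lon >= -180 & loc$lon < 180))
  expect_true(all(abs(loc$lat) <= 90))
  expect_true(all(loc$gravity >= 0) && all(loc$remoteness >= 0))
  expect_true(all(g$alerts_l1 >= 0) && all(g$alerts_l1 == round(g$alerts_l1)))
  expect_true(all(g$dhw >= 0))

  g0 <- generate_grid(sim_config(n_localities = 100, restored_fraction = 0, seed = 1))
  expect_false(any(g0$localities$restored))
  g1 <- generate_grid(sim_config(n_localities = 100, restored_fraction = 1, seed = 1))
  expect_true(all(g1$localities$restored))
})

test_that("invalid configurations are rejected with messages", {
  expect_error(sim_config(n_localities = 0), "n_localities")
  expect_error(sim_config(gravity_sdlog = 0), "degenerate covariate variance")
  expect_error(sim_config(survival_noise_sd = -1), "survival_noise_sd")
  expect_error(sim_config(not_a_field = 1), "unknown")
  g0 <- generate_grid(sim_config(n_localities = 50, restored_fraction = 0, seed = 1))
  expect_error(generate_records(g0), "at least one restored locality")
})

test_that("a planted gravity coefficient makes prevalence rise across gravity deciles", {
  cfg <- sim_config(n_localities = 20000, lon_range = c(-180, 179.5),
                    lat_range = c(-30, 30), restored_fraction = 0.5,
                    beta = c(gravity = 3, remoteness = 0, impact_mean = 0,
                             impact_trend = 0, coral_richness = 0),
                    spatial_range_km = 0, spatial_sd = 0, seed = 42)
  loc <- generate_grid(cfg)$localities
  dec <- cut(loc$gravity, quantile(loc$gravity, 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  prev <- tapply(loc$restored, dec, mean)
  expect_true(all(diff(prev) >= 0))
  expect_gt(prev[10] - prev[1], 0.5)
})

test_that("planted truth is recoverable by an independent logistic refit", {
  cfg <- sim_config(n_localities = 6000, lon_range = c(-180, 179.5),
                    lat_range = c(-30, 30), restored_fraction = 0.3,
                    beta = c(gravity = 1.5, remoteness = -1.2, impact_mean = 0.8,
                             impact_trend = 0, coral_richness = 0),
                    spatial_range_km = 0, spatial_sd = 0, seed = 11)
  loc <- generate_grid(cfg)$localities
  fit <- suppressWarnings(   # separation warnings expected: planted effects are strong
    glm(restored ~ scale(gravity) + scale(remoteness) + scale(impact_mean),
        family = binomial, data = loc))
  co <- coef(fit)[-1]
  expect_gt(co[1], 0); expect_lt(co[2], 0); expect_gt(co[3], 0)
})

test_that("restored flags cluster when the random-field range is positive", {
  null_cfg <- list(restored_fraction = 0.3,
                   beta = c(gravity = 0, remoteness = 0, impact_mean = 0,
                            impact_trend = 0, coral_richness = 0))
  pvals <- function(range_km, sd, seeds) vapply(seeds, function(s) {
    cfg <- do.call(sim_config, c(null_cfg, list(n_localities = 250,
      spatial_range_km = range_km, spatial_sd = sd, seed = s)))
    loc <- generate_grid(cfg)$localities
    jc <- join_count_test(loc$restored,
                          distance_band_graph(loc[, c("lon", "lat")], 300))
    p <- reefrestore:::join_count_p(jc)
    if (is.na(p)) 1 else p
  }, numeric(1))
  reject_null <- mean(pvals(0, 0, 1:100) < 0.05)
  reject_clustered <- mean(pvals(500, 2, 1:60) < 0.05)
  expect_gte(reject_null, 0.0); expect_lte(reject_null, 0.10)   # 0.05 +/- 5 pts
  expect_gt(reject_clustered, 0.4)
})

test_that("records obey the survival process and monitoring bounds", {
  # noiseless limit: observed survival equals the decay expectation, so the
  # success score is exactly ln(101) for every record
  cfg <- sim_config(n_localities = 150, restored_fraction = 0.4,
                    survival_noise_sd = 0, record_missing_fraction = 0, seed = 3)
  g <- generate_grid(cfg)
  rec <- generate_records(g)
  curve <- decay_curve(cfg$decay_asymptote, cfg$decay_rate)
  sc <- score_records(rec, curve)
  expect_equal(sc$s_r, rep(log(101), nrow(sc)), tolerance = 1e-12)
  expect_true(all(rec$monitoring_months >= 0.8 & rec$monitoring_months <= 144))
  expect_true(all(rowSums(rec[, c("gardening", "transplantation",
                                  "artificial_reef", "larval_enhancement")]) >= 1))

  # boundary of the time axis: monitoring forced to one month
  cfg1 <- sim_config(n_localities = 100, restored_fraction = 0.4,
                     monitoring_range = c(1, 1), survival_noise_sd = 0,
                     record_missing_fraction = 0, seed = 3)
  rec1 <- generate_records(generate_grid(cfg1))
  expect_equal(rec1$observed_survival,
               rep(expected_survival(curve, 1), nrow(rec1)), tolerance = 1e-12)
})

test_that("a planted technique effect raises the mean success score", {
  cfg <- sim_config(n_localities = 1500, lon_range = c(-180, 179.5),
                    lat_range = c(-30, 30), restored_fraction = 0.6,
                    records_extra_lambda = 2.5, survival_noise_sd = 0.2,
                    record_missing_fraction = 0,
                    survival_effects = list(gardening = 0.4), seed = 8)
  g <- generate_grid(cfg)
  rec <- generate_records(g)
  expect_gt(nrow(rec), 2000)
  sc <- score_records(rec, decay_curve(cfg$decay_asymptote, cfg$decay_rate))
  expect_gt(mean(sc$s_r[sc$gardening]), mean(sc$s_r[!sc$gardening]) + 0.1)
  expect_true(all(rec$observed_survival <= cfg$survival_cap, na.rm = TRUE))
})

test_that("DHW series follow baseline + trend with exact threshold crossings", {
  mk <- function(...) generate_grid(sim_config(
    n_localities = 50, dhw_trend_restored_bonus = 0, seed = 4, ...))
  g0 <- mk(dhw_baseline_mean = 0, dhw_baseline_sd = 0,
           dhw_trend_mean = 0, dhw_trend_sd = 0, dhw_noise_sd = 0)
  expect_true(all(g0$dhw == 0))
  expect_equal(sum(dhw_exceedance(g0)$per_locality$n_exceedance_years), 0)

  # baseline + trend x (2063 - 2015) = 20 exactly: first exceedance 2063
  g1 <- mk(dhw_baseline_mean = 2, dhw_baseline_sd = 0,
           dhw_trend_mean = 18 / 48, dhw_trend_sd = 0, dhw_noise_sd = 0)
  ex <- dhw_exceedance(g1)$per_locality
  expect_true(all(ex$first_exceedance_year == 2063))

  # stochastic ensemble: mean first crossing within 2 years of the
  # noiseless one (1,000 replicate series)
  g2 <- generate_grid(sim_config(n_localities = 1000, lon_range = c(-180, 179.5),
    lat_range = c(-30, 30), dhw_baseline_mean = 2, dhw_baseline_sd = 0,
    dhw_trend_mean = 18 / 48, dhw_trend_sd = 0.03, dhw_noise_sd = 0.5,
    dhw_trend_restored_bonus = 0, seed = 4))
  mfe <- mean(dhw_exceedance(g2)$per_locality$first_exceedance_year, na.rm = TRUE)
  expect_lt(abs(mfe - 2063), 2)
  expect_error(sim_config(dhw_noise_sd = -0.1), "dhw_noise_sd")
})

test_that("grid and records round-trip to plain-text files", {
  dir <- withr::local_tempdir()
  g <- generate_grid(sim_config(n_localities = 40, restored_fraction = 0.3, seed = 2))
  rec <- generate_records(g)
  files <- write_grid_csv(g, dir, records = rec)
  expect_true(all(file.exists(files)))
  loc2 <- read.csv(file.path(dir, "localities.csv"))
  expect_equal(loc2$gravity, g$localities$gravity)
  dhw2 <- read.csv(file.path(dir, "dhw_annual_max.csv"))
  expect_equal(nrow(dhw2), 40 * length(g$dhw_years))
  expect_true(any(grepl("seed", readLines(file.path(dir, "config.txt")))))
})
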
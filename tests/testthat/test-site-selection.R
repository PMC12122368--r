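# TSS threshold scanning, the collinearity screen and the site-selection
# pipeline on synthetic grids with and without planted structure.

test_that("TSS scan handles the perfect and the chance classifier", {
  y <- c(rep(1, 20), rep(0, 30))
  p <- c(runif(20, 0.8, 1), runif(30, 0, 0.2))
  ev <- tss_threshold_scan(p, y)
  expect_equal(ev$tss, 1)
  expect_equal(ev$false_positive_rate, 0)
  expect_equal(ev$false_negative_rate, 0)

  set.seed(2)
  yn <- rbinom(10000, 1, 0.3)
  pn <- runif(10000)
  expect_lt(abs(tss_threshold_scan(pn, yn)$tss), 0.05)
  expect_error(tss_threshold_scan(pn, rep(1, 10000)), "both classes")
})

test_that("TSS scan equals brute-force maximisation over the 900-point grid", {
  set.seed(7)
  y <- rbinom(400, 1, 0.25)
  p <- plogis(rnorm(400) + 2 * y)
  ev <- tss_threshold_scan(p, y)
  # independent brute force: confusion matrix per threshold
  thresholds <- seq(0.001, 0.900, by = 0.001)
  best <- -Inf; best_t <- NA
  for (t in thresholds) {
    tp <- sum(p >= t & y == 1); fn <- sum(p < t & y == 1)
    tn <- sum(p < t & y == 0); fp <- sum(p >= t & y == 0)
    tss <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (tss > best + 1e-15) { best <- tss; best_t <- t }
  }
  expect_equal(ev$tss, best, tolerance = 1e-12)
  expect_equal(ev$threshold, best_t)
  expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1)
})

test_that("collinearity screen flags duplicates and matches regression R^2", {
  set.seed(1)
  f <- data.frame(a = rnorm(200), b = rnorm(200))
  f$dup <- f$a
  expect_message(res <- collinearity_screen(f), "flagged")
  expect_equal(res$r2["a", "dup"], 1)
  expect_true(any(res$flagged$var_a == "a" & res$flagged$var_b == "dup"))

  big <- as.data.frame(matrix(rnorm(10000 * 4), 10000))
  res2 <- collinearity_screen(big)
  off <- res2$r2[upper.tri(res2$r2)]
  expect_lt(max(off), 0.01)
  # correlation squared equals regression R-squared
  r2_reg <- summary(lm(big$V1 ~ big$V2))$r.squared
  expect_equal(res2$r2["V1", "V2"], r2_reg, tolerance = 1e-12)

  f$const <- 1
  expect_message(res3 <- collinearity_screen(f), "flagged")
  expect_true(all(is.na(res3$r2["const", c("a", "b", "dup")])))
})

test_that("site predictor table carries alert window statistics", {
  a1 <- matrix(0L, 2, 36); a2 <- matrix(0L, 2, 36)
  # locality 1: severe counts 1,2,3,4,5 over 2006-2010
  a1[1, 21:25] <- 1:5
  g <- toy_grid(c(100, 101), c(0, 0), c(TRUE, FALSE), a1, a2)
  tab <- build_site_table(g, reference_year = 2010)
  expect_equal(tab$alert_mean_pre[1], mean(1:5))
  expect_equal(tab$alert_trend_pre[1], 1)    # OLS slope of 1..5 per year
  expect_equal(tab$alert_mean_pre[2], 0)
  expect_error(build_site_table(g, reference_year = 1986), "outside")
})

test_that("the pipeline is reproducible and near chance on a null grid", {
  # test splits are kept large (wide window, high prevalence) because the
  # TSS threshold scan is optimistically biased on small ones
  null_grid <- generate_grid(sim_config(
    n_localities = 1500, lon_range = c(-180, 179.5), lat_range = c(-30, 30),
    restored_fraction = 0.35,
    beta = c(gravity = 0, remoteness = 0, impact_mean = 0, impact_trend = 0,
             coral_richness = 0),
    spatial_range_km = 0, spatial_sd = 0, seed = 31))
  cfg <- site_config(replicates = 8, brt = fast_brt())
  res <- run_site_selection(null_grid, config = cfg, seed = 12)
  expect_lt(abs(res$summary$tss_mean), 0.12)

  one <- site_config(replicates = 1, brt = fast_brt())
  r1 <- run_site_selection(null_grid, config = one, seed = 99)
  r2 <- run_site_selection(null_grid, config = one, seed = 99)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$influence, r2$influence)
  # aggregates recomputable from the stored per-replicate values
  expect_equal(res$summary$tss_mean, mean(res$replicates$tss))
  expect_equal(res$summary$tss_sd, sd(res$replicates$tss))
})

test_that("planted accessibility effects are recovered with sensible error balance", {
  g <- generate_grid(sim_config(
    n_localities = 1200, restored_fraction = 0.12,
    beta = c(gravity = 2, remoteness = -1.2, impact_mean = 0.5,
             impact_trend = 0, coral_richness = -0.3),
    spatial_range_km = 250, spatial_sd = 0.6, seed = 11))
  res <- run_site_selection(g, config = site_config(replicates = 6,
                                                    brt = fast_brt()),
                            seed = 5)
  expect_identical(res$influence$variable[1], "gravity")
  pd <- res$partial_dependence$gravity
  expect_gt(cor(pd$value, pd$yhat, method = "spearman"), 0.9)
  expect_gt(res$summary$tss_mean, 0.4)
  # symmetric planted model + prevalence weights: sensitivity near specificity
  expect_lt(abs(mean(res$replicates$sensitivity) -
                mean(res$replicates$specificity)), 0.15)

  # halving the training information degrades skill only modestly
  res50 <- run_site_selection(g, config = site_config(replicates = 6,
                                                      train_fraction = 0.5,
                                                      brt = fast_brt()),
                              seed = 5)
  expect_gte(res50$summary$tss_mean, res$summary$tss_mean - 0.15)
})

test_that("tuning over a small grid picks a parameterization and reports it", {
  g <- generate_grid(sim_config(
    n_localities = 700, restored_fraction = 0.15,
    beta = c(gravity = 2, remoteness = -1, impact_mean = 0, impact_trend = 0,
             coral_richness = 0),
    spatial_range_km = 0, spatial_sd = 0, seed = 17))
  tune <- brt_tuning_grid(learning_rate = 0.05, bag_fraction = c(0.5, 0.8),
                          tree_complexity = c(1, 3))
  cfg <- site_config(replicates = 3, brt = fast_brt(), tuning = tune,
                     n_tune_models = 2)
  res <- run_site_selection(g, config = cfg, seed = 21)
  expect_equal(nrow(res$tuning), 4)
  expect_true(all(is.finite(res$tuning$mean_tss)))
  best <- res$tuning[which.max(res$tuning$mean_tss), ]
  expect_equal(res$model$config$bag_fraction, best$bag_fraction)
})
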
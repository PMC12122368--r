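# Stage 2: do technique, environment and thermal exposure predict the
# standardized restoration-success score? BRT regression on deduplicated,
# Moran-screened record sets, accuracy as test-split Pearson R-squared.

SUCCESS_PREDICTORS <- c("gardening", "transplantation", "artificial_reef",
                        "larval_enhancement", "n_genera", "gravity",
                        "remoteness", "impact_mean", "impact_trend",
                        "coral_richness", "alerts_pre", "alerts_post")

#' Feature/response table for the success analysis
#'
#' Scores each restoration record ([score_records()]), joins the locality
#' covariates, and adds counts of severe (level I or worse) bleaching-alert
#' events in the 5-year windows before and after each record's restoration
#' year (the restoration year belongs to the pre window; the post window is
#' the 5 years strictly after, clipped to alert coverage). Rows with any
#' missing field are dropped with a reported count.
#'
#' @param records `restoration_records`.
#' @param grid The `reef_grid` the records belong to.
#' @param curve `decay_curve` for the expected-survival standardization.
#' @return Data frame with response `s_r`, the technique/environment/
#'   exposure predictors, and lon/lat for thinning; attribute `n_excluded`.
#' @export
build_success_table <- function(records, grid, curve = default_decay_curve()) {
  scored <- suppressMessages(score_records(records, curve))
  n_excluded <- attr(scored, "n_excluded")
  loc <- grid$localities
  j <- match(scored$locality_id, loc$id)
  if (anyNA(j))
    stop("record(s) reference unknown localities: ",
         paste(unique(scored$locality_id[is.na(j)]), collapse = ", "),
         call. = FALSE)
  sev <- severe_alerts(grid)
  count_window <- function(row_idx, year, side) {
    yrs <- intersect(window_years(year, side), grid$alert_years)
    if (length(yrs) == 0L) return(0)
    sum(sev[row_idx, as.character(yrs)])
  }
  out <- data.frame(
    locality_id = scored$locality_id,
    lon = loc$lon[j], lat = loc$lat[j],
    s_r = scored$s_r,
    gardening = as.numeric(scored$gardening),
    transplantation = as.numeric(scored$transplantation),
    artificial_reef = as.numeric(scored$artificial_reef),
    larval_enhancement = as.numeric(scored$larval_enhancement),
    n_genera = scored$n_genera,
    gravity = loc$gravity[j], remoteness = loc$remoteness[j],
    impact_mean = loc$impact_mean[j], impact_trend = loc$impact_trend[j],
    coral_richness = loc$coral_richness[j],
    alerts_pre = vapply(seq_len(nrow(scored)), function(i)
      count_window(j[i], scored$year[i], "pre"), numeric(1)),
    alerts_post = vapply(seq_len(nrow(scored)), function(i)
      count_window(j[i], scored$year[i], "post"), numeric(1)))
  keep <- complete.cases(out)
  if (any(!keep)) message(sum(!keep), " joined row(s) dropped: incomplete")
  out <- out[keep, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded + sum(!keep)
  out
}

#' Configuration for the success analysis
#'
#' @param replicates Number of train/test replicates.
#' @param thinning_km Deduplication distance (1 km: only coincident sites
#'   are collapsed).
#' @param alpha Moran's I screen level; subsets are retained when p >
#'   `alpha`.
#' @param max_tries Maximum subset redraws.
#' @param train_fraction Training fraction (0.8).
#' @param brt [brt_config()] for the regression; the default carries the
#'   selected parameterization (learning rate 0.001, bag fraction 0.7,
#'   tree complexity 5) with squared-error loss.
#' @param suppress_threshold Mean R-squared below which variable-importance
#'   reporting is suppressed as potentially misleading (0.05).
#' @return List of class `success_config`.
#' @export
success_config <- function(replicates = 50L, thinning_km = 1, alpha = 0.05,
                           max_tries = 200L, train_fraction = 0.8,
                           brt = brt_config(learning_rate = 0.001,
                                            bag_fraction = 0.7,
                                            tree_complexity = 5,
                                            loss = "squared"),
                           suppress_threshold = 0.05) {
  if (brt$loss != "squared")
    stop("the success model is a regression: use squared loss", call. = FALSE)
  structure(list(replicates = as.integer(replicates), thinning_km = thinning_km,
                 alpha = alpha, max_tries = as.integer(max_tries),
                 train_fraction = train_fraction, brt = brt,
                 suppress_threshold = suppress_threshold),
            class = "success_config")
}

pearson_r2 <- function(obs, pred) {
  if (sd(pred) == 0 || sd(obs) == 0) return(0)
  cor(obs, pred)^2
}

#' Run the restoration-success analysis
#'
#' Per replicate: thin the record table at `thinning_km` (1 km collapses
#' only coincident sites), screen the retained success scores for spatial
#' autocorrelation with Moran's I (keeping subsets with p > `alpha`), split
#' 80/20, fit the BRT regression with holdout-deviance tree selection, and
#' record the Pearson R-squared of predicted versus observed success on the
#' test split. If the aggregate mean R-squared falls below
#' `suppress_threshold`, relative influence and partial dependence are
#' withheld with an explanatory message, since importance rankings from a
#' model without predictive skill are potentially misleading.
#'
#' @param table Output of [build_success_table()].
#' @param config A [success_config()].
#' @param seed Integer seed.
#' @return Object of class `success_result`: `replicates` (per-replicate
#'   R-squared and sizes), `summary` (mean/s.d. and pooled scatter
#'   R-squared), `influence` (`NULL` when suppressed), `suppressed`,
#'   `model` (full-data fit, always present for inspection).
#' @export
run_success_model <- function(table, config = success_config(), seed = 1L) {
  if (nrow(table) < 20L)
    stop("need at least 20 usable success records", call. = FALSE)
  reps <- vector("list", config$replicates)
  pooled_obs <- pooled_pred <- numeric(0)
  for (r in seq_len(config$replicates)) {
    rs <- derive_seed(seed, paste0("rep", r))
    sub <- sample_independent_subset(
      table[, c("lon", "lat")], table$s_r, config$thinning_km,
      test = "morans_i", alpha = config$alpha, max_tries = config$max_tries,
      seed = rs)
    d <- table[sub$indices, , drop = FALSE]
    tr <- with_seed(derive_seed(rs, "split"),
                    sort(sample.int(nrow(d), round(config$train_fraction * nrow(d)))))
    cfg <- config$brt; cfg$seed <- derive_seed(rs, "brt")
    fit <- fit_brt(d[tr, SUCCESS_PREDICTORS], d$s_r[tr], cfg)
    pred <- predict(fit, d[-tr, SUCCESS_PREDICTORS])
    obs <- d$s_r[-tr]
    reps[[r]] <- data.frame(r2 = pearson_r2(obs, pred), n_subset = nrow(d),
                            n_test = length(obs), n_trees = fit$n_trees,
                            moran_p = sub$independence_p)
    pooled_obs <- c(pooled_obs, obs); pooled_pred <- c(pooled_pred, pred)
  }
  reps <- do.call(rbind, reps)
  mean_r2 <- mean(reps$r2)
  suppressed <- mean_r2 < config$suppress_threshold

  full_cfg <- config$brt; full_cfg$seed <- derive_seed(seed, "full")
  full <- fit_brt(table[, SUCCESS_PREDICTORS], table$s_r, full_cfg)
  influence <- NULL
  if (suppressed) {
    message(sprintf(paste0("mean R^2 = %.3f < %.2f: variable-importance ",
                           "reporting suppressed as potentially misleading"),
                    mean_r2, config$suppress_threshold))
  } else {
    influence <- relative_influence(full)
  }
  structure(list(replicates = reps,
                 summary = list(r2_mean = mean_r2, r2_sd = sd(reps$r2),
                                pooled_r2 = pearson_r2(pooled_obs, pooled_pred),
                                n_replicates = nrow(reps)),
                 influence = influence, suppressed = suppressed,
                 model = full, config = config, seed = seed),
            class = "success_result")
}

#' @export
print.success_result <- function(x, ...) {
  s <- x$summary
  cat("Restoration-success model (", s$n_replicates, " replicates)\n", sep = "")
  cat(sprintf("  mean R^2 = %.3f +/- %.3f ; pooled scatter R^2 = %.5f\n",
              s$r2_mean, s$r2_sd, s$pooled_r2))
  if (x$suppressed)
    cat("  variable importance suppressed (no predictive skill)\n")
  invisible(x)
}
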
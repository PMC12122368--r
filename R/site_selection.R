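# Stage 1: which reef localities get restored? A BRT classifier on
# spatially independent subsets with inverse-prevalence class weights,
# evaluated by the true skill statistic at a scanned probability threshold.

#' Threshold scan maximising the true skill statistic
#'
#' Evaluates sensitivity and specificity at every probability threshold in
#' `thresholds` (default 0.001, 0.002, ..., 0.900) and returns the
#' evaluation at the TSS-maximising threshold (smallest threshold on ties).
#' A case is classified positive when its probability is >= the threshold.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param labels 0/1 observed classes (both must be present).
#' @param thresholds Candidate thresholds.
#' @return Object of class `classifier_eval`: list with `threshold`,
#'   `sensitivity`, `specificity`, `tss`, `false_positive_rate`,
#'   `false_negative_rate`.
#' @export
tss_threshold_scan <- function(probabilities, labels,
                               thresholds = seq(0.001, 0.900, by = 0.001)) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("TSS needs both classes in `labels`", call. = FALSE)
  p1 <- probabilities[y == 1]
  p0 <- probabilities[y == 0]
  sens <- vapply(thresholds, function(t) mean(p1 >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(p0 < t), numeric(1))
  tss <- sens + spec - 1
  i <- which.max(tss)   # first maximum = smallest threshold on ties
  structure(list(threshold = thresholds[i], sensitivity = sens[i],
                 specificity = spec[i], tss = tss[i],
                 false_positive_rate = 1 - spec[i],
                 false_negative_rate = 1 - sens[i]),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("TSS = %.3f at threshold %.3f (sens %.3f, spec %.3f; FPR %.3f, FNR %.3f)\n",
              x$tss, x$threshold, x$sensitivity, x$specificity,
              x$false_positive_rate, x$false_negative_rate))
  invisible(x)
}

#' Pairwise collinearity screen
#'
#' Squared Pearson correlations between all feature pairs; pairs at or above
#' the threshold are flagged (and reported) but nothing is removed -- the
#' analyses keep all predictors when every pairwise R-squared is below 0.7.
#'
#' @param features All-numeric data frame or matrix.
#' @param r2_threshold Flagging threshold (default 0.7).
#' @return List with `r2` (matrix; NA where a feature has zero variance)
#'   and `flagged` (data frame of flagged pairs, including undefined ones).
#' @export
collinearity_screen <- function(features, r2_threshold = 0.7) {
  x <- as_feature_matrix(features)
  if (ncol(x) < 2L) stop("need at least two features", call. = FALSE)
  sds <- apply(x, 2, sd)
  r2 <- suppressWarnings(cor(x))^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  diag(r2) <- 1
  flagged <- data.frame(var_a = character(0), var_b = character(0),
                        r2 = numeric(0))
  nm <- colnames(x)
  for (i in seq_len(ncol(x) - 1L)) for (j in (i + 1L):ncol(x)) {
    v <- r2[i, j]
    if (is.na(v) || v >= r2_threshold)
      flagged <- rbind(flagged, data.frame(var_a = nm[i], var_b = nm[j], r2 = v))
  }
  if (nrow(flagged) > 0)
    message(nrow(flagged), " collinear or undefined feature pair(s) flagged")
  list(r2 = r2, flagged = flagged)
}

# Severe (level I or worse) yearly event counts: level-I events plus
# level-II events.
severe_alerts <- function(grid) grid$alerts_l1 + grid$alerts_l2

# Pre/post windows around a restoration year: the restoration year belongs
# to the 5-year pre window, the post window is the 5 years strictly after.
window_years <- function(year, side = c("pre", "post"), width = 5L) {
  side <- match.arg(side)
  if (side == "pre") seq(year - width + 1L, year) else seq(year + 1L, year + width)
}

#' Predictor table for the site-selection model
#'
#' Joins the locality covariates with the mean and ordinary-least-squares
#' trend of severe (level I or worse) bleaching-alert counts over the
#' 5-year window ending at `reference_year`. Restoration is modelled from
#' conditions preceding it; non-restored localities have no restoration
#' date, so a common reference year (by default the median restoration year
#' of `records`, else the midpoint of alert coverage) anchors their window.
#'
#' @param grid A `reef_grid`.
#' @param records Optional `restoration_records` used to set the default
#'   reference year.
#' @param reference_year Calendar year anchoring the pre-restoration alert
#'   window.
#' @return Data frame with the response `restored` plus predictors gravity,
#'   remoteness, impact_mean, impact_trend, coral_richness,
#'   alert_mean_pre, alert_trend_pre (and lon/lat/id for thinning).
#' @export
build_site_table <- function(grid, records = NULL, reference_year = NULL) {
  reference_year <- reference_year %||%
    (if (!is.null(records)) as.integer(median(records$year))
     else as.integer(median(grid$alert_years)))
  yrs <- window_years(reference_year, "pre")
  if (!all(yrs %in% grid$alert_years))
    stop("pre-restoration alert window outside alert data coverage", call. = FALSE)
  sev <- severe_alerts(grid)[, as.character(yrs), drop = FALSE]
  loc <- grid$localities
  data.frame(id = loc$id, lon = loc$lon, lat = loc$lat,
             restored = as.numeric(loc$restored),
             gravity = loc$gravity, remoteness = loc$remoteness,
             impact_mean = loc$impact_mean, impact_trend = loc$impact_trend,
             coral_richness = loc$coral_richness,
             alert_mean_pre = rowMeans(sev),
             alert_trend_pre = apply(sev, 1, function(v) ols_slope(yrs, v)))
}

SITE_PREDICTORS <- c("gravity", "remoteness", "impact_mean", "impact_trend",
                     "coral_richness", "alert_mean_pre", "alert_trend_pre")

# Stratified train index: `fraction` of each class, at least one per class.
stratified_split <- function(y, fraction, seed) {
  with_seed(seed, {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    tr <- c(sample(idx1, max(1L, round(fraction * length(idx1)))),
            sample(idx0, max(1L, round(fraction * length(idx0)))))
    sort(tr)
  })
}

inverse_prevalence_weights <- function(y) {
  n <- length(y)
  prev <- c(`0` = mean(y == 0), `1` = mean(y == 1))
  unname(1 / prev[as.character(y)] / n * (n / 2))
}

#' Configuration for the site-selection analysis
#'
#' @param replicates Number of train/test replicates.
#' @param thinning_km Spatial-independence thinning distance (150 km).
#' @param band_km Join-count neighbour band (twice the thinning distance).
#' @param alpha Significance level of the join-count screen.
#' @param max_tries Maximum subset redraws per replicate.
#' @param train_fraction Fraction of each class used for training (0.8).
#' @param brt [brt_config()] used for every replicate; the default carries
#'   the selected parameterization (learning rate 0.001, bag fraction 0.5,
#'   tree complexity 3).
#' @param tuning Optional data frame of candidate parameterizations (see
#'   [brt_tuning_grid()]); when supplied, each combination is scored on
#'   `n_tune_models` replicates and the best mean TSS wins.
#' @param n_tune_models Replicates per tuning combination.
#' @param min_class_size Minimum restored/non-restored count a thinned
#'   subset must retain to be usable.
#' @return List of class `site_config`.
#' @export
site_config <- function(replicates = 50L, thinning_km = 150, band_km = 2 * thinning_km,
                        alpha = 0.05, max_tries = 200L, train_fraction = 0.8,
                        brt = brt_config(learning_rate = 0.001, bag_fraction = 0.5,
                                         tree_complexity = 3),
                        tuning = NULL, n_tune_models = 10L,
                        min_class_size = 5L) {
  structure(list(replicates = as.integer(replicates), thinning_km = thinning_km,
                 band_km = band_km, alpha = alpha,
                 max_tries = as.integer(max_tries),
                 train_fraction = train_fraction, brt = brt, tuning = tuning,
                 n_tune_models = as.integer(n_tune_models),
                 min_class_size = as.integer(min_class_size)),
            class = "site_config")
}

# One replicate: draw a join-count-validated thinned subset retaining both
# classes, split by class, weight by inverse prevalence, fit, scan TSS.
site_replicate <- function(table, config, brt_cfg, seed) {
  for (try in seq_len(config$max_tries)) {
    sub <- sample_independent_subset(
      table[, c("lon", "lat")], table$restored, config$thinning_km,
      test = "join_count", alpha = config$alpha,
      max_tries = config$max_tries,
      seed = derive_seed(seed, paste0("sub", try)),
      band_km = config$band_km)
    d <- table[sub$indices, , drop = FALSE]
    if (min(sum(d$restored == 1), sum(d$restored == 0)) >= config$min_class_size)
      break
    if (try == config$max_tries)
      stop("no thinned subset retained enough of both classes", call. = FALSE)
  }
  tr <- stratified_split(d$restored, config$train_fraction,
                         derive_seed(seed, "split"))
  xtr <- d[tr, SITE_PREDICTORS]; ytr <- d$restored[tr]
  xte <- d[-tr, SITE_PREDICTORS]; yte <- d$restored[-tr]
  if (length(unique(yte)) < 2L) return(NULL)  # caller redraws
  cfg <- brt_cfg; cfg$seed <- derive_seed(seed, "brt")
  fit <- fit_brt(xtr, ytr, cfg, weights = inverse_prevalence_weights(ytr))
  ev <- tss_threshold_scan(predict(fit, xte), yte)
  data.frame(tss = ev$tss, sensitivity = ev$sensitivity,
             specificity = ev$specificity,
             false_positive_rate = ev$false_positive_rate,
             false_negative_rate = ev$false_negative_rate,
             threshold = ev$threshold, n_subset = nrow(d),
             n_trees = fit$n_trees, subset_attempts = sub$attempts)
}

#' Run the restoration site-selection analysis
#'
#' Per replicate: draw a spatially independent locality subset (greedy
#' thinning at `thinning_km` validated by the join-count screen), split it
#' 80/20 stratified by restored status, weight classes inversely to their
#' prevalence, fit a BRT with holdout-deviance tree selection and evaluate
#' the true skill statistic at the optimal threshold on the test split.
#' Replicate evaluations are aggregated (mean and s.d. of TSS and both
#' error rates), and a final full-data model with the chosen
#' parameterization supplies relative influence and partial dependence.
#'
#' @param grid A `reef_grid`.
#' @param records Optional records (sets the alert reference year).
#' @param config A [site_config()].
#' @param seed Integer seed.
#' @return Object of class `site_selection_result`: `replicates` (per-
#'   replicate evaluations), `summary` (aggregates), `influence`,
#'   `partial_dependence` (list of curves), `model` (full-data `reef_brt`),
#'   `tuning` (mean TSS per candidate, when tuned), `collinearity`.
#' @export
run_site_selection <- function(grid, records = NULL, config = site_config(),
                               seed = 1L) {
  table <- build_site_table(grid, records)
  if (anyNA(table[, SITE_PREDICTORS])) {
    drop <- !complete.cases(table[, SITE_PREDICTORS])
    message(sum(drop), " localit(ies) dropped: missing predictors")
    table <- table[!drop, , drop = FALSE]
  }
  if (length(unique(table$restored)) < 2L)
    stop("need both restored and non-restored localities", call. = FALSE)
  screen <- collinearity_screen(table[, SITE_PREDICTORS])

  brt_cfg <- config$brt
  tuning_out <- NULL
  if (!is.null(config$tuning)) {
    tune_tss <- numeric(nrow(config$tuning))
    for (g in seq_len(nrow(config$tuning))) {
      cfg_g <- config$brt
      cfg_g$learning_rate <- config$tuning$learning_rate[g]
      cfg_g$bag_fraction <- config$tuning$bag_fraction[g]
      cfg_g$tree_complexity <- as.integer(config$tuning$tree_complexity[g])
      vals <- vapply(seq_len(config$n_tune_models), function(m) {
        r <- site_replicate(table, config, cfg_g,
                            derive_seed(seed, paste0("tune", g, "_", m)))
        if (is.null(r)) NA_real_ else r$tss
      }, numeric(1))
      tune_tss[g] <- mean(vals, na.rm = TRUE)
    }
    tuning_out <- cbind(config$tuning, mean_tss = tune_tss)
    best <- which.max(tune_tss)
    brt_cfg$learning_rate <- config$tuning$learning_rate[best]
    brt_cfg$bag_fraction <- config$tuning$bag_fraction[best]
    brt_cfg$tree_complexity <- as.integer(config$tuning$tree_complexity[best])
  }

  reps <- list()
  r <- 0L; attempt <- 0L
  while (r < config$replicates && attempt < config$replicates * 5L) {
    attempt <- attempt + 1L
    res <- site_replicate(table, config, brt_cfg,
                          derive_seed(seed, paste0("rep", attempt)))
    if (!is.null(res)) { r <- r + 1L; reps[[r]] <- res }
  }
  if (r == 0L) stop("no usable replicate produced", call. = FALSE)
  reps <- do.call(rbind, reps)

  full_cfg <- brt_cfg; full_cfg$seed <- derive_seed(seed, "full")
  full <- fit_brt(table[, SITE_PREDICTORS], table$restored, full_cfg,
                  weights = inverse_prevalence_weights(table$restored))
  # quantile-spaced grids: gravity and impact are strongly right-skewed, so
  # an even grid would spend most points in the data-free tail
  pd <- lapply(setNames(nm = SITE_PREDICTORS),
               function(v) partial_dependence(full, v, quantile_grid = TRUE))

  summary <- list(
    tss_mean = mean(reps$tss), tss_sd = sd(reps$tss),
    false_positive_mean = mean(reps$false_positive_rate),
    false_positive_sd = sd(reps$false_positive_rate),
    false_negative_mean = mean(reps$false_negative_rate),
    false_negative_sd = sd(reps$false_negative_rate),
    n_replicates = nrow(reps))
  structure(list(replicates = reps, summary = summary,
                 influence = relative_influence(full),
                 partial_dependence = pd, model = full,
                 tuning = tuning_out, collinearity = screen,
                 config = config, seed = seed),
            class = "site_selection_result")
}

#' @export
print.site_selection_result <- function(x, ...) {
  s <- x$summary
  cat("Restoration site-selection model (", s$n_replicates, " replicates)\n", sep = "")
  cat(sprintf("  TSS  = %.2f +/- %.2f\n", s$tss_mean, s$tss_sd))
  cat(sprintf("  FPR  = %.2f +/- %.2f ; FNR = %.2f +/- %.2f\n",
              s$false_positive_mean, s$false_positive_sd,
              s$false_negative_mean, s$false_negative_sd))
  cat("  Relative influence (%):\n")
  inf <- x$influence
  for (i in seq_len(nrow(inf)))
    cat(sprintf("    %-16s %5.1f\n", inf$variable[i], inf$influence[i]))
  invisible(x)
}
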
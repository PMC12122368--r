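# Boosted-regression-tree engine: stagewise gradient boosting with row
# subsampling, depth-limited trees and observation weights. Tree fitting is
# delegated to xgboost, which satisfies the contracts the analyses rely on
# (bag fraction, depth limit, weights in the loss, staged predictions at any
# intermediate tree count, seeded determinism); tree-count selection by
# holdout deviance, relative influence and partial dependence are built on
# top of it here.

#' Boosted-regression-tree configuration
#'
#' @param learning_rate Shrinkage per tree (> 0).
#' @param bag_fraction Row subsample fraction per tree, in (0, 1].
#' @param tree_complexity Maximum interaction depth (>= 1).
#' @param loss `"bernoulli"` (binary classification, logistic link) or
#'   `"squared"` (regression).
#' @param tree_range Candidate ensemble sizes, `c(min, max)`.
#' @param tree_step Step between candidate sizes.
#' @param n_folds Cross-validation folds for holdout-deviance tree-count
#'   selection.
#' @param seed Integer seed for subsampling and fold assignment.
#' @return Object of class `brt_config`.
#' @export
brt_config <- function(learning_rate = 0.001, bag_fraction = 0.5,
                       tree_complexity = 3,
                       loss = c("bernoulli", "squared"),
                       tree_range = c(50, 10000), tree_step = 10,
                       n_folds = 5, seed = 1L) {
  loss <- match.arg(loss)
  assert_number(learning_rate, "learning_rate", lower = 1e-12)
  assert_number(bag_fraction, "bag_fraction", lower = 1e-12, upper = 1)
  assert_number(tree_complexity, "tree_complexity", lower = 1)
  assert_number(tree_step, "tree_step", lower = 1)
  if (length(tree_range) != 2L || tree_range[1] > tree_range[2] ||
      tree_range[1] < 1)
    stop("tree_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  structure(list(learning_rate = learning_rate, bag_fraction = bag_fraction,
                 tree_complexity = as.integer(tree_complexity), loss = loss,
                 tree_range = as.integer(tree_range),
                 tree_step = as.integer(tree_step),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "brt_config")
}

#' Hyperparameter grid for BRT tuning
#'
#' The default grid crossed in the analyses: learning rate 0.01/0.001/0.0001,
#' bag fraction 0.5/0.7/0.8 and tree complexity 1-5.
#'
#' @param learning_rate,bag_fraction,tree_complexity Candidate values.
#' @return Data frame, one row per parameter combination.
#' @export
brt_tuning_grid <- function(learning_rate = c(0.01, 0.001, 0.0001),
                            bag_fraction = c(0.5, 0.7, 0.8),
                            tree_complexity = 1:5) {
  expand.grid(learning_rate = learning_rate, bag_fraction = bag_fraction,
              tree_complexity = tree_complexity)
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    num <- vapply(features, function(c) is.numeric(c) || is.logical(c), logical(1))
    if (!all(num))
      stop("non-numeric feature columns: ",
           paste(names(features)[!num], collapse = ", "), call. = FALSE)
    features <- as.matrix(as.data.frame(lapply(features, as.numeric)))
  }
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  features
}

xgb_params <- function(config) {
  list(objective = if (config$loss == "bernoulli") "binary:logistic"
                   else "reg:squarederror",
       eta = config$learning_rate,
       max_depth = config$tree_complexity,
       subsample = config$bag_fraction,
       min_child_weight = 1, lambda = 0,
       nthread = 1, seed = config$seed)
}

check_brt_inputs <- function(x, y, config) {
  if (nrow(x) < 10L) stop("boosted trees need at least 10 rows", call. = FALSE)
  if (anyNA(x)) stop("missing feature values: drop incomplete rows upstream",
                     call. = FALSE)
  if (config$loss == "bernoulli") {
    if (!all(y %in% c(0, 1)))
      stop("bernoulli loss needs a 0/1 response", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("bernoulli loss needs both classes present", call. = FALSE)
  }
}

# Weighted deviance of predictions: bernoulli -2 sum w [y log p + (1-y) log(1-p)]
# with p clipped for numerical safety, or weighted squared error; both
# normalised by total weight.
brt_deviance <- function(y, pred, weights, loss) {
  if (loss == "bernoulli") {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -2 * sum(weights * (y * log(p) + (1 - y) * log(1 - p))) / sum(weights)
  } else {
    sum(weights * (y - pred)^2) / sum(weights)
  }
}

#' Select the number of trees by cross-validated holdout deviance
#'
#' Splits the data into `folds` cross-validation folds, grows a full
#' ensemble on each training part, evaluates mean out-of-fold deviance along
#' the staged ensemble at every candidate tree count in
#' `seq(tree_range[1], tree_range[2], tree_step)`, and returns the count
#' minimizing it (smallest count on ties).
#'
#' @param features Numeric matrix or all-numeric data frame.
#' @param response Response vector (0/1 for bernoulli).
#' @param config A [brt_config()].
#' @param weights Optional observation weights (default 1).
#' @param folds Number of CV folds; defaults to `config$n_folds`.
#' @return List with `n_trees` and `trace` (data frame of n_trees,
#'   deviance).
#' @export
select_n_trees <- function(features, response, config = brt_config(),
                           weights = NULL, folds = config$n_folds) {
  x <- as_feature_matrix(features)
  y <- as.numeric(response)
  check_brt_inputs(x, y, config)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  w <- weights %||% rep(1, nrow(x))
  candidates <- seq(config$tree_range[1], config$tree_range[2], config$tree_step)
  n <- nrow(x)
  fold_id <- with_seed(derive_seed(config$seed, "folds"),
                       sample(rep_len(seq_len(folds), n)))
  dev <- matrix(NA_real_, length(candidates), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                weight = w[tr])
    booster <- xgboost::xgb.train(xgb_params(config), dtr,
                                  nrounds = max(candidates), verbose = 0)
    dte <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE])
    for (i in seq_along(candidates)) {
      pr <- predict(booster, dte, iterationrange = c(1, candidates[i]))
      dev[i, f] <- brt_deviance(y[!tr], pr, w[!tr], config$loss)
    }
  }
  trace <- data.frame(n_trees = candidates, deviance = rowMeans(dev))
  list(n_trees = candidates[which.min(trace$deviance)], trace = trace)
}

#' Fit a boosted-regression-tree model
#'
#' Stagewise gradient boosting of depth-limited trees with shrinkage, row
#' subsampling at `bag_fraction` per tree and observation weights in the
#' loss. If `n_trees` is not supplied it is chosen by [select_n_trees()].
#'
#' @param features Numeric matrix or all-numeric data frame (no missing
#'   values).
#' @param response 0/1 vector for bernoulli loss, numeric for squared loss.
#' @param config A [brt_config()].
#' @param weights Optional observation weights.
#' @param n_trees Ensemble size; `NULL` to select by holdout deviance.
#' @return Object of class `reef_brt` with the fitted booster, `n_trees`,
#'   `config` and the deviance `trace` when tree count was selected.
#' @export
fit_brt <- function(features, response, config = brt_config(), weights = NULL,
                    n_trees = NULL) {
  x <- as_feature_matrix(features)
  y <- as.numeric(response)
  check_brt_inputs(x, y, config)
  w <- weights %||% rep(1, nrow(x))
  trace <- NULL
  if (is.null(n_trees)) {
    sel <- select_n_trees(x, y, config, weights = w)
    n_trees <- sel$n_trees
    trace <- sel$trace
  }
  d <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  booster <- xgboost::xgb.train(xgb_params(config), d, nrounds = n_trees,
                                verbose = 0)
  structure(list(booster = booster, n_trees = n_trees, config = config,
                 feature_names = colnames(x), trace = trace,
                 train_features = x, train_response = y, train_weights = w),
            class = "reef_brt")
}

#' @export
print.reef_brt <- function(x, ...) {
  cat(sprintf("Boosted regression trees (%s loss): %d trees, depth %d, lr %g, bag %g\n",
              x$config$loss, x$n_trees, x$config$tree_complexity,
              x$config$learning_rate, x$config$bag_fraction))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.reef_brt <- function(object, ...) {
  print(object)
  cat("\nRelative influence (%):\n")
  print(relative_influence(object), row.names = FALSE, digits = 3)
  invisible(object)
}

#' Predict from a fitted BRT
#'
#' @param object A `reef_brt`.
#' @param newdata Feature matrix/data frame; defaults to the training data.
#' @param n_trees Use only the first `n_trees` trees of the ensemble
#'   (staged prediction); defaults to the full ensemble.
#' @param ... Unused.
#' @return Probabilities in \[0, 1\] for bernoulli loss, numeric predictions
#'   otherwise.
#' @export
predict.reef_brt <- function(object, newdata = NULL, n_trees = NULL, ...) {
  x <- as_feature_matrix(newdata %||% object$train_features)
  x <- x[, object$feature_names, drop = FALSE]
  n_trees <- n_trees %||% object$n_trees
  if (n_trees > object$n_trees)
    stop("n_trees exceeds the fitted ensemble size", call. = FALSE)
  predict(object$booster, xgboost::xgb.DMatrix(x),
          iterationrange = c(1, n_trees))
}

#' Relative influence of each predictor
#'
#' Improvement-based importance of every feature, normalised to sum to 100.
#' Features never used by the ensemble get 0.
#'
#' @param model A fitted `reef_brt`.
#' @return Data frame with `variable` and `influence` (percent), sorted
#'   decreasing.
#' @export
relative_influence <- function(model) {
  stopifnot(inherits(model, "reef_brt"))
  imp <- xgboost::xgb.importance(model = model$booster)
  inf <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  if (!is.null(imp) && nrow(imp) > 0)
    inf[imp$Feature] <- imp$Gain / sum(imp$Gain) * 100
  out <- data.frame(variable = names(inf), influence = unname(inf))
  out[order(-out$influence), , drop = FALSE]
}

#' Partial dependence of the prediction on one feature
#'
#' For each grid value v spanning the observed range of `variable`, the
#' mean model prediction over the training rows with that feature set to v
#' (the marginal effect).
#'
#' @param model A fitted `reef_brt`.
#' @param variable Feature name.
#' @param grid_size Number of grid points (default 50).
#' @param quantile_grid Space the grid on quantiles of the observed values
#'   instead of evenly over their range; recommended for long-tailed
#'   predictors such as gravity, where an even grid spends most points in
#'   the sparse tail.
#' @return Data frame with `value` and `yhat`.
#' @export
partial_dependence <- function(model, variable, grid_size = 50L,
                               quantile_grid = FALSE) {
  stopifnot(inherits(model, "reef_brt"))
  if (!variable %in% model$feature_names)
    stop("unknown variable: ", variable, call. = FALSE)
  x <- model$train_features
  rng <- range(x[, variable])
  grid <- if (diff(rng) == 0) rng[1]
          else if (quantile_grid)
            unique(unname(quantile(x[, variable],
                                   seq(0.02, 0.98, length.out = grid_size))))
          else seq(rng[1], rng[2], length.out = grid_size)
  yhat <- vapply(grid, function(v) {
    xv <- x
    xv[, variable] <- v
    mean(predict(model, xv))
  }, numeric(1))
  data.frame(value = grid, yhat = yhat)
}

#' Plot a partial-dependence curve
#'
#' @param x A `reef_brt`.
#' @param variable Feature to plot.
#' @param ... Passed to [plot()].
#' @export
plot.reef_brt <- function(x, variable = x$feature_names[1], ...) {
  pd <- partial_dependence(x, variable)
  plot(pd$value, pd$yhat, type = "l", xlab = variable,
       ylab = "marginal prediction", ...)
  invisible(pd)
}
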
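#' Hyperparameters of the stochastic gradient-boosted tree classifier
#'
#' The boosted ensemble is built stage-wise from shallow weak-learner
#' trees: each tree is fit to the residuals of the running prediction on a
#' random row subsample, per-split feature subsampling decorrelates the
#' trees, and the shrinkage factor scales each tree's contribution.
#'
#' @param shrinkage Learning rate, > 0.
#' @param n_trees Maximum number of boosting rounds, >= 1 (training stops
#'   earlier once the training loss plateaus).
#' @param feature_fraction Fraction of descriptors considered at each
#'   split, in (0, 1].
#' @param row_fraction Fraction of compounds subsampled per tree, in
#'   (0, 1].
#' @param max_depth Depth limit of each weak learner (small by design).
#' @return A `gbt_hyperparameters` list.
#' @export
hyperparameters <- function(shrinkage = 0.1, n_trees = 200,
                            feature_fraction = 1.0, row_fraction = 1.0,
                            max_depth = 3) {
  if (shrinkage <= 0) abort_config("hyperparameters: shrinkage must be > 0")
  if (n_trees < 1) abort_config("hyperparameters: n_trees must be >= 1")
  if (!(feature_fraction > 0 && feature_fraction <= 1))
    abort_config("hyperparameters: feature_fraction must be in (0,1]")
  if (!(row_fraction > 0 && row_fraction <= 1))
    abort_config("hyperparameters: row_fraction must be in (0,1]")
  if (max_depth < 1) abort_config("hyperparameters: max_depth must be >= 1")
  structure(list(shrinkage = shrinkage, n_trees = as.integer(n_trees),
                 feature_fraction = feature_fraction,
                 row_fraction = row_fraction,
                 max_depth = as.integer(max_depth)),
            class = "gbt_hyperparameters")
}

#' Fit a stochastic gradient-boosted tree classifier
#'
#' Trains a boosted ensemble on a (typically under-sampled, balanced)
#' training set. Boosting stops early once the training log-loss has not
#' improved for `patience` rounds ("until no further improvement").
#' Deterministic for a fixed seed.
#'
#' @param train Labelled `descriptor_matrix` with both classes present.
#' @param hp A `gbt_hyperparameters` object.
#' @param seed Integer seed controlling row/feature subsampling.
#' @param patience Early-stopping patience in boosting rounds.
#' @return A `gbt_classifier` with the fitted booster, the training
#'   descriptor schema and the training-loss history.
#' @export
fit_gbt <- function(train, hp, seed, patience = 10) {
  if (is.null(train$labels)) abort_config("fit_gbt: training labels missing")
  counts <- class_counts(train)
  if (any(counts == 0))
    abort_config("fit_gbt: single-class training data (missing '%s')",
                 names(counts)[counts == 0][1L])
  if (!inherits(hp, "gbt_hyperparameters")) hp <- do.call(hyperparameters, hp)
  y <- as.numeric(train$labels == "toxic")
  dtrain <- xgboost::xgb.DMatrix(train$x, label = y, nthread = 1)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    eval_metric = "logloss",
    eta = hp$shrinkage,
    max_depth = hp$max_depth,
    subsample = hp$row_fraction,
    colsample_bynode = hp$feature_fraction,
    min_child_weight = 1,
    lambda = 0,
    tree_method = "hist",
    nthread = 1,
    seed = as.integer(seed %% .Machine$integer.max))
  booster <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = hp$n_trees,
    evals = list(train = dtrain),
    early_stopping_rounds = patience, verbose = 0)
  log <- attributes(booster)$evaluation_log
  structure(list(booster = booster,
                 descriptors = colnames(train$x),
                 hp = hp, seed = seed,
                 train_loss = log$train_logloss),
            class = "gbt_classifier")
}

#' Predicted toxic-class probabilities
#'
#' @param model A `gbt_classifier` (or a plain `function(matrix)` returning
#'   probabilities, accepted so simple analytic models can be explained and
#'   validated with the same tooling).
#' @param compounds A `descriptor_matrix` or numeric matrix whose columns
#'   cover the model's training descriptors.
#' @return Vector of probabilities in `[0, 1]`; a compound is classified
#'   toxic when its probability exceeds 0.5.
#' @export
predict_proba <- function(model, compounds) {
  x <- if (inherits(compounds, "descriptor_matrix")) compounds$x else compounds
  if (is.function(model)) return(model(x))
  if (!inherits(model, "gbt_classifier"))
    abort_config("predict_proba: unsupported model class")
  missing_desc <- setdiff(model$descriptors, colnames(x))
  if (length(missing_desc))
    abort_config("predict_proba: missing descriptors: %s",
                 paste(missing_desc, collapse = ", "))
  x <- x[, model$descriptors, drop = FALSE]
  stats::predict(model$booster, x)
}

#' Persist / restore a fitted classifier
#'
#' A model is stored as a pair of files: `<path>.json` carries the
#' versioned metadata (descriptor schema, hyperparameters, seed) and
#' `<path>.model` the native booster. Loading reconstructs a
#' `gbt_classifier` whose predictions are identical to the original's.
#'
#' @param model A `gbt_classifier`.
#' @param path File stem (written as `<path>.json` + `<path>.model`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the restored `gbt_classifier`.
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "gbt_classifier"))
    abort_config("save_classifier: not a gbt_classifier")
  meta <- list(format_version = 1L,
               descriptors = model$descriptors,
               hp = unclass(model$hp),
               seed = model$seed,
               train_loss = model$train_loss)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  xgboost::xgb.save(model$booster, paste0(path, ".model"))
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    abort_config("load_classifier: unsupported model format version")
  booster <- xgboost::xgb.load(paste0(path, ".model"))
  structure(list(booster = booster,
                 descriptors = meta$descriptors,
                 hp = do.call(hyperparameters, as.list(meta$hp)),
                 seed = meta$seed,
                 train_loss = meta$train_loss),
            class = "gbt_classifier")
}

#' @export
print.gbt_classifier <- function(x, ...) {
  cat(sprintf("<gbt_classifier> %d descriptors, %d boosting rounds\n",
              length(x$descriptors), length(x$train_loss)))
  invisible(x)
}
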
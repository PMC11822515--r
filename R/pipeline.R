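#' Configuration of the end-to-end workflow
#'
#' Bundles the stage configurations. All stage seeds are derived from the
#' single global seed by stable hashing of stage names, so the whole run
#' is reproducible and adding a stage does not shift the random streams of
#' the others.
#'
#' @param synthetic A [synthetic_config()] (used when no dataset is
#'   supplied to [run_pipeline()]).
#' @param breakpoint NOEC class breakpoint in mg/kg (default 100).
#' @param test_size External test-set size; default scales the published
#'   147-of-449 split to the dataset (`round(n * 147 / 449)`).
#' @param stratified_split Stratify the external split by class.
#' @param ga A [ga_config()]; its seed is overridden by the derived stage
#'   seed.
#' @param shap_background_size Background compounds for SHAP imputation.
#' @param shap_explain_max Explanations computed per model (test-set
#'   compounds, capped for tractability).
#' @param shap_replicates Imputation replicates per coalition.
#' @param t_tox_grid,t_non_grid AD threshold grids.
#' @param coverage_floor Coverage floor of the operating-point search.
#' @param y_scramble_repeats Scrambled refits in the validation stage.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            breakpoint = 100,
                            test_size = NULL,
                            stratified_split = FALSE,
                            ga = ga_config(),
                            shap_background_size = 50,
                            shap_explain_max = 40,
                            shap_replicates = 8,
                            t_tox_grid = seq(0, 1, by = 0.02),
                            t_non_grid = seq(0, -1, by = -0.02),
                            coverage_floor = 0.7,
                            y_scramble_repeats = 100,
                            seed = 1) {
  structure(list(synthetic = synthetic, breakpoint = breakpoint,
                 test_size = test_size,
                 stratified_split = stratified_split, ga = ga,
                 shap_background_size = shap_background_size,
                 shap_explain_max = shap_explain_max,
                 shap_replicates = shap_replicates,
                 t_tox_grid = t_tox_grid, t_non_grid = t_non_grid,
                 coverage_floor = coverage_floor,
                 y_scramble_repeats = y_scramble_repeats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

metric_row <- function(model, set, report) {
  data.frame(model = model, set = set,
             Sens = report$sens, Spec = report$spec, Acc = report$acc,
             BalAcc = report$balacc, MCC = report$mcc,
             TP = report$tp, TN = report$tn, FP = report$fp,
             FN = report$fn, total = report$total)
}

#' Run the full modeling workflow
#'
#' Stages: (1) generate (or accept) a labelled descriptor dataset and
#' derive classes from the NOEC records through the curation rules,
#' discarding unclassifiable intervals; (2) split off an external test
#' set; (3) evolve descriptor masks with the genetic algorithm (nested
#' Bayesian tuning, under-sampled training); (4) refit the hall-of-fame
#' individuals as Model A (specificity-oriented) and Model B
#' (sensitivity-oriented) and tabulate train/validation/test metrics;
#' (5) rank descriptors of both models by kernel-SHAP importance;
#' (6) stack the two models, scan the AD threshold grid on the test set,
#' pick the operating point, and tabulate ensemble metrics inside the AD
#' (train/validation rows are computed on the compounds shared by both
#' models' resamples); (7) Y-scramble Model A's configuration as a chance
#' baseline.
#'
#' @param config A `pipeline_config`.
#' @param dataset Optional `synthetic_dataset` (or list with elements
#'   `descriptor_matrix` and `noec_records`); generated from
#'   `config$synthetic` when omitted.
#' @param output_dir Optional directory; when given, all report tables
#'   are written there as CSV plus a `summary.json`.
#' @return A report bundle: models, metric tables, SHAP importance,
#'   threshold surface, operating point, Y-scrambling summary.
#' @export
run_pipeline <- function(config, dataset = NULL, output_dir = NULL) {
  stage <- function(name) derive_seed(config$seed, name)
  if (is.null(dataset)) {
    syn <- config$synthetic
    syn$seed <- stage("simulate")
    dataset <- generate_dataset(syn)
  }
  dm <- dataset$descriptor_matrix
  # curation: classes from NOEC records; discards dropped
  if (!is.null(dataset$noec_records)) {
    cls <- assign_classes(dataset$noec_records, config$breakpoint)
    keep <- cls != "discard"
    dm <- descriptor_matrix(dm$x[keep, , drop = FALSE],
                            labels = cls[keep],
                            compound_id = dm$compound_id[keep])
  }
  n <- nrow(dm$x)
  test_size <- config$test_size %||% round(n * 147 / 449)
  parts <- split_dataset(dm, test_size, seed = stage("split"),
                         stratified = config$stratified_split)
  modeling <- parts$modeling
  test <- parts$test

  ga_cfg <- config$ga
  ga_cfg$seed <- stage("ga")
  ga_out <- run_ga(modeling, ga_cfg)
  modeling_ga <- modeling[, ga_out$descriptors]

  hall <- ga_out$hall_of_fame
  fits <- list(A = refit_individual(hall$best_spec, modeling_ga, ga_cfg),
               B = refit_individual(hall$best_sens, modeling_ga, ga_cfg))
  lab <- function(p) ifelse(p > 0.5, "toxic", "nontoxic")
  model_rows <- list()
  for (m in names(fits)) {
    f <- fits[[m]]
    for (s in c("train", "val")) {
      p <- predict_proba(f$model, f[[s]])
      model_rows[[paste(m, s)]] <-
        metric_row(m, s, compute_metrics(count_confusion(f[[s]]$labels,
                                                         lab(p))))
    }
    p <- predict_proba(f$model, test)
    model_rows[[paste(m, "test")]] <-
      metric_row(m, "test", compute_metrics(count_confusion(test$labels,
                                                            lab(p))))
  }
  model_metrics <- do.call(rbind, model_rows)
  rownames(model_metrics) <- NULL

  # SHAP importance per model, explained on test compounds
  bg_seed <- stage("shap_background")
  importance <- list()
  explanations <- list()
  for (m in names(fits)) {
    f <- fits[[m]]
    bg_n <- min(config$shap_background_size, nrow(f$train$x))
    bg <- f$train[with_seed(bg_seed, sample.int(nrow(f$train$x), bg_n)), ]
    n_expl <- min(config$shap_explain_max, nrow(test$x))
    expl_idx <- with_seed(stage("shap_pick"), sample.int(nrow(test$x),
                                                         n_expl))
    expl <- explain_all(f$model, test[expl_idx, ], bg,
                        seed = stage(paste0("shap_", m)),
                        n_imputation_replicates = config$shap_replicates)
    explanations[[m]] <- expl
    imp <- importance_ranking(expl)
    imp$model <- m
    importance[[m]] <- imp
  }
  importance <- do.call(rbind, importance)
  rownames(importance) <- NULL

  # ensemble + applicability domain on the test set
  score_test <- ensemble_score(predict_proba(fits$A$model, test),
                               predict_proba(fits$B$model, test))
  surface <- threshold_scan(score_test, test$labels,
                            config$t_tox_grid, config$t_non_grid)
  op <- pick_operating_point(surface, config$coverage_floor)
  ensemble <- ad_ensemble(fits$A$model, fits$B$model, op$t_tox, op$t_non)
  ens_rows <- list()
  shared <- list(
    train = intersect(fits$A$train$compound_id, fits$B$train$compound_id),
    val = intersect(fits$A$val$compound_id, fits$B$val$compound_id))
  for (s in c("train", "val")) {
    ids <- shared[[s]]
    if (length(ids) < 2) next
    sub <- modeling_ga[match(ids, modeling_ga$compound_id), ]
    pr <- predict_ensemble(ensemble, sub)
    inside <- pr$verdict != "outside_AD"
    if (sum(inside) < 2 || length(unique(sub$labels[inside])) < 1) next
    r <- compute_metrics(count_confusion(sub$labels[inside],
                                         pr$verdict[inside]))
    row <- metric_row("A&B", s, r)
    row$coverage <- coverage(sum(inside), nrow(sub$x))
    ens_rows[[s]] <- row
  }
  pr_test <- predict_ensemble(ensemble, test)
  inside <- pr_test$verdict != "outside_AD"
  r <- compute_metrics(count_confusion(test$labels[inside],
                                       pr_test$verdict[inside]))
  row <- metric_row("A&B", "test", r)
  row$coverage <- coverage(sum(inside), nrow(test$x))
  ens_rows[["test"]] <- row
  ensemble_metrics <- do.call(rbind, ens_rows)
  rownames(ensemble_metrics) <- NULL

  # Y-scrambling null for Model A's configuration
  hp_a <- hall$best_spec$tuned_hp
  mask_a <- hall$best_spec$mask
  trainer <- function(train_dm, s) fit_gbt(train_dm, hp_a, seed = s)
  scrambles <- y_scramble(select_descriptors(modeling_ga, mask_a), trainer,
                          n_repeats = config$y_scramble_repeats,
                          seed = stage("y_scramble"))
  scr_mcc <- vapply(scrambles, function(r) r$mcc, numeric(1))
  yscr <- list(mean_mcc = mean(scr_mcc),
               se_mcc = stats::sd(scr_mcc) / sqrt(length(scr_mcc)),
               p95_mcc = unname(stats::quantile(scr_mcc, 0.95)),
               model_mcc = hall$best_spec$objectives[["mcc_val"]],
               n_repeats = length(scr_mcc))

  bundle <- list(config = config, dataset = dataset,
                 modeling = modeling, test = test,
                 ga = ga_out, models = fits,
                 model_metrics = model_metrics,
                 explanations = explanations,
                 shap_importance = importance,
                 threshold_surface = surface,
                 operating_point = op,
                 ensemble = ensemble,
                 ensemble_metrics = ensemble_metrics,
                 y_scrambling = yscr)
  if (!is.null(output_dir)) write_report(bundle, output_dir)
  bundle
}

#' Write the report tables of a pipeline bundle
#'
#' @param bundle Result of [run_pipeline()].
#' @param output_dir Directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  wr(bundle$model_metrics, "model_metrics.csv")
  wr(bundle$ensemble_metrics, "ensemble_metrics.csv")
  wr(bundle$shap_importance, "shap_importance.csv")
  wr(as.data.frame(bundle$threshold_surface), "threshold_surface.csv")
  wr(bundle$ga$log, "ga_log.csv")
  jsonlite::write_json(
    list(operating_point = bundle$operating_point,
         y_scrambling = bundle$y_scrambling,
         model_a_descriptors =
           bundle$ga$descriptors[bundle$ga$hall_of_fame$best_spec$mask],
         model_b_descriptors =
           bundle$ga$descriptors[bundle$ga$hall_of_fame$best_sens$mask]),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Predict new compounds with a pipeline bundle
#'
#' Produces the per-compound decision record: both models' probabilities,
#' the ensemble score, the AD verdict, and per-descriptor SHAP values
#' from each model.
#'
#' @param bundle Result of [run_pipeline()].
#' @param compounds `descriptor_matrix` covering both models' descriptors.
#' @param explain_shap Attach SHAP attributions (default `TRUE`).
#' @param seed Integer seed for the SHAP imputations.
#' @return Data frame with one row per compound; SHAP columns are named
#'   `shap_<model>_<descriptor>`.
#' @export
predict_compounds <- function(bundle, compounds, explain_shap = TRUE,
                              seed = 1) {
  decisions <- predict_ensemble(bundle$ensemble, compounds)
  if (!explain_shap || nrow(compounds$x) == 0) return(decisions)
  for (m in c("A", "B")) {
    f <- bundle$models[[m]]
    bg_n <- min(bundle$config$shap_background_size, nrow(f$train$x))
    bg <- f$train[seq_len(bg_n), ]
    expl <- explain_all(f$model, compounds, bg,
                        seed = derive_seed(seed, paste0("predict_", m)),
                        n_imputation_replicates =
                          bundle$config$shap_replicates)
    B <- t(vapply(expl, function(e) e$betas,
                  numeric(length(f$model$descriptors))))
    colnames(B) <- paste0("shap_", m, "_", f$model$descriptors)
    decisions <- cbind(decisions, as.data.frame(B))
  }
  decisions
}
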
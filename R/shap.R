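#' Impute a coalition back into descriptor space
#'
#' Maps a binary coalition vector to a full descriptor vector: positions
#' with 1 keep the explained compound's values; positions with 0 take the
#' corresponding values from one randomly drawn background compound (a
#' full-row draw per replicate), i.e. missing descriptors are stochastically
#' replaced with values from the same distribution as the dataset.
#'
#' @param x Numeric descriptor vector of the explained compound.
#' @param z_prime Binary coalition vector of the same length.
#' @param background `descriptor_matrix` (or numeric matrix) to sample
#'   replacement rows from.
#' @param seed Integer seed for the background row draw.
#' @return A numeric descriptor vector.
#' @export
impute_coalition <- function(x, z_prime, background, seed) {
  bg <- if (inherits(background, "descriptor_matrix")) background$x
        else background
  if (is.null(bg) || nrow(bg) == 0)
    abort_config("impute_coalition: background is empty")
  if (length(x) != length(z_prime) || length(x) != ncol(bg))
    abort_config("impute_coalition: lengths disagree (x %d, z %d, bg %d)",
                 length(x), length(z_prime), ncol(bg))
  z <- as.logical(z_prime)
  row <- with_seed(seed, sample.int(nrow(bg), 1))
  out <- x
  out[!z] <- bg[row, !z]
  out
}

#' Shapley kernel weight of a coalition size
#'
#' `pi(z') = (M - 1) / (choose(M, |z'|) * |z'| * (M - |z'|))`: the unique
#' weighting that attributes most weight to coalitions with only one
#' descriptor present or missing and makes the weighted least-squares
#' attributions recover Shapley values. Full and empty coalitions are
#' handled as hard equality constraints, not weighted points.
#'
#' @param M Number of descriptors in the explained model.
#' @param coalition_size Number of set bits, strictly between 0 and `M`.
#' @return A positive weight.
#' @examples
#' shap_kernel_weight(4, 1) # 0.25
#' shap_kernel_weight(4, 2) # 0.125
#' @export
shap_kernel_weight <- function(M, coalition_size) {
  if (coalition_size <= 0 || coalition_size >= M)
    abort_config(
      "shap_kernel_weight: size %d of M = %d is a constraint, not a weight",
      coalition_size, M)
  (M - 1) / (choose(M, coalition_size) * coalition_size * (M - coalition_size))
}

# all non-trivial coalitions of M players as a (2^M - 2) x M 0/1 matrix
enumerate_coalitions <- function(M) {
  grid <- as.matrix(expand.grid(rep(list(0:1), M)))
  dimnames(grid) <- NULL
  sizes <- rowSums(grid)
  grid[sizes > 0 & sizes < M, , drop = FALSE]
}

# sample coalitions from the kernel size distribution (uniform within size)
sample_coalitions <- function(M, n, seed) {
  sizes <- 1:(M - 1)
  size_w <- vapply(sizes, function(s) shap_kernel_weight(M, s) *
                     choose(M, s), numeric(1))
  with_seed(seed, {
    draw_sizes <- sample(sizes, n, replace = TRUE, prob = size_w)
    t(vapply(draw_sizes, function(s) {
      z <- numeric(M)
      z[sample.int(M, s)] <- 1
      z
    }, numeric(M)))
  })
}

#' Kernel SHAP explanation of one prediction
#'
#' Fits the explanatory additive model `g(z') = beta0 + sum_i beta_i z'_i`
#' over coalitions by kernel-weighted least squares, subject to the two
#' hard constraints `g(empty) = beta0` (the mean background prediction)
#' and `g(full) = f(x)` — so the attributions satisfy local accuracy
#' exactly: `beta0 + sum(beta) = f(x)`.
#'
#' All `2^M` coalitions are enumerated when `M <= 15` (models in this
#' workflow use few descriptors); larger `M` falls back to sampling
#' coalitions from the kernel's size distribution, and `M > 25` without an
#' explicit sampling budget is an error. The value of each coalition is
#' the model output averaged over `n_imputation_replicates` stochastic
#' background imputations.
#'
#' @param model A `gbt_classifier` or `function(matrix) -> probabilities`.
#' @param x Named numeric descriptor vector of the compound to explain
#'   (must cover the model's descriptors).
#' @param background `descriptor_matrix` or matrix of background compounds
#'   (training set by default in the pipeline).
#' @param n_imputation_replicates Background draws per coalition
#'   (default 16; a single background row makes imputation deterministic).
#' @param seed Integer seed.
#' @param n_coalition_samples Sampling budget when `M > 15`.
#' @param compound_id Identifier stored in the explanation.
#' @return An object of class `shap_explanation`: `beta0`, named `betas`,
#'   `fx` (the explained prediction) and `compound_id`.
#' @export
explain <- function(model, x, background, n_imputation_replicates = 16,
                    seed = 1, n_coalition_samples = NULL,
                    compound_id = NA_character_) {
  bg <- if (inherits(background, "descriptor_matrix")) background$x
        else background
  if (is.null(bg) || nrow(bg) == 0)
    abort_config("explain: background is empty")
  desc <- if (inherits(model, "gbt_classifier")) model$descriptors
          else colnames(bg) %||% names(x) %||% paste0("d", seq_along(x))
  if (!is.null(names(x))) {
    missing_desc <- setdiff(desc, names(x))
    if (length(missing_desc))
      abort_config("explain: x lacks descriptors: %s",
                   paste(missing_desc, collapse = ", "))
    x <- x[desc]
  }
  if (!is.null(colnames(bg))) bg <- bg[, desc, drop = FALSE]
  M <- length(desc)
  f <- function(mat) {
    colnames(mat) <- desc
    predict_proba(model, mat)
  }
  fx <- f(matrix(x, nrow = 1))
  beta0 <- mean(f(bg))
  if (M == 1) {
    betas <- fx - beta0
    names(betas) <- desc
    return(structure(list(beta0 = beta0, betas = betas, fx = fx,
                          compound_id = compound_id),
                     class = "shap_explanation"))
  }
  if (M <= 15 && is.null(n_coalition_samples)) {
    Z <- enumerate_coalitions(M)
    w <- vapply(rowSums(Z), function(s) shap_kernel_weight(M, s),
                numeric(1))
  } else {
    if (M > 25 && is.null(n_coalition_samples))
      abort_config(
        "explain: M = %d needs an explicit n_coalition_samples budget", M)
    n_s <- n_coalition_samples %||% 4096L
    Z <- sample_coalitions(M, n_s, derive_seed(seed, "coalitions"))
    w <- rep(1, nrow(Z)) # sampled proportionally to the kernel
  }
  # coalition values: model output averaged over stochastic imputations
  reps <- max(1L, as.integer(n_imputation_replicates))
  rows <- matrix(0, nrow(Z) * reps, M)
  for (k in seq_len(nrow(Z))) {
    for (r in seq_len(reps)) {
      rows[(k - 1) * reps + r, ] <-
        impute_coalition(x, Z[k, ], bg,
                         seed = derive_seed(seed, sprintf("imp_%d_%d", k, r)))
    }
  }
  v <- colMeans(matrix(f(rows), nrow = reps))
  # constrained weighted least squares: eliminate beta_M through the
  # efficiency constraint sum(beta) = fx - beta0
  e <- fx - beta0
  y <- v - beta0 - Z[, M] * e
  X <- Z[, -M, drop = FALSE] - Z[, M]
  fit <- stats::lm.wfit(X, y, w)
  betas_head <- fit$coefficients
  betas_head[is.na(betas_head)] <- 0
  betas <- c(betas_head, e - sum(betas_head))
  names(betas) <- desc
  structure(list(beta0 = beta0, betas = betas, fx = fx,
                 compound_id = compound_id),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %s: f(x) = %.4f, baseline = %.4f\n",
              x$compound_id, x$fx, x$beta0))
  print(round(sort(x$betas, decreasing = TRUE), 4))
  invisible(x)
}

#' Explain several compounds of a descriptor matrix
#'
#' @param model A `gbt_classifier` or prediction function.
#' @param compounds `descriptor_matrix` of compounds to explain.
#' @param background Background `descriptor_matrix`.
#' @param ... Passed to [explain()].
#' @param seed Integer seed (one sub-seed per compound).
#' @return List of `shap_explanation`s.
#' @export
explain_all <- function(model, compounds, background, seed = 1, ...) {
  desc <- if (inherits(model, "gbt_classifier")) model$descriptors
          else descriptor_names(compounds)
  lapply(seq_len(nrow(compounds$x)), function(i) {
    xi <- compounds$x[i, desc]
    explain(model, xi, background,
            seed = derive_seed(seed, paste0("expl_", i)),
            compound_id = compounds$compound_id[i], ...)
  })
}

#' Rank descriptors by SHAP importance
#'
#' Orders descriptors by decreasing mean absolute SHAP value over the
#' explained compounds; exact ties are broken alphabetically.
#'
#' @param explanations List of `shap_explanation`s with a common
#'   descriptor set.
#' @return Data frame with `rank`, `descriptor`, `importance`
#'   (mean |beta|).
#' @export
importance_ranking <- function(explanations) {
  if (!length(explanations))
    abort_config("importance_ranking: no explanations supplied")
  B <- t(vapply(explanations, function(e) e$betas,
                numeric(length(explanations[[1L]]$betas))))
  imp <- colMeans(abs(B))
  ord <- order(-imp, names(imp))
  data.frame(rank = seq_along(imp), descriptor = names(imp)[ord],
             importance = unname(imp[ord]))
}
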
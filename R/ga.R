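#' Configuration of the descriptor-selection genetic algorithm
#'
#' Each individual is a binary mask over the descriptors. Per generation,
#' 50% of individuals participate in crossover, 10% in mutation and 40%
#' are left unchanged, in a mutually exclusive manner; training/validation
#' sets are resampled every generation; each evaluated individual gets its
#' own Bayesian hyperparameter search; survivors are chosen by NSGA-II
#' over five objectives (MCC and Brier score on train and validation, plus
#' a sparsity penalty).
#'
#' @param population_size Number of individuals (default 50).
#' @param n_generations Generation budget (default 20; the search has no
#'   natural convergence criterion).
#' @param crossover_share,mutation_share,unchanged_share Operator shares;
#'   must sum to 1.
#' @param crossover_swap_prob Per-gene swap probability in uniform
#'   crossover (default 0.5).
#' @param mutation_bitflip_prob Per-bit flip probability; default
#'   `NULL` means `1 / n_descriptors` at apply time.
#' @param target_bits Expected set bits of initial masks (default 10).
#' @param bo_iterations Bayesian-search budget per individual (default 32).
#' @param cv_folds Folds of the nested cross-validation (default 5).
#' @param train_fraction Train share of the per-generation resample.
#' @param space A [search_space()] for the hyperparameter search.
#' @param seed Integer seed; the whole run is deterministic under it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, n_generations = 20,
                      crossover_share = 0.5, mutation_share = 0.1,
                      unchanged_share = 0.4, crossover_swap_prob = 0.5,
                      mutation_bitflip_prob = NULL, target_bits = 10,
                      bo_iterations = 32, cv_folds = 5,
                      train_fraction = 0.8, space = search_space(),
                      seed = 1) {
  if (abs(crossover_share + mutation_share + unchanged_share - 1) > 1e-9)
    abort_config("ga_config: operator shares must sum to 1")
  if (population_size < 4)
    abort_config("ga_config: population_size must be >= 4")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_share = crossover_share,
                 mutation_share = mutation_share,
                 unchanged_share = unchanged_share,
                 crossover_swap_prob = crossover_swap_prob,
                 mutation_bitflip_prob = mutation_bitflip_prob,
                 target_bits = target_bits,
                 bo_iterations = as.integer(bo_iterations),
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 space = space, seed = as.integer(seed)),
            class = "ga_config")
}

new_individual <- function(mask) {
  structure(list(mask = as.logical(mask), tuned_hp = NULL,
                 objectives = NULL, train_report = NULL, val_report = NULL,
                 split_seed = NULL, gen_seed = NULL),
            class = "ga_individual")
}

repair_mask <- function(mask, seed) {
  if (!any(mask)) mask[with_seed(seed, sample.int(length(mask), 1))] <- TRUE
  mask
}

#' Initialize a GA population of descriptor masks
#'
#' Seeded random masks with expected density `target_bits / n_descriptors`
#' (capped at 0.5); empty masks are repaired by setting one random bit.
#'
#' @param n_descriptors Mask length.
#' @param config A `ga_config`.
#' @return List of `ga_individual`s of length `population_size`.
#' @export
init_population <- function(n_descriptors, config) {
  p <- min(config$target_bits / n_descriptors, 0.5)
  lapply(seq_len(config$population_size), function(i) {
    s <- derive_seed(config$seed, paste0("init_", i))
    mask <- with_seed(s, stats::runif(n_descriptors) < p)
    new_individual(repair_mask(mask, derive_seed(s, "repair")))
  })
}

#' Apply genetic operators to a population
#'
#' A seeded partition assigns `round(crossover_share * n)` individuals to
#' crossover (taken in pairs; with an odd count the extra individual is
#' moved to the unchanged group), `round(mutation_share * n)` to mutation,
#' and the remainder stays unchanged. Crossover swaps each gene between
#' the pair with probability `crossover_swap_prob`; mutation flips each
#' bit with probability `mutation_bitflip_prob`. Masks emptied by an
#' operator are repaired with one random set bit. Modified individuals
#' have their objectives invalidated (flagged via the `changed` attribute).
#'
#' @param population List of `ga_individual`s (length >= 2).
#' @param config A `ga_config`.
#' @param seed Integer seed for this application.
#' @return A list of `ga_individual`s of the same length.
#' @export
apply_operators <- function(population, config, seed) {
  n <- length(population)
  if (n < 2) abort_config("apply_operators: population size must be >= 2")
  n_desc <- length(population[[1L]]$mask)
  flip_p <- config$mutation_bitflip_prob %||% (1 / n_desc)
  n_cross <- round(config$crossover_share * n)
  n_mut <- round(config$mutation_share * n)
  with_seed(seed, {
    ord <- sample.int(n)
    cross_idx <- ord[seq_len(n_cross)]
    if (length(cross_idx) %% 2 == 1) {
      # odd crossover group: largest even subset crosses, one moves over
      cross_idx <- cross_idx[-length(cross_idx)]
    }
    mut_idx <- ord[seq_len(n_mut) + n_cross]
    out <- population
    changed <- rep(FALSE, n)
    if (length(cross_idx) >= 2) {
      pairs <- matrix(cross_idx, nrow = 2)
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        swap <- stats::runif(n_desc) < config$crossover_swap_prob
        mi <- population[[i]]$mask
        mj <- population[[j]]$mask
        ni <- ifelse(swap, mj, mi)
        nj <- ifelse(swap, mi, mj)
        out[[i]] <- new_individual(repair_mask(ni, stats::runif(1) * 1e9))
        out[[j]] <- new_individual(repair_mask(nj, stats::runif(1) * 1e9))
        changed[c(i, j)] <- TRUE
      }
    }
    for (i in mut_idx) {
      flips <- stats::runif(n_desc) < flip_p
      m <- xor(population[[i]]$mask, flips)
      out[[i]] <- new_individual(repair_mask(m, stats::runif(1) * 1e9))
      changed[i] <- TRUE
    }
    attr(out, "changed") <- changed
    out
  })
}

#' Sparsity penalty on the number of selected descriptors
#'
#' `P(d) = 1 / (1 + d)`: a monotonically decreasing score that applies
#' evolutionary pressure toward smaller descriptor sets (it is maximized,
#' like the MCC objectives).
#'
#' @param n_selected Number of set bits in the mask, >= 1.
#' @return Penalty value in (0, 1].
#' @export
penalty <- function(n_selected) {
  if (any(n_selected < 1))
    abort_config("penalty: empty descriptor sets are forbidden")
  1 / (1 + n_selected)
}

#' Evaluate one GA individual
#'
#' The full inner pipeline of the wrapper search: restrict the modeling
#' set to the masked descriptors; draw a fresh train/validation resample
#' under the generation seed (degenerate draws with a class missing from
#' either part are redrawn, at most 10 times); under-sample the training
#' part; run the budgeted Bayesian hyperparameter search with the
#' cross-validated Brier objective; fit the final model on the balanced
#' training set; record MCC and Brier score on the (imbalanced) training
#' and validation sets plus the sparsity penalty.
#'
#' @param ind A `ga_individual`.
#' @param modeling_set Labelled `descriptor_matrix`.
#' @param generation_seed Seed of this evaluation event.
#' @param config A `ga_config`.
#' @return The individual with `objectives` (named 5-vector: `mcc_train`,
#'   `mcc_val`, `bs_train`, `bs_val`, `penalty`), `tuned_hp`, metric
#'   reports and the seeds needed to refit it exactly.
#' @export
evaluate_individual <- function(ind, modeling_set, generation_seed, config) {
  dm <- select_descriptors(modeling_set, ind$mask)
  split_seed <- derive_seed(generation_seed, "resample")
  parts <- resample_train_val(dm, config$train_fraction, seed = split_seed)
  att <- 0
  while (any(class_counts(parts$train) == 0) ||
         any(class_counts(parts$val) == 0)) {
    att <- att + 1
    if (att > 10)
      abort_config("evaluate_individual: no class-complete resample found")
    parts <- resample_train_val(dm, config$train_fraction,
                                seed = split_seed + att)
  }
  bal <- under_sample(parts$train, seed = derive_seed(generation_seed,
                                                      "balance"))
  bo <- bayes_optimize(
    function(hp) cv_objective(parts$train, rep(TRUE, ncol(parts$train$x)),
                              do.call(hyperparameters, hp),
                              k = config$cv_folds,
                              seed = derive_seed(generation_seed, "cv")),
    space = config$space, n_iterations = config$bo_iterations,
    seed = derive_seed(generation_seed, "bayes"))
  hp <- do.call(hyperparameters, bo$best_hp)
  model <- fit_gbt(bal, hp, seed = derive_seed(generation_seed, "fit"))
  p_train <- predict_proba(model, parts$train)
  p_val <- predict_proba(model, parts$val)
  lab <- function(p) ifelse(p > 0.5, "toxic", "nontoxic")
  train_report <- compute_metrics(count_confusion(parts$train$labels,
                                                  lab(p_train)))
  val_report <- compute_metrics(count_confusion(parts$val$labels,
                                                lab(p_val)))
  ind$tuned_hp <- hp
  ind$objectives <- c(mcc_train = train_report$mcc,
                      mcc_val = val_report$mcc,
                      bs_train = brier_score(parts$train$labels, p_train),
                      bs_val = brier_score(parts$val$labels, p_val),
                      penalty = penalty(sum(ind$mask)))
  ind$train_report <- train_report
  ind$val_report <- val_report
  ind$split_seed <- split_seed + att
  ind$gen_seed <- generation_seed
  ind
}

#' Refit the model of an evaluated individual
#'
#' Reproduces the exact resample, under-sample and fit of the evaluation,
#' returning the fitted classifier and the train/validation parts.
#'
#' @param ind An evaluated `ga_individual`.
#' @param modeling_set The same labelled `descriptor_matrix`.
#' @param config The same `ga_config`.
#' @return List with `model`, `train`, `val`.
#' @export
refit_individual <- function(ind, modeling_set, config) {
  if (is.null(ind$objectives))
    abort_config("refit_individual: individual was never evaluated")
  dm <- select_descriptors(modeling_set, ind$mask)
  parts <- resample_train_val(dm, config$train_fraction,
                              seed = ind$split_seed)
  bal <- under_sample(parts$train, seed = derive_seed(ind$gen_seed,
                                                      "balance"))
  model <- fit_gbt(bal, ind$tuned_hp,
                   seed = derive_seed(ind$gen_seed, "fit"))
  list(model = model, train = parts$train, val = parts$val)
}

# canonical minimization matrix for NSGA-II
objective_matrix <- function(population) {
  obj <- t(vapply(population, function(ind) {
    if (is.null(ind$objectives))
      abort_config("nsga2_select: unevaluated individual in population")
    ind$objectives
  }, numeric(5)))
  cbind(-obj[, "mcc_train"], -obj[, "mcc_val"],
        obj[, "bs_train"], obj[, "bs_val"], -obj[, "penalty"])
}

nds_fronts <- function(M) {
  n <- nrow(M)
  dominated_by <- integer(n)
  dominates_list <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(M[i, ] <= M[j, ]) && any(M[i, ] < M[j, ])) {
        dominates_list[[i]] <- c(dominates_list[[i]], j)
      } else if (all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dominated_by == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates_list[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

crowding_distance <- function(M) {
  n <- nrow(M)
  d <- numeric(n)
  if (n <= 2) return(rep(Inf, n))
  for (k in seq_len(ncol(M))) {
    ord <- order(M[, k])
    rng <- M[ord[n], k] - M[ord[1L], k]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (M[ord[i + 1], k] - M[ord[i - 1], k]) / rng
      }
    }
  }
  d
}

#' NSGA-II environmental selection
#'
#' Fast non-dominated sorting on the canonical minimization vector
#' (-MCC_train, -MCC_val, BS_train, BS_val, -penalty), filling the
#' survivor set front by front; the last, partially admitted front is
#' ordered by crowding distance (boundary points get infinite distance) to
#' preserve objective-space diversity.
#'
#' @param population List of evaluated `ga_individual`s.
#' @param k Number of survivors.
#' @return List of exactly `k` individuals.
#' @export
nsga2_select <- function(population, k) {
  if (k > length(population))
    abort_config("nsga2_select: k = %d exceeds population size %d",
                 k, length(population))
  M <- objective_matrix(population)
  fronts <- nds_fronts(M)
  chosen <- integer(0)
  for (front in fronts) {
    if (length(chosen) + length(front) <= k) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowding_distance(M[front, , drop = FALSE])
      take <- front[order(-cd)][seq_len(k - length(chosen))]
      chosen <- c(chosen, take)
    }
    if (length(chosen) >= k) break
  }
  population[chosen]
}

update_hall <- function(hall, ind) {
  better <- function(a, b, key) {
    if (is.null(b)) return(TRUE)
    ka <- a$val_report[[key]]; kb <- b$val_report[[key]]
    if (is.na(ka)) return(FALSE)
    if (is.na(kb)) return(TRUE)
    ka > kb || (ka == kb && a$objectives[["mcc_val"]] >
                  b$objectives[["mcc_val"]])
  }
  if (better(ind, hall$best_spec, "spec")) hall$best_spec <- ind
  if (better(ind, hall$best_sens, "sens")) hall$best_sens <- ind
  hall
}

#' Run the descriptor-selection genetic algorithm
#'
#' Evolves descriptor masks for `n_generations`: operators are applied,
#' modified individuals are re-tuned and evaluated under a fresh
#' generation seed (the train/validation resample changes every
#' generation), and NSGA-II selects the next population from parents plus
#' modified offspring. A hall of fame tracks the best individual by
#' validation specificity and by validation sensitivity (MCC_val breaking
#' ties), mirroring the selection of a specificity-oriented and a
#' sensitivity-oriented model.
#'
#' @param modeling_set Labelled `descriptor_matrix`.
#' @param config A `ga_config`.
#' @param drop_constant Remove zero-variance descriptors first (the only
#'   pre-filter applied).
#' @return List with `population` (final evaluated individuals),
#'   `hall_of_fame` (`best_spec`, `best_sens`), `log` (one row per
#'   evaluation: generation, individual, mask size, five objectives) and
#'   `descriptors` (the descriptor names masks index into).
#' @export
run_ga <- function(modeling_set, config, drop_constant = TRUE) {
  if (drop_constant) {
    keep <- apply(modeling_set$x, 2, function(v) stats::var(v) > 0)
    modeling_set <- modeling_set[, which(keep)]
  }
  n_desc <- ncol(modeling_set$x)
  log_rows <- list()
  hall <- list(best_spec = NULL, best_sens = NULL)
  note <- function(gen, i, ind) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      generation = gen, individual = i, mask_size = sum(ind$mask),
      t(ind$objectives))
  }
  gen_seed <- derive_seed(config$seed, "gen_0")
  pop <- init_population(n_desc, config)
  for (i in seq_along(pop)) {
    pop[[i]] <- evaluate_individual(pop[[i]], modeling_set,
                                    derive_seed(gen_seed, paste0("ind_", i)),
                                    config)
    hall <- update_hall(hall, pop[[i]])
    note(0L, i, pop[[i]])
  }
  if (config$n_generations > 0) {
    for (g in seq_len(config$n_generations)) {
      gen_seed <- derive_seed(config$seed, paste0("gen_", g))
      offspring <- apply_operators(pop, config,
                                   seed = derive_seed(config$seed,
                                                      paste0("op_", g)))
      changed <- attr(offspring, "changed")
      pool <- pop
      for (i in which(changed)) {
        ev <- evaluate_individual(offspring[[i]], modeling_set,
                                  derive_seed(gen_seed, paste0("ind_", i)),
                                  config)
        hall <- update_hall(hall, ev)
        note(g, i, ev)
        pool[[length(pool) + 1L]] <- ev
      }
      pop <- nsga2_select(pool, config$population_size)
    }
  }
  list(population = pop, hall_of_fame = hall,
       log = do.call(rbind, log_rows),
       descriptors = descriptor_names(modeling_set))
}
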
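test_that("initial populations are seeded, non-empty, and near the target density", {
  cfg <- ga_config(population_size = 50, seed = 3, target_bits = 10)
  pop <- init_population(300, cfg)
  expect_length(pop, 50)
  sizes <- vapply(pop, function(i) sum(i$mask), numeric(1))
  expect_true(all(sizes >= 1))
  expect_lt(abs(mean(sizes) - 10), 2) # Monte-Carlo mean over 50 draws
  pop2 <- init_population(300, cfg)
  expect_identical(lapply(pop, `[[`, "mask"), lapply(pop2, `[[`, "mask"))
})

test_that("operator shares partition the population 50/10/40 with odd-pair repair", {
  cfg <- ga_config(population_size = 10, seed = 1)
  pop <- init_population(40, cfg)
  out <- apply_operators(pop, cfg, seed = 2)
  changed <- attr(out, "changed")
  # round(0.5*10)=5 assigned to crossover -> 4 actually cross (2 pairs),
  # 1 reassigned to unchanged; round(0.1*10)=1 mutated; 5 untouched total
  expect_equal(sum(changed), 5)
  expect_length(out, 10)
  expect_true(all(vapply(out, function(i) any(i$mask), logical(1))))
  # unchanged individuals keep their masks
  for (i in which(!changed))
    expect_identical(out[[i]]$mask, pop[[i]]$mask)
})

test_that("degenerate operator probabilities behave as identities and complements", {
  cfg0 <- ga_config(population_size = 8, crossover_swap_prob = 0, seed = 5)
  pop <- init_population(30, cfg0)
  out <- apply_operators(pop, cfg0, seed = 1)
  # zero swap probability: crossover leaves masks unchanged
  for (i in seq_along(pop)) expect_identical(out[[i]]$mask, pop[[i]]$mask)
  cfg1 <- ga_config(population_size = 8, crossover_share = 0,
                    mutation_share = 1, unchanged_share = 0,
                    mutation_bitflip_prob = 1, seed = 5)
  out1 <- apply_operators(pop, cfg1, seed = 1)
  for (i in seq_along(pop)) {
    m <- out1[[i]]$mask
    comp <- !pop[[i]]$mask
    if (any(comp)) expect_identical(m, comp)
    else expect_equal(sum(m), 1) # full mask flips to empty, then repaired
  }
})

test_that("the sparsity penalty is the specified decreasing function", {
  expect_equal(penalty(1), 0.5)
  expect_equal(penalty(4), 0.2)
  d <- 1:2199
  expect_true(all(diff(penalty(d)) < 0))
  expect_error(penalty(0), "empty")
})

test_that("evaluation fills a finite five-objective vector and is refittable", {
  ds <- small_benchmark()
  cfg <- ga_config(population_size = 4, bo_iterations = 4, cv_folds = 3,
                   seed = 2)
  ind <- wormtox:::new_individual(
    descriptor_names(ds$descriptor_matrix) %in% ds$truth)
  ev <- evaluate_individual(ind, ds$descriptor_matrix, 777, cfg)
  expect_named(ev$objectives,
               c("mcc_train", "mcc_val", "bs_train", "bs_val", "penalty"))
  expect_true(all(is.finite(ev$objectives)))
  expect_s3_class(ev$tuned_hp, "gbt_hyperparameters")
  # the informative mask clearly beats chance on validation
  expect_gt(ev$objectives[["mcc_val"]], 0.2)
  # refitting reproduces the evaluation's validation metrics exactly
  refit <- refit_individual(ev, ds$descriptor_matrix, cfg)
  p <- predict_proba(refit$model, refit$val)
  r <- compute_metrics(count_confusion(refit$val$labels,
                                       ifelse(p > 0.5, "toxic",
                                              "nontoxic")))
  expect_equal(r$mcc, ev$objectives[["mcc_val"]])
  # a pure-noise mask stays in the null band
  noise_mask <- grepl("^noise", descriptor_names(ds$descriptor_matrix)) &
    cumsum(grepl("^noise", descriptor_names(ds$descriptor_matrix))) <= 4
  evn <- evaluate_individual(wormtox:::new_individual(noise_mask),
                             ds$descriptor_matrix, 778, cfg)
  expect_lt(evn$objectives[["mcc_val"]], 0.45)
})

test_that("NSGA-II selection matches a brute-force domination oracle", {
  for (s in 1:25) {
    withr::local_seed(s)
    n <- sample(4:15, 1)
    raw <- matrix(round(rnorm(n * 5), 2), n, 5)
    k <- sample(2:(n - 1), 1)
    pop <- population_from_objectives(raw)
    sel <- nsga2_select(pop, k)
    key <- function(ind) paste(ind$objectives, collapse = ",")
    got <- sort(match(vapply(sel, key, character(1)),
                      vapply(pop, key, character(1))))
    # canonical minimization: negate the maximized objectives
    M <- cbind(-raw[, 1], -raw[, 2], raw[, 3], raw[, 4], -raw[, 5])
    expect_identical(got, brute_nsga_select(M, k))
  }
})

test_that("domination extremes select as the definition requires", {
  # one individual dominating on every objective is always kept
  raw <- rbind(c(0.9, 0.9, 0.01, 0.01, 0.5),
               c(0.1, 0.1, 0.30, 0.30, 0.1),
               c(0.2, 0.1, 0.20, 0.30, 0.1),
               c(0.1, 0.3, 0.30, 0.10, 0.2))
  pop <- population_from_objectives(raw)
  sel <- nsga2_select(pop, 1)
  expect_equal(sel[[1]]$objectives[["mcc_train"]], 0.9)
  # identical objective vectors are mutually non-dominated: one front
  same <- population_from_objectives(matrix(0.5, 6, 5))
  fronts <- wormtox:::nds_fronts(wormtox:::objective_matrix(same))
  expect_length(fronts, 1)
  expect_error(nsga2_select(pop, 10), "exceeds")
})

test_that("a zero-generation run returns the evaluated initial population", {
  ds <- small_benchmark()
  cfg <- ga_config(population_size = 4, n_generations = 0,
                   bo_iterations = 2, cv_folds = 3, target_bits = 5,
                   seed = 4)
  out <- run_ga(ds$descriptor_matrix, cfg)
  expect_length(out$population, 4)
  expect_true(all(vapply(out$population,
                         function(i) !is.null(i$objectives), logical(1))))
  expect_equal(sort(unique(out$log$generation)), 0)
  expect_false(is.null(out$hall_of_fame$best_spec))
  expect_false(is.null(out$hall_of_fame$best_sens))
})

test_that("GA runs are reproducible and constants are pre-filtered", {
  ds <- small_benchmark()
  cfg <- ga_config(population_size = 6, n_generations = 2,
                   bo_iterations = 2, cv_folds = 3, target_bits = 5,
                   seed = 8)
  a <- run_ga(ds$descriptor_matrix, cfg)
  b <- run_ga(ds$descriptor_matrix, cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$hall_of_fame$best_spec$mask,
                   b$hall_of_fame$best_spec$mask)
  expect_false(any(grepl("^const", a$descriptors)))
})

test_that("the penalty drives mask shrinkage on signal-free data", {
  ds <- generate_dataset(synthetic_config(n_compounds = 120,
                                          n_descriptors = 30,
                                          n_informative = 0,
                                          n_nonlinear = 0,
                                          correlated_block_size = 3,
                                          n_constant = 0,
                                          toxic_fraction = 0.5, seed = 21))
  cfg <- ga_config(population_size = 8, n_generations = 3,
                   bo_iterations = 2, cv_folds = 3, target_bits = 10,
                   seed = 10)
  out <- run_ga(ds$descriptor_matrix, cfg)
  init_median <- median(subset(out$log, generation == 0)$mask_size)
  final_median <- median(vapply(out$population,
                                function(i) sum(i$mask), numeric(1)))
  expect_lte(final_median, init_median)
})
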
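test_that("the generator is deterministic under config and seed", {
  cfg <- synthetic_config(n_compounds = 80, n_descriptors = 25,
                          n_informative = 3, n_nonlinear = 1,
                          correlated_block_size = 3, n_constant = 2,
                          seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$descriptor_matrix$x, b$descriptor_matrix$x)
  expect_identical(a$descriptor_matrix$labels, b$descriptor_matrix$labels)
  expect_identical(a$noec_text, b$noec_text)
  c <- generate_dataset(synthetic_config(n_compounds = 80,
                                         n_descriptors = 25,
                                         n_informative = 3,
                                         n_nonlinear = 1,
                                         correlated_block_size = 3,
                                         n_constant = 2, seed = 6))
  expect_false(identical(a$descriptor_matrix$x, c$descriptor_matrix$x))
})

test_that("default dataset mirrors the curated pesticide set's scale", {
  ds <- generate_dataset(synthetic_config(seed = 1))
  expect_equal(dim(ds$descriptor_matrix), c(449, 300))
  counts <- class_counts(ds$descriptor_matrix)
  # toxic count within binomial sampling error of 355/449
  expect_lt(abs(counts[["toxic"]] - 355), 3 * sqrt(449 * (355 / 449) * (94 / 449)))
})

test_that("planted informative descriptors separate the classes, noise does not", {
  ds <- generate_dataset(synthetic_config(seed = 2))
  dm <- ds$descriptor_matrix
  sig_auc <- vapply(ds$truth, function(d)
    univariate_auc(dm$x[, d], dm$labels), numeric(1))
  noise_cols <- grep("^noise", descriptor_names(dm), value = TRUE)
  noise_auc <- vapply(noise_cols, function(d)
    univariate_auc(dm$x[, d], dm$labels), numeric(1))
  expect_gt(min(sig_auc), 0.55)
  expect_gt(mean(sig_auc), 0.6)
  expect_gt(mean(sig_auc), mean(noise_auc))
  # constant columns have zero variance
  const_cols <- grep("^const", descriptor_names(dm), value = TRUE)
  expect_true(all(apply(dm$x[, const_cols], 2, var) == 0))
})

test_that("with no informative descriptors every univariate AUC is near chance", {
  ds <- generate_dataset(synthetic_config(n_compounds = 300,
                                          n_descriptors = 30,
                                          n_informative = 0,
                                          n_nonlinear = 0,
                                          correlated_block_size = 4,
                                          n_constant = 0,
                                          toxic_fraction = 0.5, seed = 3))
  aucs <- vapply(descriptor_names(ds$descriptor_matrix), function(d)
    univariate_auc(ds$descriptor_matrix$x[, d], ds$descriptor_matrix$labels),
    numeric(1))
  expect_lt(max(aucs), 0.62)   # folded null AUCs stay near 0.5
  expect_lt(mean(aucs), 0.56)
  expect_length(ds$truth, 0)
})

test_that("curation of generated NOEC records recovers the generating class", {
  for (seed in 1:3) {
    ds <- generate_dataset(synthetic_config(n_compounds = 300,
                                            n_descriptors = 20,
                                            n_informative = 2,
                                            n_nonlinear = 0,
                                            correlated_block_size = 2,
                                            n_constant = 1,
                                            interval_fraction = 0.5,
                                            seed = seed))
    cls <- assign_classes(ds$noec_records)
    keep <- cls != "discard"
    expect_true(all(cls[keep] ==
                      as.character(ds$descriptor_matrix$labels)[keep]))
    expect_gt(sum(!keep), 0) # discard dialects do occur
  }
})

test_that("all NOEC dialects, including the discard forms, are emitted", {
  ds <- generate_dataset(synthetic_config(n_compounds = 600,
                                          n_descriptors = 10,
                                          n_informative = 1,
                                          n_nonlinear = 0,
                                          correlated_block_size = 2,
                                          n_constant = 1,
                                          interval_fraction = 0.5,
                                          seed = 11))
  txt <- ds$noec_text
  expect_true(any(grepl("^[0-9]", txt)))          # real values
  expect_true(any(txt == ">100"))
  expect_true(any(txt %in% c(">0-10", "<100")))
  expect_true(any(txt %in% c(">10-100", "<100-inf")))
})

test_that("invalid generator configurations are rejected by name", {
  expect_error(synthetic_config(toxic_fraction = 1.2), "toxic_fraction")
  expect_error(synthetic_config(n_descriptors = 5, n_informative = 4,
                                n_constant = 3), "n_informative")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_informative = 2, n_nonlinear = 5),
               "n_nonlinear")
})

test_that("a dataset round-trips through its CSV serialization", {
  ds <- generate_dataset(synthetic_config(n_compounds = 40,
                                          n_descriptors = 12,
                                          n_informative = 2,
                                          n_nonlinear = 0,
                                          correlated_block_size = 2,
                                          n_constant = 1, seed = 4))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_descriptor_csv(file.path(dir, "descriptors.csv"))
  expect_equal(back$x, ds$descriptor_matrix$x, tolerance = 1e-12)
  expect_identical(back$labels, ds$descriptor_matrix$labels)
  expect_identical(back$compound_id, ds$descriptor_matrix$compound_id)
})
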
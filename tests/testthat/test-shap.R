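test_that("the Shapley kernel has its closed form and symmetry", {
  expect_equal(shap_kernel_weight(4, 1), 0.25)
  expect_equal(shap_kernel_weight(4, 2), 0.125)
  for (M in c(3, 6, 11)) {
    for (s in 1:(M - 1)) {
      expect_equal(shap_kernel_weight(M, s), shap_kernel_weight(M, M - s))
      expect_gt(shap_kernel_weight(M, s), 0)
    }
    # singleton and near-complete coalitions carry the most weight
    expect_gte(shap_kernel_weight(M, 1),
               max(vapply(1:(M - 1), shap_kernel_weight, numeric(1),
                          M = M)))
  }
  expect_error(shap_kernel_weight(4, 0), "constraint")
  expect_error(shap_kernel_weight(4, 4), "constraint")
})

test_that("coalition imputation keeps present values and draws full background rows", {
  bg <- matrix(1:12, 3, 4, dimnames = list(NULL, paste0("d", 1:4)))
  x <- c(d1 = 100, d2 = 200, d3 = 300, d4 = 400)
  expect_equal(impute_coalition(x, c(1, 1, 1, 1), bg, seed = 1), x)
  z0 <- impute_coalition(x, c(0, 0, 0, 0), bg, seed = 1)
  expect_true(any(apply(bg, 1, function(r) all(r == z0))))
  # a single background row makes imputation deterministic
  bg1 <- bg[1, , drop = FALSE]
  for (s in 1:5)
    expect_equal(impute_coalition(x, c(1, 0, 1, 0), bg1, seed = s),
                 c(d1 = 100, d2 = 4, d3 = 300, d4 = 10))
  expect_error(impute_coalition(x, c(1, 0, 1, 0), bg[0, , drop = FALSE],
                                seed = 1), "empty")
})

test_that("kernel SHAP equals exhaustive-enumeration Shapley values", {
  withr::local_seed(11)
  for (M in c(3, 5, 8)) {
    x <- matrix(rnorm(60 * M), 60, M, dimnames = list(NULL, paste0("d", 1:M)))
    labs <- ifelse(x[, 1] - 0.8 * x[, 2] + rnorm(60, 0, 0.4) > 0,
                   "toxic", "nontoxic")
    dm <- descriptor_matrix(x, labels = labs)
    m <- fit_gbt(dm, hyperparameters(0.4, 25, 1, 1, 3), seed = M)
    f <- function(mat) {
      colnames(mat) <- paste0("d", 1:M)
      predict_proba(m, mat)
    }
    xq <- x[7, ]
    bg <- x[40, , drop = FALSE] # deterministic single-row background
    phi <- exact_shapley(f, xq, bg[1, ])
    ex <- explain(m, xq, bg, n_imputation_replicates = 1, seed = 3)
    expect_lt(max(abs(ex$betas - phi)), 1e-6)
  }
})

test_that("every explanation satisfies local accuracy exactly", {
  withr::local_seed(12)
  dm <- toy_separable_dm(n_per_class = 15, n_noise = 3)
  m <- fit_gbt(dm, hyperparameters(0.3, 40, 0.8, 0.8, 3), seed = 2)
  bg <- dm[1:10, ]
  for (i in c(1, 8, 20)) {
    ex <- explain(m, dm$x[i, ], bg, n_imputation_replicates = 4, seed = i)
    expect_equal(ex$beta0 + sum(ex$betas), unname(ex$fx), tolerance = 1e-10)
  }
})

test_that("additive models split attributions by the background means", {
  withr::local_seed(13)
  f <- function(mat) mat[, 1] + mat[, 2]
  bg <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  x <- c(a = 1.2, b = -0.5)
  ex <- explain(f, x, bg, n_imputation_replicates = 512, seed = 4)
  expect_equal(unname(ex$betas), unname(x - colMeans(bg)),
               tolerance = 0.15)
})

test_that("symmetric duplicate descriptors share their attribution", {
  f <- function(mat) mat[, 1] + mat[, 2] # identical roles
  bg <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  x <- c(a = 2, b = 2)
  ex <- explain(f, x, bg, n_imputation_replicates = 1, seed = 1)
  expect_equal(ex$betas[["a"]], ex$betas[["b"]], tolerance = 1e-10)
})

test_that("descriptors the model never uses receive zero attribution", {
  dm <- toy_separable_dm(n_per_class = 15, n_noise = 2, gap = 3)
  # depth-1 single tree can only split on the separating descriptor
  m <- fit_gbt(dm, hyperparameters(1, 1, 1, 1, max_depth = 1), seed = 1)
  bg <- dm$x[3, , drop = FALSE]
  ex <- explain(m, dm$x[1, ], bg, n_imputation_replicates = 1, seed = 2)
  expect_equal(unname(abs(ex$betas[c("nz1", "nz2")])), c(0, 0),
               tolerance = 1e-10)
})

test_that("sampled coalitions approximate the enumerated attributions", {
  withr::local_seed(14)
  M <- 6
  x <- matrix(rnorm(50 * M), 50, M, dimnames = list(NULL, paste0("d", 1:M)))
  dm <- descriptor_matrix(x, labels = ifelse(x[, 1] > 0, "toxic",
                                             "nontoxic"))
  m <- fit_gbt(dm, hyperparameters(0.4, 20, 1, 1, 2), seed = 1)
  bg <- x[2, , drop = FALSE]
  full <- explain(m, x[5, ], bg, n_imputation_replicates = 1, seed = 5)
  samp <- explain(m, x[5, ], bg, n_imputation_replicates = 1, seed = 5,
                  n_coalition_samples = 3000)
  expect_lt(max(abs(full$betas - samp$betas)), 0.05)
})

test_that("very high dimension without a sampling budget is refused", {
  f <- function(mat) rowSums(mat)
  bg <- matrix(0, 2, 30, dimnames = list(NULL, paste0("d", 1:30)))
  x <- setNames(rep(1, 30), paste0("d", 1:30))
  expect_error(explain(f, x, bg, seed = 1), "n_coalition_samples")
})

test_that("importance ranking orders by mean absolute attribution with alphabetic ties", {
  mk <- function(betas) structure(list(beta0 = 0, betas = betas, fx = 0,
                                       compound_id = "c"),
                                  class = "shap_explanation")
  ranks <- importance_ranking(list(
    mk(c(b = 0.5, a = -0.1, zz = 0)),
    mk(c(b = -0.3, a = 0.1, zz = 0))))
  expect_equal(ranks$descriptor, c("b", "a", "zz"))
  expect_equal(ranks$rank, 1:3)
  # all-zero attribution ranks last; exact ties break alphabetically
  tied <- importance_ranking(list(mk(c(q = 0.2, b = 0.2, a = 0.2))))
  expect_equal(tied$descriptor, c("a", "b", "q"))
})
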
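test_that("the NOEC interval grammar parses into the intended bounds", {
  r <- parse_noec("50", "a")
  expect_equal(r$kind, "real")
  expect_equal(r$value, 50)
  r <- parse_noec(">0-10", "b")
  expect_equal(c(r$lower, r$upper), c(0, 10))
  expect_false(r$lower_closed)
  expect_true(r$upper_closed)
  r <- parse_noec("<100", "c")
  expect_equal(c(r$lower, r$upper), c(0, 100))
  expect_false(r$upper_closed)
  r <- parse_noec(">100", "d")
  expect_equal(c(r$lower, r$upper), c(100, Inf))
  r <- parse_noec("<100-inf", "e")
  expect_equal(c(r$lower, r$upper), c(0, Inf))
  expect_error(parse_noec("100-200"), "dialect")
  expect_error(noec_record("x", lower = 10, upper = 5), "lower < upper")
  expect_error(noec_record("x", value = -1), ">= 0")
})

test_that("class assignment straddles the breakpoint exactly as specified", {
  # the seven conversion rules at the 100 mg/kg breakpoint
  expect_equal(assign_class(noec_record("r1", value = 50)), "toxic")
  expect_equal(assign_class(noec_record("r2", value = 100)), "nontoxic")
  expect_equal(assign_class(parse_noec(">0-10")), "toxic")
  expect_equal(assign_class(parse_noec(">10-100")), "discard")
  expect_equal(assign_class(parse_noec(">100")), "nontoxic")
  expect_equal(assign_class(parse_noec("<100")), "toxic")
  expect_equal(assign_class(parse_noec("<100-inf")), "discard")
  # boundary behaviour: a real at the breakpoint is nontoxic, just below toxic
  expect_equal(assign_class(noec_record("b", value = 99.999)), "toxic")
  # explicit interval records (JSON-style construction) agree
  expect_equal(assign_class(noec_record("j", lower = 10, upper = 100,
                                        upper_closed = TRUE)), "discard")
  expect_equal(assign_class(noec_record("j2", lower = 100, upper = Inf)),
               "nontoxic")
  # every record receives exactly one of the three labels
  recs <- list(noec_record("x", value = 3), parse_noec(">0-10"),
               parse_noec(">10-100"), parse_noec(">100"),
               parse_noec("<100"), parse_noec("<100-inf"))
  expect_true(all(assign_classes(recs) %in%
                    c("toxic", "nontoxic", "discard")))
  # the breakpoint generalizes
  expect_equal(assign_class(noec_record("g", value = 50), breakpoint = 10),
               "nontoxic")
})

test_that("the external split is an exact, seeded, disjoint partition", {
  ds <- small_benchmark()
  dm <- ds$descriptor_matrix
  sp <- split_dataset(dm, 66, seed = 3)
  expect_equal(nrow(sp$modeling$x), 134)
  expect_equal(nrow(sp$test$x), 66)
  expect_length(intersect(sp$modeling$compound_id, sp$test$compound_id), 0)
  expect_setequal(c(sp$modeling$compound_id, sp$test$compound_id),
                  dm$compound_id)
  sp2 <- split_dataset(dm, 66, seed = 3)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  # degenerate split keeps everything in the modeling set
  sp0 <- split_dataset(dm, 0, seed = 1)
  expect_equal(nrow(sp0$test$x), 0)
  expect_equal(nrow(sp0$modeling$x), nrow(dm$x))
  expect_error(split_dataset(dm, nrow(dm$x), seed = 1), "test_size")
  # stratified split preserves class proportions exactly up to rounding
  st <- split_dataset(dm, 50, seed = 4, stratified = TRUE)
  expect_equal(sum(st$test$labels == "toxic"),
               round(50 * sum(dm$labels == "toxic") / nrow(dm$x)))
})

test_that("train/validation resampling has the specified sizes and varies by seed", {
  ds <- generate_dataset(synthetic_config(n_compounds = 302,
                                          n_descriptors = 10,
                                          n_informative = 1,
                                          n_nonlinear = 0,
                                          correlated_block_size = 2,
                                          n_constant = 1, seed = 9))
  dm <- ds$descriptor_matrix
  tv <- resample_train_val(dm, 0.8, seed = 1)
  expect_equal(nrow(tv$train$x), 241)
  expect_equal(nrow(tv$val$x), 61)
  expect_length(intersect(tv$train$compound_id, tv$val$compound_id), 0)
  # resampling with incremented seeds changes the membership
  tv2 <- resample_train_val(dm, 0.8, seed = 2)
  expect_false(identical(sort(tv$train$compound_id),
                         sort(tv2$train$compound_id)))
  # an even split on a tiny set
  tiny <- dm[1:4, ]
  half <- resample_train_val(tiny, 0.5, seed = 1)
  expect_equal(nrow(half$train$x), 2)
  expect_error(resample_train_val(dm, 1, seed = 1), "train_fraction")
  # partition property over many seeds
  for (s in 1:20) {
    p <- resample_train_val(dm, 0.8, seed = s)
    expect_setequal(c(p$train$compound_id, p$val$compound_id),
                    dm$compound_id)
  }
})

test_that("under-sampling balances to the minority count and keeps all minority rows", {
  mk <- function(n_tox, n_non, seed = 1) {
    x <- matrix(rnorm((n_tox + n_non) * 3), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    descriptor_matrix(x, labels = rep(c("toxic", "nontoxic"),
                                      c(n_tox, n_non)))
  }
  bal <- under_sample(mk(100, 20), seed = 1)
  expect_equal(unname(class_counts(bal)), c(20, 20))
  # all minority compounds retained
  dm <- mk(100, 20)
  expect_true(all(dm$compound_id[dm$labels == "nontoxic"] %in%
                    bal$compound_id))
  # already balanced input is unchanged
  dm2 <- mk(30, 30)
  expect_identical(under_sample(dm2, seed = 5)$compound_id,
                   dm2$compound_id)
  # single-class input cannot be balanced
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(under_sample(descriptor_matrix(x, labels = rep("toxic", 5)),
                            seed = 1), "cannot balance")
  # modeling pool at the published scale: 242 toxic + 60 nontoxic,
  # resampled 80/20 then balanced at the post-split minority size
  pool <- mk(242, 60, seed = 2)
  tv <- resample_train_val(pool, 0.8, seed = 3)
  expect_equal(nrow(tv$train$x), 241)
  minority <- min(class_counts(tv$train))
  balp <- under_sample(tv$train, seed = 4)
  expect_equal(unname(class_counts(balp)), c(minority, minority))
  # 1:1 ratio across random seeds (property)
  for (s in 1:10) {
    b <- under_sample(mk(57, 13), seed = s)
    cc <- class_counts(b)
    expect_equal(cc[["toxic"]], cc[["nontoxic"]])
  }
})

test_that("fingerprint Jaccard similarity counts set bits correctly", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  # bits {1,2} vs {1,3}: intersection 1, union 3
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_error(jaccard_similarity(c(0, 0), c(0, 0)), "undefined")
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "lengths")
})

test_that("structural identifiers validate only with >2 coinciding fingerprints", {
  fp <- c(1, 0, 1, 1)
  expect_true(identifiers_concordant(list(fp, fp, fp)))
  expect_false(identifiers_concordant(list(fp, fp)))        # too few
  expect_false(identifiers_concordant(list(fp, fp, c(1, 1, 1, 1))))
})
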
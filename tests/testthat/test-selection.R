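# small labeled feature table generator
sim_table <- function(n1 = 20, n2 = 20, p = 10, effect = 0, seed = 1,
                      informative = integer(0)) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  lab <- rep(c("aMCI", "NC"), c(n1, n2))
  for (j in informative) x[lab == "aMCI", j] <- x[lab == "aMCI", j] + effect
  tab <- data.frame(subject_id = sprintf("s%02d", seq_len(n1 + n2)),
                    label = lab, side = "left", x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[-(1:3)] <- sprintf("f%02d", seq_len(p))
  tab
}

test_that("mean imputation replaces non-finite entries and is idempotent", {
  tab <- sim_table(3, 3, 3, seed = 2)
  tab$f01 <- c(1, NaN, 3, NA, 5, Inf)
  out <- impute_abnormal(tab)
  expect_equal(out$f01, c(1, 3, 3, 3, 5, 3))
  expect_equal(impute_abnormal(out)$f01, out$f01)
  # training means reused for test rows
  te <- tab[1:2, ]; te$f01 <- c(NA, NA)
  te2 <- impute_abnormal(te, means = attr(out, "impute_means"))
  expect_equal(te2$f01, c(3, 3))
  # all-missing feature dropped with a warning
  tab$f02 <- NA_real_
  expect_warning(out2 <- impute_abnormal(tab), "dropped")
  expect_false("f02" %in% names(out2))
})

test_that("stratified split uses per-class rounding and is deterministic", {
  tab <- sim_table(42, 44, 4, seed = 3)
  sp <- split_train_test(tab, 0.7, seed = 10)
  expect_equal(nrow(sp$train), 60)  # 29 + 31
  expect_equal(nrow(sp$test), 26)   # 13 + 13
  expect_equal(sum(sp$train$label == "aMCI"), 29)
  expect_equal(sum(sp$train$label == "NC"), 31)
  expect_equal(sum(sp$test$label == "aMCI"), 13)
  expect_equal(sum(sp$test$label == "NC"), 13)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- split_train_test(tab, 0.7, seed = 10)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_train_test(tab, 1.0), "fraction")
})

test_that("standardization uses training statistics only", {
  tab <- sim_table(10, 10, 3, seed = 4)
  sp <- split_train_test(tab, 0.7, seed = 1)
  st <- standardize(sp$train, sp$test)
  for (f in feature_columns(st$train)) {
    expect_equal(mean(st$train[[f]]), 0, tolerance = 1e-12)
    expect_equal(sd(st$train[[f]]), 1, tolerance = 1e-12)
  }
  # test columns transformed with the train scaler, not their own
  f <- feature_columns(st$test)[1]
  mu <- st$scaler$mean[st$scaler$feature == f]
  sd_ <- st$scaler$sd[st$scaler$feature == f]
  expect_equal(st$test[[f]], (sp$test[[f]] - mu) / sd_, tolerance = 1e-12)
  # constant column dropped
  tab$f01 <- 5
  sp <- split_train_test(tab, 0.7, seed = 1)
  st2 <- standardize(sp$train, sp$test)
  expect_true("f01" %in% st2$dropped)
  expect_false("f01" %in% names(st2$train))
})

test_that("univariate filter keeps separated features and drops at alpha 0-like levels", {
  tab <- sim_table(30, 30, 5, effect = 3, informative = 1, seed = 5)
  uni <- univariate_filter(tab, 0.05)
  expect_true(uni$survives[uni$feature == "f01"])
  # essentially no survivors at a vanishing alpha
  uni0 <- univariate_filter(tab, 1e-12)
  expect_false(any(uni0$survives[uni0$feature != "f01"]))
  # intersection rule is at most as permissive as union
  uni_i <- univariate_filter(tab, 0.05, integration = "intersection")
  expect_true(all(uni_i$survives <= uni$survives))
})

test_that("union-rule null retention is consistent with alpha = 0.05", {
  hits <- 0; total <- 0
  for (r in 1:10) {
    tab <- sim_table(21, 22, 40, seed = 100 + r)
    uni <- univariate_filter(tab, 0.05)
    hits <- hits + sum(uni$survives); total <- total + nrow(uni)
  }
  rate <- hits / total
  # union of two correlated 5% tests: expect roughly 5-10%
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.14)
})

test_that("correlation filter removes exactly one of a perfectly correlated pair", {
  tab <- sim_table(15, 15, 4, seed = 6)
  tab$f02 <- 2 * tab$f01
  cf <- correlation_filter(tab, sprintf("f%02d", 1:4), rho = 0.9, seed = 3)
  expect_equal(length(cf$survivors), 3)
  expect_equal(sum(c("f01", "f02") %in% cf$survivors), 1)
  expect_equal(nrow(cf$removed), 1)
  expect_equal(abs(cf$removed$rho), 1)
  # determinism given seed
  cf2 <- correlation_filter(tab, sprintf("f%02d", 1:4), rho = 0.9, seed = 3)
  expect_identical(cf$survivors, cf2$survivors)
  # independent columns all survive
  cf3 <- correlation_filter(tab, sprintf("f%02d", c(1, 3, 4)), rho = 0.9, seed = 3)
  expect_equal(length(cf3$survivors), 3)
})

test_that("LASSO selection shrinks to zero at large lambda and recovers signal", {
  tab <- sim_table(30, 30, 20, effect = 2, informative = 1:3, seed = 7)
  st <- standardize(tab)
  las <- lasso_select(st$train, feature_columns(st$train), seed = 11)
  expect_false(las$empty)
  expect_true(all(c("f01", "f02", "f03") %in% las$selected$feature))
  # full-shrinkage limit: the largest lambda on the path has no nonzero coef
  expect_equal(sum(las$path[1, ] != 0), 0)
  # support size along the path is non-increasing in lambda (grid artifacts
  # tolerated at <= 1 feature)
  nnz <- rowSums(las$path != 0)  # rows ordered from largest lambda down
  expect_true(all(diff(nnz) >= -1))
  expect_gt(utils::tail(nnz, 1), utils::head(nnz, 1))
})

test_that("the cascade yields nested survivor sets and no test-row leakage", {
  tab <- sim_table(30, 32, 30, effect = 1.5, informative = 1:4, seed = 8)
  res <- run_selection(tab, selection_config(), seed = 5)
  expect_true(all(res$survivors$correlation %in% res$survivors$univariate))
  expect_true(all(res$survivors$lasso %in% res$survivors$correlation))
  expect_true(length(res$selected) >= 1)
  # perturbing test rows does not change the fitted cascade
  tab2 <- tab
  sp <- split_train_test(tab2, 0.7, seed = 5)
  test_ids <- sp$test$subject_id
  for (f in feature_columns(tab2))
    tab2[[f]][tab2$subject_id %in% test_ids] <-
      tab2[[f]][tab2$subject_id %in% test_ids] + 100
  res2 <- run_selection(tab2, selection_config(), seed = 5)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$stages, res2$stages)
})
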
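make_scored_table <- function(n1 = 20, n2 = 20, effect = 2, seed = 1, p = 3) {
  set.seed(seed)
  lab <- rep(c("aMCI", "NC"), c(n1, n2))
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  x[lab == "aMCI", 1] <- x[lab == "aMCI", 1] + effect
  tab <- data.frame(subject_id = sprintf("s%02d", seq_len(n1 + n2)),
                    label = lab, side = "left", x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[-(1:3)] <- sprintf("f%02d", seq_len(p))
  tab
}

test_that("logistic fit is deterministic and monotone in a 1D predictor", {
  tab <- make_scored_table(15, 15, effect = 1.5, seed = 2, p = 1)
  m1 <- fit_logistic(tab, "f01")
  m2 <- fit_logistic(tab, "f01")
  expect_identical(m1$coefficients, m2$coefficients)
  pr <- predict_logistic(m1, tab)
  o <- order(tab$f01)
  expect_true(all(diff(pr$probability[o]) * sign(m1$coefficients[["f01"]]) >= 0))
  # probability 0.5 threshold == score 0 threshold
  expect_identical(pr$probability >= 0.5, pr$score >= 0)
})

test_that("perfect separation falls back to a flagged ridge fit", {
  tab <- data.frame(subject_id = sprintf("s%d", 1:10),
                    label = rep(c("aMCI", "NC"), each = 5), side = "left",
                    f01 = c(1:5, 11:15) / 5, stringsAsFactors = FALSE)
  # glmnet warns about the deliberately tiny classes; irrelevant here
  m <- suppressWarnings(fit_logistic(tab, "f01"))
  expect_true(m$ridge)
  expect_true(all(is.finite(unlist(m$coefficients))))
})

test_that("evaluation metrics respect their identities", {
  set.seed(3)
  p <- runif(40)
  lab <- rep(c("aMCI", "NC"), 20)
  ev <- evaluate(p, lab)
  m <- ev$metrics
  expect_equal(m[["sensitivity"]], m[["recall"]])
  expect_equal(m[["precision"]], m[["PPV"]])
  expect_equal(m[["F_score"]],
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  expect_equal(sum(ev$confusion), 40)
  expect_true(all(m[is.finite(m)] >= 0 & m[is.finite(m)] <= 1))
  # complementing probabilities while swapping the positive role mirrors the
  # confusion matrix: AUC invariant, sensitivity <-> specificity, PPV <-> NPV
  p2 <- 1 - p  # no p is exactly 0.5, so thresholding mirrors exactly
  ev2 <- evaluate(p2, lab, positive = "NC")
  m2 <- ev2$metrics
  expect_equal(m2[["AUC"]], m[["AUC"]], tolerance = 1e-12)
  expect_equal(m2[["sensitivity"]], m[["specificity"]])
  expect_equal(m2[["specificity"]], m[["sensitivity"]])
  expect_equal(m2[["PPV"]], m[["NPV"]])
  expect_equal(m2[["NPV"]], m[["PPV"]])
  expect_equal(unname(ev2$confusion[c("TP", "FP", "TN", "FN")]),
               unname(ev$confusion[c("TN", "FN", "TP", "FP")]))
})

test_that("printed precision/recall reproduce the printed F-scores", {
  expect_equal(f_score(0.69, 0.69), 0.69, tolerance = 1e-12)
  # the paper's left-model F of 0.58 was computed from unrounded P/R; from
  # the printed two-decimal values the identity gives 0.586
  expect_equal(f_score(0.64, 0.54), 0.58, tolerance = 0.011)
  # perfect predictions
  ev <- evaluate(c(1, 1, 0, 0), c("aMCI", "aMCI", "NC", "NC"))
  expect_equal(unname(ev$metrics[c("AUC", "sensitivity", "specificity",
                                   "F_score")]), rep(1, 4))
})

test_that("rank AUC equals the trapezoid area under the ROC step curve", {
  set.seed(4)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    s <- sample(round(rnorm(n), 1))  # ties on purpose
    lab <- sample(rep(c("aMCI", "NC"), length.out = n))
    a1 <- auc_rank(s, lab)
    rc <- roc_points(s, lab)
    a2 <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- rnorm(50)
  lab <- sample(rep(c("aMCI", "NC"), 25))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = s, levels = c("NC", "aMCI"), quiet = TRUE,
    direction = "<")))
  expect_equal(auc_rank(s, lab), ref, tolerance = 1e-12)
})

test_that("score plot is ordered and permutation-invariant", {
  s <- c(0.3, -1, 2, 0.1)
  lab <- c("aMCI", "NC", "aMCI", "NC")
  sp1 <- score_plot(s, lab)
  perm <- c(3, 1, 4, 2)
  sp2 <- score_plot(s[perm], lab[perm])
  expect_identical(sp1, sp2)
  expect_true(!is.unsorted(sp1$score))
})

test_that("repeated splits report stable aggregates and an AUC gap on signal", {
  tab <- make_scored_table(21, 22, effect = 2, seed = 6)
  rep1 <- run_repetitions(tab, "f01", n_repetitions = 5, seed = 9)
  rep2 <- run_repetitions(tab, "f01", n_repetitions = 5, seed = 9)
  expect_equal(rep1$per_repetition, rep2$per_repetition)
  expect_equal(nrow(rep1$per_repetition), 5)
  expect_gt(rep1$mean[["test_AUC"]], 0.7)
  expect_gte(rep1$auc_gap, -0.1)  # train roughly >= test on average
  # null features: test AUC near chance
  null_tab <- make_scored_table(21, 22, effect = 0, seed = 7)
  rep0 <- run_repetitions(null_tab, "f01", n_repetitions = 10, seed = 11)
  expect_gt(rep0$mean[["test_AUC"]], 0.3)
  expect_lt(rep0$mean[["test_AUC"]], 0.7)
})
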
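# Positive class: case-insensitive alphabetically first label (aMCI before
# NC), compared in C order so the convention is locale-independent.
.positive_class <- function(labels) {
  u <- unique(as.character(labels))
  u[order(toupper(u), method = "radix")][1]
}

#' Fit the logistic-regression classifier
#'
#' Unpenalized maximum-likelihood logistic regression on the selected
#' features (selection is done beforehand). If the fit is perfectly
#' separated, a small ridge penalty is used as a stabilizer and flagged.
#'
#' @param train standardized training feature table.
#' @param features character vector of predictor names.
#' @return List of class `hr_logistic`: `intercept`, `coefficients` (named),
#'   `features`, `positive`, `ridge` (TRUE if the stabilizer was used).
#' @export
fit_logistic <- function(train, features) {
  stopifnot(length(features) >= 1, all(features %in% names(train)))
  pos <- .positive_class(train$label)
  y <- as.integer(train$label == pos)
  x <- as.matrix(train[features])
  df <- data.frame(y = y, x, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    # ridge stabilizer against (quasi-)separation (glmnet needs >= 2 columns;
    # a zero column is added for 1-predictor fits and contributes nothing)
    xg <- if (ncol(x) == 1) cbind(x, `.pad` = 0) else x
    rf <- glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    b <- as.matrix(stats::coef(rf))[, 1]
    intercept <- b[1]
    co <- b[1 + seq_len(ncol(x))]
  } else {
    b <- stats::coef(fit)
    intercept <- b[1]
    co <- b[-1]
    names(co) <- features
  }
  structure(list(intercept = unname(intercept),
                 coefficients = stats::setNames(unname(co), features),
                 features = features, positive = pos, ridge = sep),
            class = "hr_logistic")
}

#' Radiomics score and class probability
#'
#' The radiomics score is the linear predictor; the probability of the
#' positive class is its sigmoid. Thresholding the probability at 0.5 is
#' identical to thresholding the score at 0.
#'
#' @param model an `hr_logistic`.
#' @param table feature table with the model's predictors.
#' @return Data.frame with `score`, `probability`, `predicted` label.
#' @export
predict_logistic <- function(model, table) {
  x <- as.matrix(table[model$features])
  score <- model$intercept + drop(x %*% model$coefficients)
  p <- 1 / (1 + exp(-score))
  labs <- sort(unique(table$label))
  neg <- setdiff(labs, model$positive)
  if (length(neg) == 0) neg <- "other"
  data.frame(score = score, probability = p,
             predicted = ifelse(p >= 0.5, model$positive, neg[1]),
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve by the rank (Mann-Whitney) method
#'
#' Uses midranks for ties, so `auc` equals U / (n1 * n0) exactly.
#'
#' @param scores numeric classifier scores or probabilities.
#' @param labels class labels.
#' @param positive positive class (default: alphabetically first).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels, positive = .positive_class(labels)) {
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier evaluation battery
#'
#' Confusion matrix at the probability threshold and the eight headline
#' metrics: AUC, specificity, sensitivity, PPV, NPV, precision, recall,
#' F-score. Sensitivity = recall = TP/(TP+FN); precision = PPV =
#' TP/(TP+FP); F = 2PR/(P+R). Degenerate ratios (empty denominator) are
#' `NA`.
#'
#' @param probabilities predicted positive-class probabilities in [0, 1].
#' @param labels true class labels (both classes present for AUC).
#' @param positive the positive (case) class.
#' @param threshold decision threshold on the probability (default 0.5).
#' @return List of class `hr_eval`: `confusion` (TP/FP/TN/FN) and `metrics`
#'   (named vector of the eight metrics).
#' @export
evaluate <- function(probabilities, labels,
                     positive = .positive_class(labels), threshold = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  y <- labels == positive
  pred <- probabilities >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f <- f_score(ppv, sens)
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = c(AUC = auc_rank(probabilities, labels, positive),
                specificity = spec, sensitivity = sens,
                PPV = ppv, NPV = npv, precision = ppv, recall = sens,
                F_score = f)
  ), class = "hr_eval")
}

#' F-score from precision and recall
#'
#' @param precision,recall values in [0, 1].
#' @return 2PR/(P+R), or `NA` if undefined.
#' @export
f_score <- function(precision, recall) {
  if (!is.finite(precision) || !is.finite(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' ROC curve points
#'
#' Standard step curve over score thresholds (each distinct score, plus the
#' extremes), returned as (FPR, TPR) pairs ordered from (0,0) to (1,1).
#' The trapezoid area of this curve equals [auc_rank()].
#'
#' @inheritParams auc_rank
#' @return Data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = .positive_class(labels)) {
  y <- labels == positive
  stopifnot(any(y), any(!y))
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y); n0 <- sum(!y)
  tpr <- vapply(ths, function(t) sum(scores[y] >= t) / n1, 0)
  fpr <- vapply(ths, function(t) sum(scores[!y] >= t) / n0, 0)
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' Radiomics-score plot data
#'
#' Subjects ordered by score with their group, for a waterfall-style plot
#' with a horizontal reference at score 0 (probability 0.5): positive-class
#' subjects above the line and negative-class below are correct calls.
#'
#' @param scores radiomics scores (linear predictor).
#' @param labels class labels.
#' @return Data.frame with `rank`, `score`, `label`, ordered by score.
#' @export
score_plot <- function(scores, labels) {
  o <- order(scores)
  data.frame(rank = seq_along(scores), score = scores[o], label = labels[o],
             stringsAsFactors = FALSE)
}

#' Repeated-split training and evaluation
#'
#' Repeats the paper-style protocol: stratified 0.7/0.3 shuffle-split, fit
#' on the training rows (standardized with training statistics), evaluate
#' on train and test. Reports per-repetition metrics and mean +/- SD, plus
#' the train-test AUC gap as an overfitting indicator.
#'
#' @param table feature table for one side.
#' @param features selected feature names.
#' @param n_repetitions number of repetitions (default 10).
#' @param seed base seed; repetition r uses seed + r.
#' @param train_fraction training fraction (default 0.7).
#' @return List of class `hr_model_report`: `per_repetition` (data.frame of
#'   train/test metrics), `mean`, `sd`, `auc_gap`, `repetitions`, and the
#'   last repetition's `model`, `roc_test`, `score_plot_test`.
#' @export
run_repetitions <- function(table, features, n_repetitions = 10L, seed = 1L,
                            train_fraction = 0.7) {
  stopifnot(n_repetitions >= 1, length(features) >= 1)
  per <- list()
  model <- NULL; roc_te <- NULL; sp_te <- NULL
  for (r in seq_len(n_repetitions)) {
    sp <- split_train_test(table, train_fraction, seed = seed + r)
    tr <- impute_abnormal(sp$train)
    te <- impute_abnormal(sp$test, means = attr(tr, "impute_means"))
    st <- standardize(tr, te)
    feats <- intersect(features, names(st$train))
    model <- fit_logistic(st$train, feats)
    pr_tr <- predict_logistic(model, st$train)
    pr_te <- predict_logistic(model, st$test)
    ev_tr <- evaluate(pr_tr$probability, st$train$label, model$positive)
    ev_te <- evaluate(pr_te$probability, st$test$label, model$positive)
    per[[r]] <- data.frame(repetition = r,
                           t(c(stats::setNames(ev_tr$metrics,
                                               paste0("train_", names(ev_tr$metrics))),
                               stats::setNames(ev_te$metrics,
                                               paste0("test_", names(ev_te$metrics))))))
    if (r == n_repetitions) {
      roc_te <- roc_points(pr_te$score, st$test$label, model$positive)
      sp_te <- score_plot(pr_te$score, st$test$label)
    }
  }
  per <- do.call(rbind, per)
  mcols <- setdiff(names(per), "repetition")
  structure(list(
    per_repetition = per,
    mean = colMeans(per[mcols], na.rm = TRUE),
    sd = vapply(per[mcols], stats::sd, 0, na.rm = TRUE),
    auc_gap = mean(per$train_AUC - per$test_AUC, na.rm = TRUE),
    repetitions = n_repetitions,
    model = model, roc_test = roc_te, score_plot_test = sp_te
  ), class = "hr_model_report")
}
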
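#' Selection-stage configuration
#'
#' @param train_fraction fraction of subjects in the training split (0.7).
#' @param alpha univariate significance level (0.05).
#' @param rho correlation-filter threshold on |Spearman rho| (0.9).
#' @param integration how the t-test and rank-test survivor sets are
#'   combined: `"union"` (default) or `"intersection"`.
#' @param n_folds cross-validation folds for the LASSO stage (10).
#' @param n_lambda length of the log-spaced penalty grid.
#' @param fdr apply Benjamini-Hochberg correction at the univariate stage.
#' @return A list of class `hr_selection_config`.
#' @export
selection_config <- function(train_fraction = 0.7, alpha = 0.05, rho = 0.9,
                             integration = c("union", "intersection"),
                             n_folds = 10L, n_lambda = 100L, fdr = FALSE) {
  integration <- match.arg(integration)
  stopifnot(train_fraction > 0, train_fraction < 1, alpha > 0, alpha < 1,
            rho > 0, rho <= 1, n_folds >= 2)
  structure(list(train_fraction = train_fraction, alpha = alpha, rho = rho,
                 integration = integration, n_folds = as.integer(n_folds),
                 n_lambda = as.integer(n_lambda), fdr = fdr),
            class = "hr_selection_config")
}

#' Replace non-finite feature values by the feature mean
#'
#' Each `NA`/`NaN`/`Inf` entry is replaced by the mean of that feature's
#' finite entries (computed on the rows supplied, so call it on training
#' rows and reuse the means for test rows to avoid leakage). Features with
#' no finite entries are dropped with a warning.
#'
#' @param table feature table.
#' @param means optional named vector of imputation means (from a previous
#'   call, for applying training means to test rows).
#' @return The imputed table, with attribute `impute_means`.
#' @export
impute_abnormal <- function(table, means = NULL) {
  fc <- feature_columns(table)
  used <- numeric(0)
  drop <- character(0)
  for (f in fc) {
    x <- table[[f]]
    bad <- !is.finite(x)
    m <- if (!is.null(means)) {
      if (f %in% names(means)) means[[f]] else NA_real_
    } else mean(x[!bad])
    if (!is.finite(m)) {
      drop <- c(drop, f)
      next
    }
    if (any(bad)) table[[f]][bad] <- m
    used[f] <- m
  }
  if (length(drop)) {
    warning("dropped ", length(drop), " feature(s) with no finite values")
    table <- table[, setdiff(names(table), drop), drop = FALSE]
  }
  attr(table, "impute_means") <- used
  table
}

#' Stratified train/test split
#'
#' Random split preserving class proportions: per class,
#' `round(fraction * n_class)` subjects go to training. Deterministic given
#' the seed; train and test are disjoint and exhaustive.
#'
#' @param table feature table (one row per subject for the side modeled).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(table, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  labs <- table$label
  if (any(table(labs) < 2)) stop("each class needs >= 2 subjects")
  set.seed(seed)
  tr <- logical(nrow(table))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    n_tr <- round(fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    tr[sample(idx, n_tr)] <- TRUE
  }
  list(train = table[tr, , drop = FALSE], test = table[!tr, , drop = FALSE])
}

#' Z-score standardization fitted on the training rows
#'
#' Centers and scales every feature column by the training mean and SD;
#' the test rows are transformed with the training scaler (no leakage).
#' Zero-variance training features are dropped from both sets.
#'
#' @param train,test feature tables.
#' @return List `train`, `test`, `scaler` (data.frame of mean/sd),
#'   `dropped` (zero-variance feature names).
#' @export
standardize <- function(train, test = NULL) {
  fc <- feature_columns(train)
  mu <- vapply(train[fc], mean, 0)
  sd_ <- vapply(train[fc], stats::sd, 0)
  dropped <- fc[sd_ == 0 | !is.finite(sd_)]
  keep <- setdiff(fc, dropped)
  for (f in keep) {
    train[[f]] <- (train[[f]] - mu[[f]]) / sd_[[f]]
    if (!is.null(test)) test[[f]] <- (test[[f]] - mu[[f]]) / sd_[[f]]
  }
  train <- train[, setdiff(names(train), dropped), drop = FALSE]
  if (!is.null(test)) test <- test[, setdiff(names(test), dropped), drop = FALSE]
  list(train = train, test = test,
       scaler = data.frame(feature = keep, mean = mu[keep], sd = sd_[keep],
                           row.names = NULL),
       dropped = dropped)
}

#' Univariate two-sample filter (t-test + rank test)
#'
#' Per feature, a Welch two-sample t-test and a Mann-Whitney rank test of
#' case vs control on the training rows. A feature survives if significant
#' at `alpha` under the configured integration rule (default: union of the
#' two survivor sets).
#'
#' @param train training feature table.
#' @param alpha significance level.
#' @param integration `"union"` or `"intersection"`.
#' @param fdr apply Benjamini-Hochberg adjustment to each test's p-values.
#' @return Data.frame with `feature`, `p_t`, `p_rank`, `survives`.
#' @export
univariate_filter <- function(train, alpha = 0.05,
                              integration = c("union", "intersection"),
                              fdr = FALSE) {
  integration <- match.arg(integration)
  fc <- feature_columns(train)
  cl <- train$label
  cls <- unique(cl)
  stopifnot(length(cls) == 2)
  p_t <- p_r <- rep(NA_real_, length(fc))
  for (k in seq_along(fc)) {
    x <- train[[fc[k]]][cl == cls[1]]
    y <- train[[fc[k]]][cl == cls[2]]
    p_t[k] <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    p_r[k] <- tryCatch(
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value),
      error = function(e) 1)
  }
  if (fdr) {
    p_t_adj <- stats::p.adjust(p_t, "BH")
    p_r_adj <- stats::p.adjust(p_r, "BH")
  } else {
    p_t_adj <- p_t; p_r_adj <- p_r
  }
  surv <- if (integration == "union") p_t_adj < alpha | p_r_adj < alpha
          else p_t_adj < alpha & p_r_adj < alpha
  data.frame(feature = fc, p_t = p_t, p_rank = p_r, survives = surv,
             stringsAsFactors = FALSE)
}

#' Spearman redundancy filter
#'
#' Computes |Spearman rho| between all surviving feature pairs on the
#' training rows; pairs exceeding the threshold are visited in descending
#' |rho| (ties broken by name) and, for each pair still fully alive, one
#' member is removed by a seeded coin flip.
#'
#' @param train training feature table.
#' @param survivors character vector of feature names entering the stage.
#' @param rho threshold on |Spearman rho| (default 0.9).
#' @param seed RNG seed for the removal coin flips.
#' @return List `survivors` (kept names, original order) and `removed`
#'   (data.frame kept/removed/rho log).
#' @export
correlation_filter <- function(train, survivors, rho = 0.9, seed = 1L) {
  stopifnot(length(survivors) >= 1)
  if (length(survivors) == 1L)
    return(list(survivors = survivors,
                removed = data.frame(kept = character(0), removed = character(0),
                                     rho = numeric(0))))
  cm <- suppressWarnings(
    stats::cor(as.matrix(train[survivors]), method = "spearman"))
  cm[!is.finite(cm)] <- 0
  ut <- which(upper.tri(cm) & abs(cm) > rho, arr.ind = TRUE)
  if (nrow(ut) == 0L)
    return(list(survivors = survivors,
                removed = data.frame(kept = character(0), removed = character(0),
                                     rho = numeric(0))))
  pairs <- data.frame(a = survivors[ut[, 1]], b = survivors[ut[, 2]],
                      rho = cm[ut], stringsAsFactors = FALSE)
  pairs <- pairs[order(-abs(pairs$rho), pairs$a, pairs$b), , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(survivors)), survivors)
  log <- list()
  set.seed(seed)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    if (alive[[a]] && alive[[b]]) {
      drop <- if (stats::runif(1) < 0.5) a else b
      keep <- if (drop == a) b else a
      alive[[drop]] <- FALSE
      log[[length(log) + 1L]] <- data.frame(kept = keep, removed = drop,
                                            rho = pairs$rho[k],
                                            stringsAsFactors = FALSE)
    }
  }
  list(survivors = survivors[alive[survivors]],
       removed = if (length(log)) do.call(rbind, log)
                 else data.frame(kept = character(0), removed = character(0),
                                 rho = numeric(0)))
}

#' LASSO-penalized logistic selection with cross-validated lambda
#'
#' Fits an L1-penalized logistic regression path over a log-spaced lambda
#' grid on the training rows, chooses lambda minimizing the mean
#' cross-validated binomial deviance over stratified folds, and returns the
#' features with nonzero coefficients at that lambda together with the
#' coefficient path and CV error curve.
#'
#' @param train training feature table (standardized).
#' @param survivors feature names entering the stage (>= 2).
#' @param n_folds number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @param n_lambda grid length.
#' @return List of class `hr_lasso_result`: `selected` (data.frame of
#'   feature/coefficient at the chosen lambda), `lambda_min`, `path`
#'   (lambda x feature coefficient matrix), `cv` (lambda, mean deviance,
#'   SD), `empty` flag.
#' @export
lasso_select <- function(train, survivors, n_folds = 10L, seed = 1L,
                         n_lambda = 100L) {
  stopifnot(length(survivors) >= 2)
  x <- as.matrix(train[survivors])
  y <- as.integer(train$label == .positive_class(train$label))
  # stratified fold ids, deterministic given seed
  set.seed(seed)
  foldid <- integer(length(y))
  for (v in unique(y)) {
    idx <- sample(which(y == v))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             foldid = foldid, nlambda = n_lambda,
                             standardize = FALSE, type.measure = "deviance")
  lam <- cvfit$lambda.min
  beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
  nz <- beta[beta != 0]
  path <- t(as.matrix(cvfit$glmnet.fit$beta))
  structure(list(
    selected = data.frame(feature = names(nz), coefficient = unname(nz),
                          stringsAsFactors = FALSE),
    lambda_min = lam,
    path = path,
    cv = data.frame(lambda = cvfit$lambda, deviance = cvfit$cvm,
                    sd = cvfit$cvsd),
    empty = length(nz) == 0
  ), class = "hr_lasso_result")
}

#' Run the full three-stage selection cascade
#'
#' Imputation, stratified split, train-fitted standardization, univariate
#' t+rank filter, Spearman redundancy filter, and LASSO-CV — all fitted on
#' the training rows only. Returns the per-stage audit trail with strictly
#' nested survivor sets.
#'
#' @param table feature table for one side (one row per subject).
#' @param config an `hr_selection_config`.
#' @param seed RNG seed controlling split, coin flips, and CV folds.
#' @return List of class `hr_selection_result` with `stages` (named feature
#'   counts), `survivors` per stage, `univariate`, `correlation`, `lasso`,
#'   `train`, `test` (standardized tables), `selected` feature names.
#' @export
run_selection <- function(table, config = selection_config(), seed = 1L) {
  sp <- split_train_test(table, config$train_fraction, seed = seed)
  # impute with training means only, then standardize on train
  tr <- impute_abnormal(sp$train)
  te <- impute_abnormal(sp$test, means = attr(tr, "impute_means"))
  te <- te[, names(tr), drop = FALSE]
  st <- standardize(tr, te)
  uni <- univariate_filter(st$train, config$alpha, config$integration,
                           fdr = config$fdr)
  s1 <- uni$feature[uni$survives]
  if (length(s1) == 0L)
    return(structure(list(stages = c(input = length(feature_columns(table)),
                                     univariate = 0L),
                          survivors = list(univariate = character(0)),
                          univariate = uni, selected = character(0),
                          train = st$train, test = st$test, empty = TRUE),
                     class = "hr_selection_result"))
  cf <- correlation_filter(st$train, s1, config$rho, seed = seed + 1L)
  s2 <- cf$survivors
  las <- if (length(s2) >= 2)
    lasso_select(st$train, s2, config$n_folds, seed = seed + 2L,
                 n_lambda = config$n_lambda)
  else NULL
  s3 <- if (is.null(las)) s2 else las$selected$feature
  structure(list(
    stages = c(input = length(feature_columns(table)),
               univariate = length(s1), correlation = length(s2),
               lasso = length(s3)),
    survivors = list(univariate = s1, correlation = s2, lasso = s3),
    univariate = uni, correlation = cf, lasso = las,
    selected = s3, train = st$train, test = st$test, scaler = st$scaler,
    empty = length(s3) == 0
  ), class = "hr_selection_result")
}
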
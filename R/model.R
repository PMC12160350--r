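#' Specification of a risk-score classifier
#'
#' A small, reproducible model zoo stands in for automated model search:
#' gradient boosting (xgboost), random forest (ranger), logistic regression
#' (glm), and a stacked ensemble — a logistic combiner fitted to the zoo
#' members' out-of-fold cross-validated predictions, mirroring the common
#' finding that a stacked ensemble tops leaderboards on tabular risk data.
#'
#' @param algorithm one of "gradient_boosting", "random_forest", "logistic",
#'   "ensemble".
#' @param hyperparameters named list overriding per-algorithm defaults
#'   (see Details).
#' @param n_cv_folds cross-validation folds (default 5; must be >= 2).
#' @param seed integer seed (folds, tree randomness).
#' @param time_budget_s advisory training-time cap in seconds, echoed into
#'   the result (default 900).
#' @details Default hyperparameters: gradient boosting `nrounds = 150`,
#'   `learning_rate = 0.1`, `max_depth = 3`, `subsample = 0.8`,
#'   `colsample_bytree = 0.8`; random forest `num.trees = 300`,
#'   `min.node.size = 10`; logistic regression has none.
#' @return `model_spec` list.
#' @export
model_spec <- function(algorithm = c("gradient_boosting", "random_forest",
                                     "logistic", "ensemble"),
                       hyperparameters = list(), n_cv_folds = 5L, seed = 1L,
                       time_budget_s = 900) {
  algorithm <- match.arg(algorithm)
  if (n_cv_folds < 2) stop_cslv("n_cv_folds must be >= 2")
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 n_cv_folds = as.integer(n_cv_folds), seed = as.integer(seed),
                 time_budget_s = time_budget_s),
            class = "model_spec")
}

.ZOO <- c("gradient_boosting", "random_forest", "logistic")

# fit one algorithm on a numeric matrix; returns list(predict = function(X))
fit_one <- function(X, y, algorithm, hp, seed) {
  if (algorithm == "logistic") {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(X)))  # syntactic names for glm
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                       family = stats::binomial()))
    return(list(predict = function(Xn) {
      nd <- as.data.frame(Xn); names(nd) <- paste0("f", seq_len(ncol(Xn)))
      as.numeric(suppressWarnings(stats::predict(fit, nd, type = "response")))
    }))
  }
  if (algorithm == "gradient_boosting") {
    p <- utils::modifyList(list(nrounds = 150, learning_rate = 0.1, max_depth = 3,
                                subsample = 0.8, colsample_bytree = 0.8), hp)
    fit <- xgboost::xgboost(
      x = X, y = factor(y, levels = c(FALSE, TRUE)), nrounds = p$nrounds,
      learning_rate = p$learning_rate, max_depth = p$max_depth,
      subsample = p$subsample, colsample_bytree = p$colsample_bytree,
      nthreads = 1, seed = seed %% .Machine$integer.max, verbosity = 0)
    return(list(predict = function(Xn) as.numeric(stats::predict(fit, Xn))))
  }
  if (algorithm == "random_forest") {
    p <- utils::modifyList(list(num.trees = 300, min.node.size = 10), hp)
    df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
    fit <- ranger::ranger(x = df, y = factor(y, levels = c(FALSE, TRUE)),
                          probability = TRUE, num.trees = p$num.trees,
                          min.node.size = p$min.node.size, seed = seed,
                          num.threads = 1)
    return(list(predict = function(Xn) {
      nd <- as.data.frame(Xn); names(nd) <- paste0("f", seq_len(ncol(Xn)))
      as.numeric(stats::predict(fit, nd, num.threads = 1)$predictions[, "TRUE"])
    }))
  }
  stop_cslv("unknown algorithm '%s'", algorithm)
}

# stratified fold assignment: within each class, folds dealt out evenly
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# feature matrix for the given sample ids, aligned to stored feature names;
# medians == NULL -> compute train medians
design_matrix <- function(features, sample_ids, feature_names = NULL, medians = NULL) {
  row <- match(sample_ids, features$sample_id)
  if (anyNA(row))
    stop_cslv("%d sample(s) missing from the feature table (first: %s)",
              sum(is.na(row)), sample_ids[is.na(row)][1])
  if (is.null(feature_names)) feature_names <- setdiff(names(features), "sample_id")
  miss <- setdiff(feature_names, names(features))
  if (length(miss))
    stop_cslv("feature table lacks %d expected feature(s) (first: %s) — unseen feature layout",
              length(miss), miss[1])
  X <- as.matrix(features[row, feature_names, drop = FALSE])
  rownames(X) <- sample_ids
  if (is.null(medians)) medians <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- medians[j]
  list(X = X, medians = medians)
}

#' Fit a risk-score classifier with cross-validation
#'
#' Trains the requested algorithm on the full training cohort and reports
#' per-fold AUCs from stratified k-fold out-of-fold predictions. Missing
#' feature values are imputed with train-set column medians (stored and
#' reused at scoring time); all-missing columns are dropped with a warning.
#' The "ensemble" algorithm fits every zoo member, collects their
#' out-of-fold predictions on the shared folds, and combines them with a
#' logistic stack.
#'
#' @param features CSLV feature table ([compute_cslv()]).
#' @param train training `cohort_table`.
#' @param spec a [model_spec()].
#' @param test optional test `cohort_table`; when given, `test_auc` is
#'   computed.
#' @return `cslv_fit` list: `algorithm`, `spec`, `feature_names`, `medians`,
#'   `cv_auc` (length `n_cv_folds`), `train_auc`, `test_auc` (or NA),
#'   `oof` (out-of-fold predictions), and the opaque scoring closure.
#' @export
fit <- function(features, train, spec = model_spec(), test = NULL) {
  y <- as_case(train$label)
  if (length(unique(y)) < 2) stop_cslv("training set contains a single class")
  if (min(table(y)) < spec$n_cv_folds)
    stop_cslv("smallest class has %d members; %d-fold stratified CV needs at least %d",
              min(table(y)), spec$n_cv_folds, spec$n_cv_folds)
  feature_names <- setdiff(names(features), "sample_id")
  all_na <- feature_names[vapply(features[feature_names],
                                 function(v) all(is.na(v)), logical(1))]
  if (length(all_na)) {
    warning(sprintf("fit: dropped %d all-missing feature column(s)", length(all_na)))
    feature_names <- setdiff(feature_names, all_na)
  }
  dm <- design_matrix(features, train$sample_id, feature_names)
  X <- dm$X
  fold <- make_folds(y, spec$n_cv_folds, spec$seed)

  members <- if (spec$algorithm == "ensemble") .ZOO else spec$algorithm
  oof_member <- matrix(NA_real_, nrow(X), length(members),
                       dimnames = list(train$sample_id, members))
  for (f in seq_len(spec$n_cv_folds)) {
    hold <- fold == f
    for (m in seq_along(members)) {
      mf <- fit_one(X[!hold, , drop = FALSE], y[!hold], members[m],
                    spec$hyperparameters, spec$seed + f)
      oof_member[hold, m] <- mf$predict(X[hold, , drop = FALSE])
    }
  }
  full <- lapply(members, function(m) fit_one(X, y, m, spec$hyperparameters, spec$seed))
  names(full) <- members

  if (spec$algorithm == "ensemble") {
    sdf <- as.data.frame(oof_member)
    stack <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, sdf),
                                         family = stats::binomial()))
    predict_fun <- function(Xn) {
      p <- vapply(full, function(m) m$predict(Xn), numeric(nrow(Xn)))
      if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, members))
      nd <- as.data.frame(p)
      as.numeric(suppressWarnings(stats::predict(stack, nd, type = "response")))
    }
    oof <- as.numeric(suppressWarnings(stats::predict(stack, sdf, type = "response")))
  } else {
    predict_fun <- full[[1]]$predict
    oof <- oof_member[, 1]
  }
  cv_auc <- vapply(seq_len(spec$n_cv_folds),
                   function(f) auc(y[fold == f], oof[fold == f]), numeric(1))
  res <- structure(list(algorithm = spec$algorithm, spec = spec,
                        feature_names = feature_names, medians = dm$medians,
                        predict_fun = predict_fun, cv_auc = cv_auc,
                        train_auc = auc(y, predict_fun(X)), test_auc = NA_real_,
                        oof = stats::setNames(oof, train$sample_id),
                        seed = spec$seed),
                   class = "cslv_fit")
  if (!is.null(test))
    res$test_auc <- auc(as_case(test$label), score(res, features, test$sample_id))
  res
}

#' Score samples with a fitted classifier
#'
#' @param result a `cslv_fit`.
#' @param features CSLV feature table containing the samples.
#' @param sample_ids samples to score (default: all in `features`).
#' @return named numeric vector of risk scores in `[0, 1]`, in `sample_ids`
#'   order.
#' @export
score <- function(result, features, sample_ids = features$sample_id) {
  stopifnot(inherits(result, "cslv_fit"))
  dm <- design_matrix(features, sample_ids, result$feature_names, result$medians)
  stats::setNames(result$predict_fun(dm$X), sample_ids)
}

#' @export
print.cslv_fit <- function(x, ...) {
  cat(sprintf("cslv_fit: %s | CV AUC %.3f (mean of %d folds) | train AUC %.3f%s\n",
              x$algorithm, mean(x$cv_auc), length(x$cv_auc), x$train_auc,
              if (is.na(x$test_auc)) "" else sprintf(" | test AUC %.3f", x$test_auc)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = U / (n1 * n0)`: the probability that a random case scores above a
#' random control, with ties credited 0.5. Computed from midranks, which is
#' exactly the all-pairs count.
#'
#' @param labels case/control labels (case/control strings, 0/1 or logical).
#' @param scores numeric risk scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  y <- as_case(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop_cslv("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a percentile-bootstrap confidence interval
#'
#' @inheritParams auc
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for resampling.
#' @param conf_level confidence level (default 0.95).
#' @return named numeric: `auc`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(labels, scores, n_boot = 2000, seed = 1L, conf_level = 0.95) {
  y <- as_case(labels)
  point <- auc(y, scores)
  set.seed(seed)
  n <- length(y)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc(y[idx], scores[idx])
  }, numeric(1))
  q <- stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                       na.rm = TRUE, names = FALSE)
  c(auc = point, ci_low = q[1], ci_high = q[2])
}

#' Repeated end-to-end runs: resample, split, fit, evaluate
#'
#' Each run re-draws the age-matched control sample, the train/test split and
#' the model fit under `seed + run - 1`, and records the held-out test AUC;
#' the mean and sample sd across runs summarise run-to-run stability.
#'
#' @param features CSLV feature table.
#' @param cohort full `cohort_table` (pre-undersampling).
#' @param spec a [model_spec()].
#' @param n_runs number of runs (default 5, >= 2).
#' @param split a [split_spec()]; its seed is re-based per run.
#' @return list: `aucs` (length `n_runs`), `mean`, `sd`.
#' @export
repeated_runs <- function(features, cohort, spec = model_spec(), n_runs = 5,
                          split = split_spec()) {
  if (n_runs < 2) stop_cslv("n_runs must be >= 2")
  aucs <- vapply(seq_len(n_runs), function(r) {
    s <- split; s$seed <- split$seed + r - 1L
    ms <- spec; ms$seed <- spec$seed + r - 1L
    matched <- undersample_matched(cohort, s)
    parts <- split_train_test(matched, s)
    f <- fit(features, parts$train, ms, test = parts$test)
    f$test_auc
  }, numeric(1))
  list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs))
}
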
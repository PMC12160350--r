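#' Cross-population transfer evaluation
#'
#' For each training group: assemble an age-matched cohort *within* that
#' group, make an 80/20 split, fit the model on the 80%, then evaluate the
#' AUC on (i) the group's own 20% holdout, (ii) every other named group in
#' full, (iii) "other" — all samples belonging to none of the named training
#' groups — and (iv) "mixed" — the union of all groups, where the training
#' group contributes only its holdout (training samples never leak into any
#' test set). The whole procedure is repeated `n_runs` times under shifted
#' seeds and summarised as mean and sd per (train, test) cell.
#'
#' @param features CSLV feature table.
#' @param cohort full `cohort_table` with a `group` column.
#' @param spec a [model_spec()].
#' @param train_groups character vector of group labels to train on.
#' @param test_groups test group labels; default: the training groups plus
#'   "other" and "mixed".
#' @param n_runs repetitions (default 5).
#' @param split a [split_spec()]; its seed is re-based per run.
#' @return `transfer_result` list: `runs` (long data.frame: `train_group`,
#'   `test_group`, `run`, `auc`) and `summary` (`train_group`, `test_group`,
#'   `mean_auc`, `sd_auc`, `n_runs`).
#' @export
transfer_matrix <- function(features, cohort, spec = model_spec(), train_groups,
                            test_groups = NULL, n_runs = 5,
                            split = split_spec()) {
  have <- unique(cohort$group)
  absent <- setdiff(train_groups, have)
  if (length(absent))
    stop_cslv("group(s) %s absent from cohort; available: %s",
              paste(absent, collapse = ", "), paste(have, collapse = ", "))
  if (is.null(test_groups)) test_groups <- c(train_groups, "other", "mixed")
  rows <- list()
  for (tg in train_groups) {
    for (r in seq_len(n_runs)) {
      s <- split; s$seed <- split$seed + r - 1L
      ms <- spec; ms$seed <- spec$seed + r - 1L
      sub <- cohort[cohort$group == tg, , drop = FALSE]
      matched <- undersample_matched(sub, s)
      parts <- split_train_test(matched, s)
      f <- fit(features, parts$train, ms)
      train_ids <- parts$train$sample_id
      for (eg in test_groups) {
        te <- if (eg == tg) {
          parts$test
        } else if (eg == "other") {
          cohort[!cohort$group %in% train_groups, , drop = FALSE]
        } else if (eg == "mixed") {
          cohort[cohort$group != tg | cohort$sample_id %in% parts$test$sample_id, , drop = FALSE]
        } else {
          cohort[cohort$group == eg, , drop = FALSE]
        }
        te <- te[!te$sample_id %in% train_ids, , drop = FALSE]
        if (nrow(te) == 0 || length(unique(as_case(te$label))) < 2) next
        rows[[length(rows) + 1]] <- data.frame(
          train_group = tg, test_group = eg, run = r,
          auc = auc(te$label, score(f, features, te$sample_id)))
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(auc ~ train_group + test_group, runs,
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  summary <- data.frame(train_group = agg$train_group, test_group = agg$test_group,
                        mean_auc = agg$auc[, "mean"], sd_auc = agg$auc[, "sd"],
                        n_runs = agg$auc[, "n"])
  structure(list(runs = runs, summary = summary), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Cross-population transfer AUCs:\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Permutation feature importance on a held-out test set
#'
#' Importance of a feature = baseline test AUC minus the mean AUC after
#' shuffling that feature's column across test samples (`n_repeats`
#' shuffles). Model-agnostic; correlated informative features mask one
#' another, as with any permutation scheme. Constant columns get importance
#' 0 with a warning.
#'
#' @param result a fitted `cslv_fit`.
#' @param features CSLV feature table.
#' @param test test `cohort_table` with both classes present.
#' @param n_repeats shuffles per feature (default 10).
#' @param seed seed for the shuffles.
#' @return data.frame: `feature`, `importance` (AUC drop), `rank` (1 = most
#'   important; ranks are a permutation of 1..n_features).
#' @export
permutation_importance <- function(result, features, test, n_repeats = 10, seed = 1L) {
  stopifnot(inherits(result, "cslv_fit"))
  y <- as_case(test$label)
  if (length(unique(y)) < 2) stop_cslv("test set needs both classes")
  dm <- design_matrix(features, test$sample_id, result$feature_names, result$medians)
  X <- dm$X
  baseline <- auc(y, result$predict_fun(X))
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    if (length(unique(col)) == 1) {
      warning(sprintf("permutation_importance: feature '%s' is constant; importance 0",
                      colnames(X)[j]))
      return(0)
    }
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- col[sample.int(nrow(X))]
      baseline - auc(y, result$predict_fun(Xp))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = colnames(X), importance = imp)
  out$rank <- order(order(-out$importance, out$feature))
  out[order(out$rank), ]
}
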
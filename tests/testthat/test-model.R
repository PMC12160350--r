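# quick feature table: one row per sample, columns f1..fk
feat_table <- function(X, ids = sprintf("s%04d", seq_len(nrow(X)))) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  data.frame(sample_id = ids, X, check.names = FALSE, stringsAsFactors = FALSE)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("AUC matches hand-counted pairs and the exhaustive oracle", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)  # 3 wins, 1 loss
  expect_equal(auc(c("case", "control"), c(1, 0)), 1.0)
  expect_equal(auc(c(1, 1, 0, 0), rep(0.3, 4)), 0.5)             # all ties -> 0.5
  expect_error(auc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 2))  # rounded -> plenty of ties
    expect_equal(auc(y, s), brute_auc(y, s))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(19)
  y <- sample(c(TRUE, FALSE), 150, replace = TRUE)
  s <- round(rnorm(150), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc(y, s), ref)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  y <- rep(c(TRUE, FALSE), 30)
  s <- rnorm(60)
  a <- auc(y, s)
  expect_equal(auc(y, exp(s)), a)
  expect_equal(auc(y, 2 * s - 7), a)
  expect_equal(auc(y, rank(s)), a)
})

test_that("bootstrap CI brackets the point AUC and tightens with n", {
  set.seed(5)
  mk <- function(n) {
    y <- rep(c(TRUE, FALSE), n / 2)
    s <- rnorm(n, mean = ifelse(y, 0.5, 0))
    auc_ci(y, s, n_boot = 500, seed = 9)
  }
  small <- mk(60); big <- mk(600)
  for (ci in list(small, big)) {
    expect_gte(ci[["auc"]], ci[["ci_low"]])
    expect_lte(ci[["auc"]], ci[["ci_high"]])
  }
  expect_lt(big[["ci_high"]] - big[["ci_low"]], small[["ci_high"]] - small[["ci_low"]])
})

test_that("fitting validates its inputs", {
  X <- matrix(rnorm(40), 20, 2)
  feats <- feat_table(X)
  all_case <- toy_cohort(20, 0)
  all_case$sample_id <- feats$sample_id
  expect_error(fit(feats, all_case, model_spec("logistic")), "single class")

  few <- toy_cohort(3, 17)
  few$sample_id <- feats$sample_id
  expect_error(fit(feats, few, model_spec("logistic")), "5-fold")

  coh <- toy_cohort(10, 10)
  coh$sample_id <- feats$sample_id
  feats$f3 <- NA_real_
  expect_warning(f <- fit(feats, coh, model_spec("logistic", seed = 2)),
                 "all-missing")
  expect_equal(f$feature_names, c("f1", "f2"))
  expect_length(f$cv_auc, 5)
  expect_true(all(f$cv_auc >= 0 & f$cv_auc <= 1))
})

test_that("null features give chance-level CV AUC for every algorithm", {
  set.seed(6)
  n <- 300  # mean of 5 fold AUCs has SE ~ 0.035 at this size
  feats <- feat_table(matrix(rnorm(n * 6), n, 6))
  coh <- toy_cohort(n * 0.4, n * 0.6)
  coh$sample_id <- feats$sample_id  # labels independent of features
  for (alg in c("logistic", "gradient_boosting", "random_forest")) {
    f <- fit(feats, coh, model_spec(alg, seed = 17))
    expect_gt(mean(f$cv_auc), 0.36)
    expect_lt(mean(f$cv_auc), 0.64)
  }
})

test_that("scoring is consistent, order-equivariant and duplicate-stable", {
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- stats::runif(n) < stats::plogis(2 * X[, 1])
  coh <- cohort_table(data.frame(sample_id = sprintf("s%04d", 1:n),
                                 label = ifelse(y, "case", "control"), age = 50))
  feats <- feat_table(X)
  f <- fit(feats, coh, model_spec("gradient_boosting", seed = 3))
  sc <- score(f, feats, coh$sample_id)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(auc(coh$label, sc), f$train_auc)    # stored training AUC reproduced

  perm <- sample(n)
  expect_equal(score(f, feats, coh$sample_id[perm]), sc[perm])

  dup <- feats[c(1, 1, 2), ]
  dup$sample_id <- c("a", "b", "c")
  sd2 <- score(f, dup)
  expect_equal(unname(sd2["a"]), unname(sd2["b"]))

  expect_error(score(f, feats[, 1:3], coh$sample_id), "unseen feature layout")
  expect_error(score(f, feats, c("nope", coh$sample_id[1])), "missing from the feature table")
})

test_that("a single informative Gaussian feature reaches its analytic AUC ceiling", {
  set.seed(12)
  n1 <- 300; n0 <- 450
  delta <- 0.8; sdev <- 1
  a_star <- gaussian_auc(delta, sdev)   # ~0.714
  X <- cbind(c(rnorm(n1, delta, sdev), rnorm(n0, 0, sdev)),
             matrix(rnorm((n1 + n0) * 5), n1 + n0, 5))
  coh <- toy_cohort(n1, n0)
  feats <- feat_table(X, coh$sample_id)
  parts <- split_train_test(coh, split_spec(seed = 1))
  f <- fit(feats, parts$train, model_spec("gradient_boosting", seed = 1),
           test = parts$test)
  expect_gt(f$test_auc, a_star - 0.08)
  expect_lt(f$test_auc, a_star + 0.05)
})

test_that("the ensemble stacks its members and is not the worst of them", {
  set.seed(14)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  y <- stats::runif(n) < stats::plogis(1.5 * X[, 1] - X[, 2])
  coh <- cohort_table(data.frame(sample_id = sprintf("s%04d", 1:n),
                                 label = ifelse(y, "case", "control"), age = 50))
  feats <- feat_table(X)
  parts <- split_train_test(coh, split_spec(seed = 5))
  members <- vapply(c("logistic", "gradient_boosting", "random_forest"),
                    function(a) fit(feats, parts$train, model_spec(a, seed = 4),
                                    test = parts$test)$test_auc, numeric(1))
  ens <- fit(feats, parts$train, model_spec("ensemble", seed = 4), test = parts$test)
  expect_gte(ens$test_auc, min(members) - 0.02)  # soft property, not a theorem
  expect_length(ens$cv_auc, 5)
})

test_that("repeated runs are seed-deterministic and degenerate to sd 0", {
  # perfectly separating feature -> AUC 1 in every run -> sd 0
  n <- 100
  coh <- toy_cohort(20, 80, case_ages = 48:67, control_ages = rep(30:69, 2))
  y <- coh$label == "case"
  feats <- feat_table(matrix(as.numeric(y) * 2 - 1 + 0, n, 1), coh$sample_id)
  r <- repeated_runs(feats, coh, model_spec("logistic", seed = 2), n_runs = 3)
  expect_equal(r$aucs, rep(1, 3))
  expect_equal(r$sd, 0)

  r2 <- repeated_runs(feats, coh, model_spec("logistic", seed = 2), n_runs = 3)
  expect_identical(r, r2)
  expect_error(repeated_runs(feats, coh, model_spec("logistic"), n_runs = 1),
               "n_runs")
})
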
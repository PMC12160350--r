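# shared simulation helpers for group-structured cohorts
two_group_cfg <- function(seed, shared = TRUE, n_per_group = 300) {
  L <- 4e6
  regions <- if (shared) {
    # one region affecting both groups alike
    data.frame(chrom = "1", start = 1, end = L / 4, case_prob = 0.9,
               control_prob = 0.1, shift = -0.5, group = NA_character_)
  } else {
    # disjoint signal: group A's region is inert in group B and vice versa
    data.frame(chrom = c("1", "2"), start = 1, end = L / 4,
               case_prob = 0.9, control_prob = 0.1, shift = -0.5,
               group = c("A", "B"))
  }
  sim_config(build = toy_build(c(L, L, L)), markers_per_chrom = 120,
             seed = seed, n_cases = round(n_per_group * 0.3 * 2),
             n_controls = round(n_per_group * 0.7 * 2),
             background_cnv_rate = 0.5, effect_regions = regions,
             groups = data.frame(group = c("A", "B"), proportion = c(0.5, 0.5)))
}

sim_features <- function(cfg, k = 4) {
  d <- simulate_cohort(cfg)
  sm <- build_segments(cfg$build, d$manifest, k)
  list(features = compute_cslv(d$lrr, sm), cohort = d$cohort, segmap = sm, cfg = cfg)
}

test_that("transfer grid reports every cell with per-run AUCs", {
  x <- sim_features(two_group_cfg(seed = 41, shared = TRUE))
  tr <- transfer_matrix(x$features, x$cohort, model_spec("logistic", seed = 1),
                        train_groups = c("A", "B"), n_runs = 2,
                        split = split_spec(seed = 1))
  expect_setequal(unique(tr$runs$test_group), c("A", "B", "mixed"))  # no "other" samples exist
  expect_true(all(tr$summary$n_runs == 2))
  expect_true(all(tr$summary$mean_auc >= 0 & tr$summary$mean_auc <= 1))
  expect_error(transfer_matrix(x$features, x$cohort, model_spec(), "Z"),
               "absent from cohort; available")
})

test_that("shared effect regions transfer across groups; the gap is within noise", {
  x <- sim_features(two_group_cfg(seed = 43, shared = TRUE))
  tr <- transfer_matrix(x$features, x$cohort, model_spec("logistic", seed = 2),
                        train_groups = c("A", "B"), n_runs = 4,
                        split = split_spec(seed = 2))
  s <- tr$summary
  own <- s$mean_auc[s$train_group == "A" & s$test_group == "A"]
  cross <- s$mean_auc[s$train_group == "A" & s$test_group == "B"]
  pooled_se <- sqrt(s$sd_auc[s$train_group == "A" & s$test_group == "A"]^2 / 4 +
                    s$sd_auc[s$train_group == "A" & s$test_group == "B"]^2 / 4)
  expect_lt(abs(own - cross), max(2 * pooled_se, 0.10))
  expect_gt(cross, 0.6)  # the signal genuinely transfers
})

test_that("group-specific effect regions break transfer in both directions", {
  x <- sim_features(two_group_cfg(seed = 47, shared = FALSE, n_per_group = 400))
  tr <- transfer_matrix(x$features, x$cohort, model_spec("logistic", seed = 3),
                        train_groups = c("A", "B"), n_runs = 4,
                        split = split_spec(seed = 3))
  runs <- tr$runs
  for (tg in c("A", "B")) {
    other <- setdiff(c("A", "B"), tg)
    own <- runs$auc[runs$train_group == tg & runs$test_group == tg]
    cross <- runs$auc[runs$train_group == tg & runs$test_group == other]
    expect_gt(mean(own), mean(cross))
    w <- stats::t.test(own, cross, alternative = "greater")
    expect_lt(w$p.value, 0.05)
  }
})

test_that("own-group transfer cell equals the plain repeated-runs pipeline", {
  x <- sim_features(two_group_cfg(seed = 53, shared = TRUE))
  ms <- model_spec("logistic", seed = 5)
  ss <- split_spec(seed = 5)
  tr <- transfer_matrix(x$features, x$cohort, ms, train_groups = "A",
                        n_runs = 2, split = ss)
  rr <- repeated_runs(x$features, x$cohort[x$cohort$group == "A", ], ms,
                      n_runs = 2, split = ss)
  own <- tr$runs$auc[tr$runs$train_group == "A" & tr$runs$test_group == "A"]
  expect_equal(sort(own), sort(rr$aucs))
})

test_that("permutation importance recovers the informative segment and nulls out noise", {
  L <- 4e6
  cfg <- sim_config(build = toy_build(c(L, L)), markers_per_chrom = 160, seed = 61,
                    n_cases = 240, n_controls = 360, background_cnv_rate = 0,
                    effect_regions = data.frame(chrom = "1", start = 1, end = L / 4 - 1,
                                                case_prob = 0.95, control_prob = 0.05,
                                                shift = -0.5))
  x <- sim_features(cfg)
  parts <- split_train_test(x$cohort, split_spec(seed = 6))
  f <- fit(x$features, parts$train, model_spec("gradient_boosting", seed = 6),
           test = parts$test)
  imp <- permutation_importance(f, x$features, parts$test, n_repeats = 5, seed = 6)
  expect_setequal(imp$rank, seq_len(nrow(imp)))
  hit <- effect_segment_index(cfg, x$segmap)
  expect_equal(imp$feature[imp$rank == 1], hit)

  # label-independent features sit in a noise band around zero
  null_imp <- imp$importance[!imp$feature %in% hit]
  expect_lt(max(abs(null_imp)), 0.1)
  expect_lt(abs(mean(null_imp)), 0.02)
})

test_that("duplicated informative features mask each other under permutation", {
  set.seed(71)
  n <- 400
  signal <- c(rnorm(n / 2, 0.6), rnorm(n / 2, 0))
  coh <- toy_cohort(n / 2, n / 2)
  solo <- data.frame(sample_id = coh$sample_id, s1 = signal,
                     noise = rnorm(n), stringsAsFactors = FALSE)
  twin <- data.frame(sample_id = coh$sample_id, s1 = signal, s2 = signal,
                     noise = rnorm(n), stringsAsFactors = FALSE)
  parts <- split_train_test(coh, split_spec(seed = 7))
  f1 <- fit(solo, parts$train, model_spec("random_forest", seed = 7))
  f2 <- fit(twin, parts$train, model_spec("random_forest", seed = 7))
  i1 <- permutation_importance(f1, solo, parts$test, n_repeats = 5, seed = 7)
  i2 <- permutation_importance(f2, twin, parts$test, n_repeats = 5, seed = 7)
  top_solo <- i1$importance[i1$feature == "s1"]
  expect_lt(i2$importance[i2$feature == "s1"], top_solo)
  expect_lt(i2$importance[i2$feature == "s2"], top_solo)
})

test_that("constant feature columns get zero importance with a warning", {
  set.seed(81)
  n <- 120
  coh <- toy_cohort(n / 2, n / 2)
  feats <- data.frame(sample_id = coh$sample_id,
                      f1 = c(rnorm(n / 2, 1), rnorm(n / 2)),
                      flat = 1, stringsAsFactors = FALSE)
  parts <- split_train_test(coh, split_spec(seed = 8))
  f <- fit(feats, parts$train, model_spec("logistic", seed = 8))
  expect_warning(imp <- permutation_importance(f, feats, parts$test, n_repeats = 3),
                 "constant")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
})
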
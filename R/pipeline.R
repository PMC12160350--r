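#' Run the end-to-end CSLV risk-score pipeline
#'
#' Wires the modules into one reproducible experiment: load (or simulate)
#' the inputs, compute segment features, assemble the age-matched 40:60
#' cohort, make the 80/20 split, fit the classifier, stratify the test set
#' into score quintiles, and (optionally) run the cross-group transfer
#' grid. All artifacts are written as TSV under `out_dir`, plus a
#' `manifest.json` recording the configuration, seeds, row counts at each
#' filtering step, and an md5 per output file so byte-identical
#' reproduction is checkable.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `out_dir` (required); either `simulate` (a list of [sim_config()]
#'   arguments) or `manifest`/`lrr`/`phenotypes` paths (`lrr_dialect`
#'   defaults to "wide"); optional `k` (segments per chromosome, default 4),
#'   `min_markers`, `seed` (default 1), `test_fraction`, `algorithm`
#'   (default "gradient_boosting"), `n_cv_folds`, `n_runs` (repeated-runs
#'   summary when >= 2), `transfer_groups` (character vector enabling the
#'   transfer stage), `quiet`.
#' @return invisibly, a list with the in-memory artifacts: `features`,
#'   `fit`, `quintiles`, `transfer` (or NULL), `repeated` (or NULL),
#'   `manifest` (the JSON payload).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop_cslv("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  k <- as.integer(config$k %||% 4L)
  quiet <- isTRUE(config$quiet)
  say <- function(stage, fmt, ...) if (!quiet)
    message(sprintf("[%s | seed %d] %s", stage, seed, sprintf(fmt, ...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_cslv("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  build <- default_genome_build()
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      do.call(sim_config, args)
    })
    dat <- stage("simulate", simulate_cohort(sim))
    manifest <- dat$manifest; lrr <- dat$lrr; cohort <- dat$cohort
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write_lrr(lrr, file.path(out_dir, "lrr.tsv"))
    write_phenotypes(cohort, file.path(out_dir, "phenotypes.tsv"))
    utils::write.table(dat$truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("simulate", "%d samples x %d markers, %d ground-truth events",
        nrow(lrr), ncol(lrr), nrow(dat$truth))
  } else {
    manifest <- stage("validate", read_manifest(config$manifest, build, quiet = quiet))
    lrr <- stage("validate", read_lrr(config$lrr, config$lrr_dialect %||% "wide", manifest))
    cohort <- stage("validate", read_phenotypes(config$phenotypes))
    stage("validate", validate_inputs(manifest, lrr, cohort))
    say("validate", "%d markers, %d samples, %d phenotyped", nrow(manifest), nrow(lrr), nrow(cohort))
  }

  segmap <- stage("features", build_segments(build, manifest, k))
  features <- stage("features", compute_cslv(lrr, segmap,
                                             min_markers = config$min_markers %||% 1))
  write_cslv(features, file.path(out_dir, "features.tsv"))
  say("features", "%d samples x %d segment features", nrow(features), ncol(features) - 1)

  sspec <- split_spec(seed = seed, test_fraction = config$test_fraction %||% 0.2)
  matched <- stage("cohort", undersample_matched(cohort, sspec))
  parts <- stage("cohort", split_train_test(matched, sspec))
  say("cohort", "matched %d -> %d (cases %d, controls %d); train %d / test %d",
      nrow(cohort), nrow(matched), sum(as_case(matched$label)),
      sum(!as_case(matched$label)), nrow(parts$train), nrow(parts$test))
  write_phenotypes(parts$train, file.path(out_dir, "train.tsv"))
  write_phenotypes(parts$test, file.path(out_dir, "test.tsv"))

  mspec <- model_spec(algorithm = config$algorithm %||% "gradient_boosting",
                      n_cv_folds = config$n_cv_folds %||% 5L, seed = seed)
  f <- stage("train", fit(features, parts$train, mspec, test = parts$test))
  ci <- stage("train", auc_ci(parts$test$label, score(f, features, parts$test$sample_id),
                              seed = seed))
  report <- list(algorithm = f$algorithm, seed = seed, cv_auc = f$cv_auc,
                 train_auc = f$train_auc, test_auc = f$test_auc,
                 ci = c(ci[["ci_low"]], ci[["ci_high"]]))
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("train", "%s: CV AUC %.3f, test AUC %.3f", f$algorithm, mean(f$cv_auc), f$test_auc)

  scores <- score(f, features, parts$test$sample_id)
  bins <- stage("stratify", assign_quintiles(scores))
  qt <- stage("stratify", quintile_odds_ratios(parts$test$label, bins))
  utils::write.table(qt, file.path(out_dir, "quintiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("stratify", "top/bottom OR fold %.2f", attr(qt, "top_vs_bottom_fold"))

  repeated <- NULL
  if ((config$n_runs %||% 1) >= 2) {
    repeated <- stage("train", repeated_runs(features, cohort, mspec,
                                             n_runs = config$n_runs, split = sspec))
    say("train", "repeated runs: mean AUC %.3f, sd %.3f", repeated$mean, repeated$sd)
  }

  transfer <- NULL
  if (!is.null(config$transfer_groups)) {
    transfer <- stage("transfer", transfer_matrix(features, cohort, mspec,
                                                  train_groups = config$transfer_groups,
                                                  n_runs = config$n_runs %||% 5,
                                                  split = sspec))
    utils::write.table(transfer$runs, file.path(out_dir, "transfer_runs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(transfer$summary, file.path(out_dir, "transfer_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- list.files(out_dir, pattern = "\\.(tsv|json)$", full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest_json <- list(
    package_version = as.character(utils::packageVersion("cslv")),
    seed = seed, k = k,
    config = config[setdiff(names(config), "out_dir")],
    n_samples = nrow(cohort), n_matched = nrow(matched),
    n_train = nrow(parts$train), n_test = nrow(parts$test),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, fit = f, quintiles = qt,
                 transfer = transfer, repeated = repeated, manifest = manifest_json))
}
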
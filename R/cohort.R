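#' Specification for cohort assembly and train/test splitting
#'
#' Defaults follow the common design for imbalanced case/control array
#' studies: controls undersampled to a 40:60 case:control ratio with age
#' matching, then a label-stratified 80/20 train/test split.
#'
#' @param seed integer seed driving control selection and the split.
#' @param test_fraction fraction of samples held out for testing (default
#'   0.2).
#' @param ratio_case,ratio_control target class mix after undersampling
#'   (defaults 0.4 / 0.6; must be positive and sum to 1).
#' @param stratify_by_label stratify the split on label (default TRUE).
#' @return `split_spec` list.
#' @export
split_spec <- function(seed = 1L, test_fraction = 0.2, ratio_case = 0.4,
                       ratio_control = 0.6, stratify_by_label = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) stop_cslv("test_fraction must be in (0, 1)")
  if (ratio_case <= 0 || ratio_control <= 0 || abs(ratio_case + ratio_control - 1) > 1e-8)
    stop_cslv("class ratios must be positive and sum to 1")
  structure(list(seed = as.integer(seed), test_fraction = test_fraction,
                 ratio_case = ratio_case, ratio_control = ratio_control,
                 stratify_by_label = isTRUE(stratify_by_label)),
            class = "split_spec")
}

#' Age-matched undersampling of controls
#'
#' Retains every case and selects `ceiling(n_cases * ratio_control /
#' ratio_case)` controls (1.5x for the default 40:60 mix) by greedy
#' nearest-age matching: cases are visited in a seed-randomised order, each
#' drawing its quota (1 or 2 for the default ratio; cases earliest in the
#' randomised order absorb the remainder) of nearest-age unused controls.
#' Ties in age distance break by control sample id. Simple, deterministic
#' given the seed, and auditable; not an optimal bipartite matching.
#'
#' @param cohort a `cohort_table`.
#' @param spec a [split_spec()].
#' @return `cohort_table` subset (input row order preserved) with all cases
#'   and the matched controls; the realised ratio is within one sample of the
#'   target.
#' @export
undersample_matched <- function(cohort, spec = split_spec()) {
  case <- as_case(cohort$label)
  n_cases <- sum(case)
  if (n_cases == 0) stop_cslv("cohort contains no cases")
  target <- ceiling(n_cases * spec$ratio_control / spec$ratio_case)
  n_ctrl <- sum(!case)
  if (n_ctrl < target)
    stop_cslv("need %d controls for a %.0f:%.0f ratio with %d cases, have %d (achievable ratio %.2f:%.2f)",
              target, 100 * spec$ratio_case, 100 * spec$ratio_control, n_cases, n_ctrl,
              n_cases / (n_cases + n_ctrl), n_ctrl / (n_cases + n_ctrl))
  set.seed(spec$seed)
  case_ord <- which(case)[sample.int(n_cases)]
  base <- target %/% n_cases
  extra <- target - base * n_cases
  quota <- base + (seq_len(n_cases) <= extra)
  ctrl_idx <- which(!case)
  # sort candidate controls once by (age, id) so nearest-age lookup is stable
  ctrl_idx <- ctrl_idx[order(cohort$age[ctrl_idx], cohort$sample_id[ctrl_idx])]
  used <- logical(length(ctrl_idx))
  picked <- integer(0)
  for (i in seq_along(case_ord)) {
    free <- which(!used)
    d <- abs(cohort$age[ctrl_idx[free]] - cohort$age[case_ord[i]])
    take <- free[order(d, cohort$sample_id[ctrl_idx[free]])][seq_len(quota[i])]
    used[take] <- TRUE
    picked <- c(picked, ctrl_idx[take])
  }
  keep <- sort(c(which(case), picked))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  out
}

#' Label-stratified train/test split
#'
#' @param cohort a `cohort_table`.
#' @param spec a [split_spec()]; with stratification each label class
#'   contributes `round(test_fraction * n_class)` samples to the test set.
#' @return list of `cohort_table`s: `train`, `test` (disjoint, union = input,
#'   reproducible from the seed).
#' @export
split_train_test <- function(cohort, spec = split_spec()) {
  if (nrow(cohort) == 0) stop_cslv("cohort is empty")
  set.seed(spec$seed)
  if (spec$stratify_by_label) {
    case <- as_case(cohort$label)
    test_idx <- integer(0)
    for (cls in unique(case)) {
      idx <- which(case == cls)
      n_test <- round(spec$test_fraction * length(idx))
      if (n_test > 0) test_idx <- c(test_idx, idx[sample.int(length(idx), n_test)])
    }
  } else {
    test_idx <- sample.int(nrow(cohort), round(spec$test_fraction * nrow(cohort)))
  }
  mk <- function(idx) {
    out <- cohort[idx, , drop = FALSE]; rownames(out) <- NULL
    class(out) <- class(cohort); out
  }
  list(train = mk(sort(setdiff(seq_len(nrow(cohort)), test_idx))),
       test = mk(sort(test_idx)))
}
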
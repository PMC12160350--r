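#' Assign samples to score quintiles
#'
#' Samples are ranked by score, descending, with ties broken by sample id
#' for determinism. Bin 5 holds the highest scores; when `n` is not a
#' multiple of `n_bins` the larger bins go to the higher quintiles first
#' (e.g. 7 samples split (2, 2, 1, 1, 1) from quintile 5 downward).
#'
#' @param scores named numeric vector of risk scores (names = sample ids),
#'   or unnamed with `sample_ids` supplied.
#' @param n_bins number of bins (default 5).
#' @param sample_ids ids used for tie-breaking (default `names(scores)`).
#' @return integer bin per sample (1 = lowest scores, `n_bins` = highest),
#'   aligned to the input order.
#' @export
assign_quintiles <- function(scores, n_bins = 5, sample_ids = names(scores)) {
  n <- length(scores)
  if (n < n_bins) stop_cslv("need at least %d samples for %d bins", n_bins, n_bins)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  ord <- order(-scores, sample_ids)
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)  # q5 first
  bin <- integer(n)
  bin[ord] <- rep(seq(n_bins, 1), sizes)
  stats::setNames(bin, sample_ids)
}

#' Per-quintile case/control counts and odds ratios
#'
#' For quintile q with `a` cases and `b` controls, against test-set totals
#' `A` cases and `B` controls, the odds ratio is defined as the quintile
#' odds relative to the odds in the entire test population:
#' `OR_q = (a / b) / (A / B)`, with a Wald interval on the log odds ratio,
#' `se = sqrt(1/a + 1/b + 1/A + 1/B)`, and a Haldane-Anscombe +0.5 applied
#' to all four cells when `a` or `b` is zero. The alternative convention
#' (quintile vs its complement) is available via `reference`. The two
#' conventions give different numbers; the formula in use is recorded in the
#' result.
#'
#' @param labels case/control labels of the ranked samples.
#' @param bins quintile assignment from [assign_quintiles()].
#' @param conf_level confidence level (default 0.95).
#' @param reference "population" (quintile vs whole test population,
#'   default) or "complement" (quintile vs all other quintiles).
#' @return data.frame with one row per quintile (5 = highest scores, first):
#'   `quintile`, `n_cases`, `n_controls`, `n_total`, `odds_ratio`, `ci_low`,
#'   `ci_high`; attributes `top_vs_bottom_fold` (OR_5 / OR_1) and
#'   `reference`.
#' @export
quintile_odds_ratios <- function(labels, bins, conf_level = 0.95,
                                 reference = c("population", "complement")) {
  reference <- match.arg(reference)
  y <- as_case(labels)
  A <- sum(y); B <- sum(!y)
  if (A == 0 || B == 0) stop_cslv("both classes must be present in the test set")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  qs <- sort(unique(bins), decreasing = TRUE)
  rows <- lapply(qs, function(q) {
    a <- sum(y & bins == q); b <- sum(!y & bins == q)
    if (a + b == 0) stop_cslv("empty quintile %d", q)
    if (reference == "population") {
      refA <- A; refB <- B
    } else {
      refA <- A - a; refB <- B - b
    }
    a2 <- a; b2 <- b
    if (a == 0 || b == 0 || refA == 0 || refB == 0) {
      a2 <- a + 0.5; b2 <- b + 0.5; refA <- refA + 0.5; refB <- refB + 0.5
    }
    or <- (a2 / b2) / (refA / refB)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / refA + 1 / refB)
    data.frame(quintile = q, n_cases = a, n_controls = b, n_total = a + b,
               odds_ratio = or, ci_low = exp(log(or) - z * se),
               ci_high = exp(log(or) + z * se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "top_vs_bottom_fold") <-
    out$odds_ratio[out$quintile == max(qs)] / out$odds_ratio[out$quintile == min(qs)]
  attr(out, "reference") <- reference
  class(out) <- c("quintile_table", "data.frame")
  out
}

#' @export
print.quintile_table <- function(x, ...) {
  cat(sprintf("Quintile odds ratios (reference: %s odds); top/bottom fold = %.2f\n",
              attr(x, "reference"), attr(x, "top_vs_bottom_fold")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
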
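#' Published quintile risk-stratification table (reference data)
#'
#' Per-quintile case/control counts and odds ratios reported for a CSLV
#' breast-cancer risk model evaluated on a test set of 2,015 women
#' (quintile 5 = highest scores). Shipped as plain TSV under `extdata`.
#' Useful as the reference for structural checks: the per-quintile totals
#' sum to the test-set size, and the ratio of the top to the bottom
#' quintile's published odds ratio is the "nine-fold" headline. Note the
#' published odds-ratio column is reported as printed; it is not reproduced
#' exactly by the package's own population-reference formula applied to the
#' printed counts (see [quintile_odds_ratios()] for the formula this package
#' uses and documents).
#'
#' @return data.frame: `quintile`, `n_cases`, `n_controls`, `n_total`,
#'   `odds_ratio`, `ci_low`, `ci_high`.
#' @export
published_quintile_table <- function() {
  utils::read.delim(system.file("extdata", "published_quintile_table.tsv",
                                package = "cslv"))
}
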
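# Independent brute-force oracles used to cross-check the implementation.

# all-pairs Mann-Whitney AUC: loop over every (case, control) pair
brute_auc <- function(labels, scores) {
  y <- tolower(as.character(labels)) %in% c("case", "1", "true")
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# triple-loop CSLV: for every sample, segment, marker
brute_cslv <- function(lrr, manifest, segments) {
  out <- matrix(NA_real_, nrow(lrr), nrow(segments),
                dimnames = list(rownames(lrr), segments$feature))
  for (s in seq_len(nrow(lrr))) {
    for (g in seq_len(nrow(segments))) {
      vals <- c()
      for (m in seq_len(nrow(manifest))) {
        if (manifest$chrom[m] == segments$chrom[g] &&
            manifest$position[m] >= segments$start[g] &&
            manifest$position[m] < segments$end[g]) {
          v <- lrr[s, manifest$marker_id[m]]
          if (!is.na(v)) vals <- c(vals, v)
        }
      }
      if (length(vals) >= 1) out[s, g] <- mean(vals)
    }
  }
  out
}

# 2x2 odds ratio vs whole population, by direct arithmetic
brute_or <- function(a, b, A, B) (a / b) / (A / B)

# analytic best AUC for one feature with equal-variance Gaussian classes
gaussian_auc <- function(delta, sd) pnorm(abs(delta) / (sd * sqrt(2)))

# tiny deterministic manifest/LRR fixture on a toy build
toy_build <- function(lengths = c(100, 200)) {
  cslv::genome_build(data.frame(chrom = as.character(seq_along(lengths)),
                                length = lengths))
}

toy_manifest <- function(build, positions) {
  # positions: named list chrom -> integer vector
  rows <- do.call(rbind, lapply(names(positions), function(ch)
    data.frame(marker_id = sprintf("m%s_%02d", ch, seq_along(positions[[ch]])),
               chrom = ch, position = positions[[ch]], stringsAsFactors = FALSE)))
  rows <- rows[order(match(rows$chrom, build$chrom), rows$position, rows$marker_id), ]
  rownames(rows) <- NULL
  class(rows) <- c("marker_manifest", "data.frame")
  rows
}

toy_lrr <- function(manifest, values) {
  # values: matrix or vector recycled; rows = samples
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  dimnames(values) <- list(sprintf("s%02d", seq_len(nrow(values))), manifest$marker_id)
  values
}

toy_cohort <- function(n_cases, n_controls, case_ages = 60, control_ages = 55,
                       groups = "unknown") {
  n <- n_cases + n_controls
  cslv::cohort_table(data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    label = c(rep("case", n_cases), rep("control", n_controls)),
    age = c(rep_len(case_ages, n_cases), rep_len(control_ages, n_controls)),
    group = rep_len(groups, n), stringsAsFactors = FALSE))
}
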
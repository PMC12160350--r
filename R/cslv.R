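#' Partition autosomes into equal-length segments
#'
#' Each chromosome of length L is divided into `k` half-open intervals
#' `[start_i, end_i)` with `start_i = 1 + round((i-1) * L / k)` and
#' `end_i = 1 + round(i * L / k)`, so the k intervals tile `[1, L + 1)` with
#' no gap or overlap and their bp spans differ by at most 1. Markers are
#' assigned by half-open interval membership. "Equal length" means equal bp
#' span by default; `by = "markers"` instead splits each chromosome's sorted
#' markers into k blocks of near-equal count.
#'
#' @param build a [genome_build()].
#' @param manifest validated [read_manifest()] output.
#' @param k segments per chromosome (integer >= 1).
#' @param by "bp" (default, equal base-pair span) or "markers" (equal marker
#'   count).
#' @return `segment_map`: list with `k`, `segments` (data.frame: `feature`,
#'   `chrom`, `index`, `start`, `end`, `n_markers`) and `assignment` (named
#'   character vector mapping marker_id -> feature name).
#' @examples
#' b <- default_genome_build()
#' @export
build_segments <- function(build, manifest, k, by = c("bp", "markers")) {
  by <- match.arg(by)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k))
    stop_cslv("k must be an integer >= 1")
  k <- as.integer(k)
  seg_list <- vector("list", nrow(build))
  assign_list <- vector("list", nrow(build))
  for (ci in seq_len(nrow(build))) {
    chrom <- build$chrom[ci]; L <- build$length[ci]
    mk <- manifest[manifest$chrom == chrom, , drop = FALSE]
    if (by == "bp") {
      bounds <- 1 + round((0:k) * L / k)
      idx <- if (nrow(mk)) findInterval(mk$position, bounds, left.open = FALSE) else integer(0)
    } else {
      # equal marker count: boundaries between consecutive marker blocks
      nm <- nrow(mk)
      sizes <- rep(nm %/% k, k) + (seq_len(k) <= nm %% k)
      idx <- rep(seq_len(k), sizes)
      cuts <- cumsum(sizes)
      inner <- if (nm) mk$position[pmin(cuts, nm)] + 1 else rep(1, k)
      bounds <- c(1, utils::head(inner, k - 1), L + 1)
      bounds <- cummax(bounds)  # guard empty blocks
    }
    seg_list[[ci]] <- data.frame(
      feature = sprintf("%s_seg%d", chrom, seq_len(k)),
      chrom = chrom, index = seq_len(k),
      start = bounds[seq_len(k)], end = bounds[seq_len(k) + 1],
      n_markers = tabulate(idx, nbins = k),
      stringsAsFactors = FALSE)
    if (nrow(mk))
      assign_list[[ci]] <- stats::setNames(sprintf("%s_seg%d", chrom, idx), mk$marker_id)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  structure(list(k = k, by = by, segments = segments,
                 assignment = do.call(c, assign_list)),
            class = "segment_map")
}

#' Compute CSLV features: mean LRR per chromosome segment
#'
#' The chromosomal-scale length variation (CSLV) feature for a segment is the
#' arithmetic mean of the non-missing LRR values of the markers falling in
#' that segment: near 0 for two copies, negative under deletion burden,
#' positive under duplication burden. A feature is missing for a sample when
#' fewer than `min_markers` non-missing values are available; segments with
#' no manifest markers at all yield a missing feature for every sample (one
#' warning).
#'
#' @param lrr samples x markers LRR matrix ([read_lrr()]).
#' @param segmap a [build_segments()] segment map.
#' @param min_markers minimum non-missing markers for a defined feature
#'   (default 1).
#' @return data.frame: `sample_id` then one numeric column per segment
#'   feature (`<chrom>_seg<i>`), 22*k columns for the default build.
#' @export
compute_cslv <- function(lrr, segmap, min_markers = 1) {
  feats <- segmap$segments$feature
  known <- names(segmap$assignment)
  if (length(setdiff(colnames(lrr), known)))
    stop_cslv("LRR matrix contains markers absent from the segment map")
  n <- nrow(lrr)
  out <- matrix(NA_real_, n, length(feats), dimnames = list(rownames(lrr), feats))
  seg_of <- segmap$assignment[colnames(lrr)]
  empty <- 0L
  for (j in seq_along(feats)) {
    cols <- which(seg_of == feats[j])
    if (!length(cols)) { empty <- empty + 1L; next }
    sub <- lrr[, cols, drop = FALSE]
    nm <- rowSums(!is.na(sub))
    v <- rowMeans(sub, na.rm = TRUE)
    v[nm < min_markers | !is.finite(v)] <- NA_real_
    out[, j] <- v
  }
  if (empty > 0)
    warning(sprintf("compute_cslv: %d segment(s) contain no markers; features set to missing", empty))
  data.frame(sample_id = rownames(lrr), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram summary of one CSLV feature across samples
#'
#' Deterministic fixed-width binning of a feature's distribution, the
#' population-level view of relative chromosome-segment length.
#'
#' @param cslv CSLV feature table ([compute_cslv()]).
#' @param feature feature column name.
#' @param bin_width histogram bin width on the LRR scale (default 0.01).
#' @return list: `breaks`, `counts`, `mids`, `mean`, `sd`, `n` (non-missing
#'   samples; counts sum to `n`).
#' @export
summarize_distribution <- function(cslv, feature, bin_width = 0.01) {
  if (!feature %in% names(cslv)) stop_cslv("unknown feature '%s'", feature)
  x <- cslv[[feature]]
  x <- x[!is.na(x)]
  if (!length(x)) stop_cslv("feature '%s' is missing for every sample", feature)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < max(x)) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = length(breaks) - 1)
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       mean = mean(x), sd = stats::sd(x), n = length(x))
}
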
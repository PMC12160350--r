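#' Configuration for the synthetic LRR cohort simulator
#'
#' The simulator emulates, at desk scale, a genotyping-array case/control
#' cohort: markers placed uniformly along the 22 autosomes, per-marker
#' Gaussian intensity noise, a per-sample baseline shift (array-level
#' normalisation offset), background copy-number events placed at random,
#' and designated *effect regions* where event probability differs between
#' cases and controls (and optionally between population groups). CNV events
#' shift the LRR of every covered marker additively — deletions down
#' (default -0.5), duplications up (default +0.3), typical array-intensity
#' magnitudes.
#'
#' @param seed master integer seed; all randomness derives from it through
#'   separate sub-streams (manifest, samples, events, noise), so the marker
#'   manifest does not change when sample counts change.
#' @param n_cases,n_controls cohort sizes.
#' @param markers_per_chrom markers simulated per autosome (default 500).
#' @param sigma_marker per-marker LRR noise sd (default 0.15).
#' @param sigma_sample per-sample baseline shift sd (default 0.02).
#' @param background_cnv_rate expected background CNV events per genome
#'   (Poisson; default 2).
#' @param cnv_mean_length mean background event length in bp (exponential;
#'   default 1e7).
#' @param deletion_shift,duplication_shift LRR shifts of background events
#'   (chosen with equal probability).
#' @param effect_regions NULL or data.frame with columns `chrom`, `start`,
#'   `end` (half-open bp interval), `case_prob`, `control_prob`, `shift`, and
#'   optionally `group` (NA = applies to all groups).
#' @param groups NULL (single group "unknown") or data.frame with columns
#'   `group`, `proportion` (must sum to 1).
#' @param age_case,age_control mean/sd of age by label (years, truncated at
#'   18).
#' @param build genome build (default [default_genome_build()]).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_cases = 200L, n_controls = 600L,
                       markers_per_chrom = 500L, sigma_marker = 0.15,
                       sigma_sample = 0.02, background_cnv_rate = 2,
                       cnv_mean_length = 1e7,
                       deletion_shift = -0.5, duplication_shift = 0.3,
                       effect_regions = NULL, groups = NULL,
                       age_case = c(62, 10), age_control = c(58, 12),
                       build = default_genome_build()) {
  if (!is.null(groups)) {
    if (abs(sum(groups$proportion) - 1) > 1e-8) stop_cslv("group proportions must sum to 1")
  }
  if (!is.null(effect_regions)) {
    p <- c(effect_regions$case_prob, effect_regions$control_prob)
    if (any(p < 0 | p > 1)) stop_cslv("effect probabilities must lie in [0, 1]")
    if (is.null(effect_regions$group)) effect_regions$group <- NA_character_
  }
  if (sigma_marker < 0 || sigma_sample < 0) stop_cslv("noise sds must be >= 0")
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 markers_per_chrom = as.integer(markers_per_chrom),
                 sigma_marker = sigma_marker, sigma_sample = sigma_sample,
                 background_cnv_rate = background_cnv_rate,
                 cnv_mean_length = cnv_mean_length,
                 deletion_shift = deletion_shift,
                 duplication_shift = duplication_shift,
                 effect_regions = effect_regions, groups = groups,
                 age_case = age_case, age_control = age_control,
                 build = build),
            class = "sim_config")
}

#' Simulate a synthetic LRR cohort with known CNV ground truth
#'
#' Marker-level model:
#' `LRR[s, j] = baseline_s + sum(shifts of events covering marker j) + N(0, sigma_marker)`.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list: `manifest` (marker_manifest), `lrr` (samples x markers
#'   matrix), `cohort` (cohort_table), `truth` (data.frame of placed events:
#'   `sample_id`, `chrom`, `start`, `end`, `shift`, `source`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  if (n < 1 || config$markers_per_chrom < 1) stop_cslv("need at least one sample and one marker")
  seeds <- substream_seeds(config$seed, 4)
  build <- config$build

  # -- manifest sub-stream ---------------------------------------------------
  set.seed(seeds[1])
  man <- do.call(rbind, lapply(seq_len(nrow(build)), function(ci) {
    pos <- sort(sample.int(build$length[ci], config$markers_per_chrom))
    data.frame(marker_id = sprintf("m%s_%04d", build$chrom[ci], seq_along(pos)),
               chrom = build$chrom[ci], position = pos, stringsAsFactors = FALSE)
  }))
  man <- man[order(match(man$chrom, build$chrom), man$position, man$marker_id), ]
  rownames(man) <- NULL
  class(man) <- c("marker_manifest", "data.frame")

  # -- sample sub-stream -----------------------------------------------------
  set.seed(seeds[2])
  ids <- sprintf("S%05d", seq_len(n))
  case <- c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls))
  grp <- if (is.null(config$groups)) rep("unknown", n) else
    sample(config$groups$group, n, replace = TRUE, prob = config$groups$proportion)
  rage <- function(k, ms) pmax(18, stats::rnorm(k, ms[1], ms[2]))
  age <- numeric(n)
  age[case] <- rage(sum(case), config$age_case)
  age[!case] <- rage(sum(!case), config$age_control)
  baseline <- stats::rnorm(n, 0, config$sigma_sample)
  cohort <- cohort_table(data.frame(sample_id = ids,
                                    label = ifelse(case, "case", "control"),
                                    age = round(age), group = grp,
                                    stringsAsFactors = FALSE))

  # -- event sub-stream ------------------------------------------------------
  set.seed(seeds[3])
  ev <- vector("list", n)
  for (s in seq_len(n)) {
    evs <- list()
    nb <- stats::rpois(1, config$background_cnv_rate)
    if (nb > 0) {
      ci <- sample.int(nrow(build), nb, replace = TRUE, prob = build$length)
      for (e in seq_len(nb)) {
        L <- build$length[ci[e]]
        len <- max(1, round(stats::rexp(1, 1 / config$cnv_mean_length)))
        st <- sample.int(L, 1)
        sh <- if (stats::runif(1) < 0.5) config$deletion_shift else config$duplication_shift
        evs[[length(evs) + 1]] <- data.frame(chrom = build$chrom[ci[e]], start = st,
                                             end = min(st + len, L + 1), shift = sh,
                                             source = "background")
      }
    }
    er <- config$effect_regions
    if (!is.null(er)) {
      for (r in seq_len(nrow(er))) {
        if (!is.na(er$group[r]) && er$group[r] != grp[s]) next
        p <- if (case[s]) er$case_prob[r] else er$control_prob[r]
        if (stats::runif(1) < p)
          evs[[length(evs) + 1]] <- data.frame(chrom = er$chrom[r], start = er$start[r],
                                               end = er$end[r], shift = er$shift[r],
                                               source = "effect")
      }
    }
    ev[[s]] <- if (length(evs)) cbind(sample_id = ids[s], do.call(rbind, evs)) else NULL
  }
  truth <- do.call(rbind, ev)
  if (is.null(truth))
    truth <- data.frame(sample_id = character(), chrom = character(), start = numeric(),
                        end = numeric(), shift = numeric(), source = character())
  rownames(truth) <- NULL

  # -- noise sub-stream + assembly ------------------------------------------
  set.seed(seeds[4])
  M <- nrow(man)
  lrr <- matrix(stats::rnorm(n * M, 0, config$sigma_marker), n, M,
                dimnames = list(ids, man$marker_id))
  lrr <- lrr + baseline
  if (nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      cover <- man$chrom == truth$chrom[r] &
        man$position >= truth$start[r] & man$position < truth$end[r]
      if (any(cover))
        lrr[truth$sample_id[r], cover] <- lrr[truth$sample_id[r], cover] + truth$shift[r]
    }
  }
  list(manifest = man, lrr = lrr, cohort = cohort, truth = truth)
}

#' Feature names overlapped by the configured effect regions
#'
#' Maps each effect region to the `<chrom>_seg<i>` features whose half-open
#' interval it overlaps — the ground-truth answer key for feature-recovery
#' checks.
#'
#' @param config a [sim_config()].
#' @param segmap segment map built from the simulated manifest.
#' @return character vector of feature names (segment order); empty when no
#'   effect regions are configured.
#' @export
effect_segment_index <- function(config, segmap) {
  er <- config$effect_regions
  if (is.null(er) || nrow(er) == 0) return(character(0))
  segs <- segmap$segments
  build <- config$build
  hits <- logical(nrow(segs))
  for (r in seq_len(nrow(er))) {
    ci <- match(er$chrom[r], build$chrom)
    if (is.na(ci)) stop_cslv("effect region chromosome '%s' not in build", er$chrom[r])
    if (er$start[r] < 1 || er$end[r] > build$length[ci] + 1 || er$start[r] >= er$end[r])
      stop_cslv("effect region [%s, %s) outside chromosome %s",
                format(er$start[r]), format(er$end[r]), er$chrom[r])
    hits <- hits | (segs$chrom == er$chrom[r] & segs$start < er$end[r] & segs$end > er$start[r])
  }
  segs$feature[hits]
}
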
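#' Read and validate a marker manifest
#'
#' A manifest places each array marker on the genome. Records on sex
#' chromosomes are dropped (with a reported count): CSLV features use
#' autosomes only. Records on chromosomes absent from the build, or with a
#' position outside `[1, chromosome length]`, are likewise dropped and
#' counted. The returned manifest is sorted by chromosome (build order), then
#' position, then marker id (tie-break), which defines the canonical marker
#' order used by all downstream readers.
#'
#' @param path TSV with header columns `marker_id`, `chromosome`, `position`
#'   (1-based bp).
#' @param build a [genome_build()]; default [default_genome_build()].
#' @param quiet suppress the drop-count message.
#' @return data.frame (`marker_manifest`) with columns `marker_id`, `chrom`,
#'   `position`; attribute `dropped` holds named counts
#'   (`sex_chrom`, `unknown_chrom`, `out_of_range`).
#' @export
read_manifest <- function(path, build = default_genome_build(), quiet = FALSE) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(raw)))
    stop_cslv("manifest %s is missing columns: %s", path,
              paste(setdiff(need, names(raw)), collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- which(!is.finite(pos) | pos != floor(pos))
  if (length(bad))
    stop_cslv("manifest row %d: unparseable position '%s'", bad[1], raw$position[bad[1]])
  if (anyDuplicated(raw$marker_id)) {
    d <- raw$marker_id[duplicated(raw$marker_id)][1]
    stop_cslv("duplicate marker_id '%s' in manifest", d)
  }
  m <- data.frame(marker_id = raw$marker_id, chrom = raw$chromosome,
                  position = pos, stringsAsFactors = FALSE)
  is_sex <- m$chrom %in% .SEX_CHROMS
  unknown <- !is_sex & !(m$chrom %in% build$chrom)
  zero <- which(!is_sex & !unknown & m$position < 1)
  if (length(zero))
    stop_cslv("manifest row %d (marker '%s'): position %d violates 1-based coordinates",
              zero[1], m$marker_id[zero[1]], m$position[zero[1]])
  len <- build$length[match(m$chrom, build$chrom)]
  out_of_range <- !is_sex & !unknown & m$position > len
  dropped <- c(sex_chrom = sum(is_sex), unknown_chrom = sum(unknown),
               out_of_range = sum(out_of_range, na.rm = TRUE))
  m <- m[!is_sex & !unknown & !out_of_range, , drop = FALSE]
  if (!quiet && sum(dropped) > 0)
    message(sprintf("read_manifest: dropped %d sex-chromosome, %d unknown-chromosome, %d out-of-range marker(s)",
                    dropped[1], dropped[2], dropped[3]))
  m <- m[order(match(m$chrom, build$chrom), m$position, m$marker_id), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "dropped") <- dropped
  class(m) <- c("marker_manifest", "data.frame")
  m
}

#' Write a marker manifest as TSV
#'
#' Emits the on-disk column layout expected by [read_manifest()]
#' (`marker_id`, `chromosome`, `position`).
#'
#' @param manifest a `marker_manifest`.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(
    data.frame(marker_id = manifest$marker_id, chromosome = manifest$chrom,
               position = manifest$position),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LRR matrix (wide or long dialect)
#'
#' Wide dialect: one row per sample, first column `sample_id`, one column per
#' marker. Long dialect mirrors Illumina GenomeStudio final-report columns:
#' `sample_id`, `marker_id`, `lrr` (a configurable number of header lines may
#' be skipped first). Markers not present in the manifest are dropped with a
#' warning; columns are returned in manifest order. Empty fields and "NA" are
#' missing values; any other non-numeric token is an error.
#'
#' @param path TSV file.
#' @param dialect "wide" or "long".
#' @param manifest validated [read_manifest()] output.
#' @param max_missing maximum tolerated overall fraction of missing LRR
#'   values (default 0.2); above it the dataset is rejected.
#' @param skip number of lines to skip before the header (long dialect).
#' @return numeric matrix, samples in rows (rownames = sample ids), markers
#'   in columns (manifest order).
#' @export
read_lrr <- function(path, dialect = c("wide", "long"), manifest,
                     max_missing = 0.2, skip = 0) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                            colClasses = list(character = 1), data.table = FALSE)
    if (names(dt)[1] != "sample_id") stop_cslv("wide LRR file must start with a sample_id column")
    if (anyDuplicated(dt$sample_id)) stop_cslv("duplicate sample_id in wide LRR file")
    ids <- dt$sample_id
    vals <- dt[, -1, drop = FALSE]
    unknown <- setdiff(names(vals), manifest$marker_id)
    if (length(unknown)) {
      warning(sprintf("read_lrr: dropped %d column(s) not in manifest", length(unknown)))
      vals <- vals[, setdiff(names(vals), unknown), drop = FALSE]
    }
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) stop_cslv("non-numeric LRR values in column '%s'", names(vals)[bad][1])
    mat <- as.matrix(vals)
    rownames(mat) <- ids
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = skip,
                            na.strings = c("", "NA"), data.table = TRUE)
    names(dt) <- sub("^Sample ID$", "sample_id", names(dt))
    names(dt) <- sub("^SNP Name$", "marker_id", names(dt))
    names(dt) <- sub("^Log R Ratio$", "lrr", names(dt))
    need <- c("sample_id", "marker_id", "lrr")
    if (!all(need %in% names(dt)))
      stop_cslv("long LRR file is missing columns: %s", paste(setdiff(need, names(dt)), collapse = ", "))
    if (!is.numeric(dt$lrr)) {
      tok <- dt$lrr[is.na(suppressWarnings(as.numeric(dt$lrr))) & !is.na(dt$lrr)][1]
      stop_cslv("non-numeric LRR value '%s' in long file", tok)
    }
    dup <- duplicated(paste(dt$sample_id, dt$marker_id, sep = "\r"))
    if (any(dup))
      stop_cslv("duplicate (sample, marker) entry: (%s, %s)",
                dt$sample_id[dup][1], dt$marker_id[dup][1])
    unknown <- setdiff(unique(dt$marker_id), manifest$marker_id)
    if (length(unknown)) {
      warning(sprintf("read_lrr: dropped %d marker(s) not in manifest", length(unknown)))
      dt <- dt[!dt$marker_id %in% unknown, ]
    }
    wide <- data.table::dcast(dt, sample_id ~ marker_id, value.var = "lrr")
    ids <- wide$sample_id
    mat <- as.matrix(wide[, -1, drop = FALSE])
    rownames(mat) <- ids
  }
  keep <- intersect(manifest$marker_id, colnames(mat))
  mat <- mat[, keep, drop = FALSE]
  frac_na <- mean(is.na(mat))
  if (frac_na > max_missing)
    stop_cslv("fraction of missing LRR values (%.3f) exceeds ceiling %.3f", frac_na, max_missing)
  mat
}

#' Write an LRR matrix as wide TSV
#' @param lrr samples x markers matrix with dimnames.
#' @param path output path.
#' @export
write_lrr <- function(lrr, path) {
  dt <- data.table::data.table(sample_id = rownames(lrr))
  dt <- cbind(dt, data.table::as.data.table(lrr))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype / cohort table
#'
#' @param path TSV with header columns `sample_id`, `label` (case/control or
#'   1/0), `age` (years), and optionally `group` (self-identified group label;
#'   missing values become "unknown").
#' @return `cohort_table` data.frame with columns `sample_id`, `label`
#'   (factor case/control), `age`, `group`.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "label", "age")
  if (!all(need %in% names(x)))
    stop_cslv("phenotype file is missing columns: %s", paste(setdiff(need, names(x)), collapse = ", "))
  cohort_table(data.frame(
    sample_id = x$sample_id,
    label = x$label,
    age = as.numeric(x$age),
    group = if ("group" %in% names(x)) x$group else "unknown",
    stringsAsFactors = FALSE))
}

#' Construct and validate a cohort table
#'
#' @param x data.frame with columns `sample_id`, `label`, `age` and
#'   optionally `group`.
#' @return validated `cohort_table` data.frame.
#' @export
cohort_table <- function(x) {
  if (anyDuplicated(x$sample_id)) stop_cslv("duplicate sample_id in cohort table")
  case <- as_case(x$label)
  if (any(!is.finite(x$age)) || any(x$age < 0)) stop_cslv("ages must be finite and >= 0")
  out <- data.frame(sample_id = as.character(x$sample_id),
                    label = factor(ifelse(case, "case", "control"), levels = c("control", "case")),
                    age = as.numeric(x$age),
                    group = if (is.null(x$group)) "unknown" else {
                      g <- as.character(x$group); g[is.na(g) | g == ""] <- "unknown"; g
                    },
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table as TSV
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a CSLV feature table
#'
#' TSV with `sample_id` then one column per segment feature, named
#' `<chrom>_seg<i>`. The pair round-trips losslessly (missing values written
#' as "NA").
#'
#' @param table CSLV feature data.frame (first column `sample_id`).
#' @param path output path.
#' @export
write_cslv <- function(table, path) {
  stopifnot(names(table)[1] == "sample_id")
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cslv
#' @export
read_cslv <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                         colClasses = c(sample_id = "character"))
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Validate consistency between manifest, LRR matrix, and phenotypes
#'
#' @param manifest [read_manifest()] output.
#' @param lrr LRR matrix.
#' @param cohort `cohort_table` or NULL.
#' @return invisibly TRUE; errors describe the first inconsistency.
#' @export
validate_inputs <- function(manifest, lrr, cohort = NULL) {
  extra <- setdiff(colnames(lrr), manifest$marker_id)
  if (length(extra)) stop_cslv("%d LRR marker(s) absent from manifest (first: %s)",
                               length(extra), extra[1])
  if (!is.null(cohort)) {
    missing <- setdiff(cohort$sample_id, rownames(lrr))
    if (length(missing)) stop_cslv("%d cohort sample(s) absent from LRR matrix (first: %s)",
                                   length(missing), missing[1])
  }
  invisible(TRUE)
}
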
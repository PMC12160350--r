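#' Default human autosome genome build
#'
#' Assembly lengths of the 22 human autosomes (GRCh38). Only autosomes are
#' included: intensity data from the X and Y chromosomes is excluded from
#' CSLV feature computation throughout the package, so the build is the
#' coordinate frame for segmentation of chromosomes "1".."22".
#'
#' @return A `genome_build`: data.frame with columns `chrom` (character,
#'   "1".."22") and `length` (bp, numeric).
#' @examples
#' b <- default_genome_build()
#' nrow(b)  # 22
#' @export
default_genome_build <- function() {
  lengths <- c(
    248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
    159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
    114364328, 107043718, 101991189,  90338345,  83257441,  80373285,
     58617616,  64444167,  46709983,  50818468)
  genome_build(data.frame(chrom = as.character(1:22), length = lengths))
}

#' Construct and validate a genome build
#'
#' @param x data.frame with columns `chrom` and `length`.
#' @return validated `genome_build` data.frame.
#' @export
genome_build <- function(x) {
  if (!all(c("chrom", "length") %in% names(x)))
    stop_cslv("genome build needs columns 'chrom' and 'length'")
  x$chrom <- as.character(x$chrom)
  x$length <- as.numeric(x$length)
  if (anyDuplicated(x$chrom)) stop_cslv("duplicate chromosome names in build")
  if (any(!is.finite(x$length)) || any(x$length <= 0))
    stop_cslv("chromosome lengths must be positive")
  rownames(x) <- NULL
  class(x) <- c("genome_build", "data.frame")
  x
}

#' Read a genome build from TSV
#'
#' @param path TSV with header columns `chrom`, `length`.
#' @return `genome_build` data.frame.
#' @export
read_genome_build <- function(path) {
  genome_build(utils::read.delim(path, colClasses = c("character", "numeric")))
}

# chromosome names conventionally treated as sex chromosomes
.SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24", "XY", "MT", "M")
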
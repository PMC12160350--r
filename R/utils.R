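`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_cslv <- function(...) stop(sprintf(...), call. = FALSE)

#' Draw reproducible sub-stream seeds from one master seed
#'
#' Seeding each stage of a computation from an independent sub-stream keeps
#' upstream artifacts (e.g. a simulated marker manifest) bit-identical when a
#' downstream size parameter (e.g. number of samples) changes.
#'
#' @param seed master integer seed.
#' @param n number of sub-stream seeds to draw.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# binary label vector (TRUE = case) from a cohort label column
as_case <- function(label) {
  if (is.logical(label)) return(label)
  lab <- tolower(as.character(label))
  if (all(lab %in% c("case", "control"))) return(lab == "case")
  if (all(lab %in% c("0", "1", "true", "false"))) return(lab %in% c("1", "true"))
  stop_cslv("labels must be case/control, 0/1 or logical; got: %s",
            paste(utils::head(unique(lab), 5), collapse = ", "))
}
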
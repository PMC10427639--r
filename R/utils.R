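#' Map chromosome-arm labels to chromosome classes
#'
#' The four autosomal arms (2R, 2L, 3R, 3L) collapse to class `"autosome"`;
#' the X, the (collapsed) Y contigs and the mitochondrial genome keep their
#' own class; anything else becomes `"UNKNOWN"`.
#'
#' @param arm character vector of arm labels.
#' @return character vector of classes, one of
#'   `c("autosome", "X", "Y", "MT", "UNKNOWN")`.
#' @examples
#' armToClass(c("2R", "X", "weird"))
#' @export
armToClass <- function(arm) {
  cls <- rep("UNKNOWN", length(arm))
  cls[arm %in% c("2R", "2L", "3R", "3L")] <- "autosome"
  cls[arm == "X"] <- "X"
  cls[arm == "Y"] <- "Y"
  cls[arm == "MT"] <- "MT"
  cls
}

#' @keywords internal
.chromClasses <- c("autosome", "X", "Y", "MT")

#' @keywords internal
.chromArms <- c("2R", "2L", "3R", "3L", "X", "Y", "MT")

# counts accessor that tolerates plain SummarizedExperiment input
#' @keywords internal
.counts <- function(x) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  SummarizedExperiment::assay(x, "counts")
}

#' @keywords internal
.logcounts <- function(x) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(x)) {
    stop("no 'logcounts' assay; run normalizeLog() first")
  }
  SummarizedExperiment::assay(x, "logcounts")
}

# run expr with a private RNG stream; restores the caller's .Random.seed
#' @keywords internal
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
.checkWholeNumber <- function(x, what) {
  if (any(!is.finite(x)) || any(x != round(x))) {
    stop(what, " must be whole numbers")
  }
  invisible(TRUE)
}
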
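#' Define an ordered ROI label set
#'
#' The ROI set fixes the canonical row/column order of every matrix in the
#' pipeline: connectivity matrices, adjacency matrices and representational
#' dissimilarity matrices are all indexed by these labels in this order.
#'
#' @param labels character vector of unique region labels, or a single
#'   integer `n` to generate `ROI01 .. ROIn` (default 43, the size of the
#'   associative-cortex parcellation the pipeline was designed around).
#' @return character vector of class `roi_set`.
#' @export
#' @examples
#' roi_set(5)
#' roi_set(c("BA44", "BA45", "ATL"))
roi_set <- function(labels = 43L) {
  if (is.numeric(labels) && length(labels) == 1L) {
    n <- as.integer(labels)
    if (is.na(n) || n < 2L) stop("an ROI set needs at least 2 regions", call. = FALSE)
    labels <- sprintf("ROI%02d", seq_len(n))
  }
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  if (length(labels) < 2L) stop("an ROI set needs at least 2 regions", call. = FALSE)
  structure(labels, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set with", length(x), "regions:",
      paste(utils::head(unclass(x), 4), collapse = ", "),
      if (length(x) > 4) "..." else "", "\n")
  invisible(x)
}
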
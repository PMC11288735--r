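#' Length of a genomic interval
#'
#' Interval coordinates throughout the package are 1-based and inclusive on
#' both ends, so a span runs from \code{start} to \code{end} and covers
#' \code{end - start + 1} bp. The representative full-length element on
#' chromosome 11 at 10,103,867..10,109,980 therefore spans 6,114 bp.
#'
#' @param start,end Interval bounds, 1-based inclusive. Alternatively
#'   \code{start} may be a \link[GenomicRanges]{GRanges} object, in which case
#'   \code{end} is ignored and a width per range is returned.
#' @return Integer span length(s) in bp.
#' @examples
#' spanLength(10103867, 10109980)  # 6114
#' @export
spanLength <- function(start, end) {
  if (methods::is(start, "GRanges"))
    return(GenomicRanges::width(start))
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval bounds must be finite numbers")
  if (any(end < start))
    stop("invalid interval: start > end")
  as.integer(end - start + 1)
}

#' Convert between internal 1-based inclusive and BED half-open coordinates
#'
#' BED files are 0-based, half-open; internally the package uses 1-based
#' inclusive coordinates. These helpers convert a (start, end) pair between
#' the two conventions and are the identity map when composed.
#'
#' @param start,end Interval bounds.
#' @return A list with elements \code{start} and \code{end} in the target
#'   convention.
#' @export
toBedCoords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname toBedCoords
#' @export
fromBedCoords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = as.integer(start + 1L), end = as.integer(end))
}
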
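# 1-based inclusive genomic coordinates, as printed for PCR amplicons.

#' Construct a genomic interval
#'
#' @param contig Contig/arm label, e.g. \code{"3L"}.
#' @param start,end 1-based inclusive coordinates.
#' @return A [GenomicInterval-class].
#' @examples
#' genomicInterval("3L", 15826279, 15827223)
#' @export
genomicInterval <- function(contig, start, end) {
  new("GenomicInterval", contig = as.character(contig),
      start = as.numeric(start), end = as.numeric(end))
}

#' Parse a coordinate string
#'
#' Understands the \code{"3L:15826279..15827223"} convention (and the
#' hyphen variant \code{"3L:15826279-15827223"}).
#'
#' @param text Coordinate string.
#' @return A [GenomicInterval-class].
#' @export
parseGenomicInterval <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^([A-Za-z0-9_]+):\\s*([0-9]+)(?:\\.\\.|-)([0-9]+)$", text))[[1]]
  if (length(m) == 0)
    stop(sprintf("malformed coordinate string '%s'", text), call. = FALSE)
  genomicInterval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Length of a genomic interval in base pairs
#'
#' Both endpoints are included: \code{end - start + 1}. The 945 bp candidate
#' region 3L:15826279..15827223 is the canonical worked example.
#'
#' @param x A [GenomicInterval-class] (or anything coercible via
#'   [parseGenomicInterval()] when given as a string).
#' @return Integer-valued length in bp.
#' @examples
#' intervalLength(parseGenomicInterval("3L:15826279..15827223"))  # 945
#' @export
intervalLength <- function(x) {
  if (is.character(x)) x <- parseGenomicInterval(x)
  stopifnot(is(x, "GenomicInterval"))
  x@end - x@start + 1
}

#' Format a genomic interval
#' @param x A [GenomicInterval-class].
#' @return String in \code{contig:start..end} form.
#' @export
formatGenomicInterval <- function(x) {
  stopifnot(is(x, "GenomicInterval"))
  sprintf("%s:%.0f..%.0f", x@contig, x@start, x@end)
}

setMethod("show", "GenomicInterval", function(object) {
  cat("GenomicInterval ", formatGenomicInterval(object),
      " (", format(intervalLength(object), big.mark = ","), " bp)\n", sep = "")
})
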
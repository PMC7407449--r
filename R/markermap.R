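# Marker maps: the visible recessive markers the cross is scored against.

#' Construct a marker map
#'
#' @param name Marker symbols (unique).
#' @param cm Map positions in centiMorgans, strictly increasing.
#' @param band Polytene band strings (see [parseCytoband()]).
#' @param chromosome Chromosome label.
#' @param recessive Logical vector (recycled): visible recessive phenotype?
#' @return A [MarkerMap-class].
#' @export
MarkerMap <- function(name, cm, band, chromosome = "3", recessive = TRUE) {
  df <- data.frame(name = as.character(name), cm = as.numeric(cm),
                   band = as.character(band),
                   recessive = rep_len(as.logical(recessive), length(name)),
                   stringsAsFactors = FALSE)
  new("MarkerMap", chromosome = as.character(chromosome), markers = df)
}

#' The standard rucuca chromosome-3 marker map
#'
#' The multiply marked chromosome used for recombination mapping carries
#' eight visible recessives: roughoid (ru), hairy (h), thread (th), scarlet
#' (st), curled (cu), stripe (sr), ebony (e) and claret (ca). Positions are
#' the standard D. melanogaster chromosome-3 map (ru 0.0, h 26.5, th 43.2,
#' st 44.0, cu 50.0, sr 62.0, e 70.7, ca 100.7 cM). Positions and bands are
#' package defaults and can be overridden by supplying a map file to
#' [readMarkerMap()].
#'
#' @return A [MarkerMap-class] with the eight markers.
#' @examples
#' rucucaMap()
#' @export
rucucaMap <- function() {
  MarkerMap(
    name = c("ru", "h", "th", "st", "cu", "sr", "e", "ca"),
    cm   = c(0.0, 26.5, 43.2, 44.0, 50.0, 62.0, 70.7, 100.7),
    band = c("61F1", "66D10", "72D1", "73A3", "86D2", "90E1", "93C7", "99B9"),
    chromosome = "3")
}

#' Read a marker map from TSV
#'
#' Expects a header \code{name  chrom  cm  band} (an optional
#' \code{recessive} column of TRUE/FALSE is honoured). Lines starting with
#' \code{#} are comments.
#'
#' @param file Path to the TSV file.
#' @return A [MarkerMap-class].
#' @export
readMarkerMap <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "chrom", "cm", "band")
  if (!all(need %in% names(df)))
    stop(sprintf("marker map file needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  chrom <- unique(df$chrom)
  if (length(chrom) != 1)
    stop("marker map file must describe a single chromosome", call. = FALSE)
  MarkerMap(df$name, df$cm, df$band, chromosome = as.character(chrom),
            recessive = if ("recessive" %in% names(df)) df$recessive else TRUE)
}

#' @describeIn markerNames Marker cM positions, named by marker.
#' @export
markerPositions <- function(map) {
  stopifnot(is(map, "MarkerMap"))
  setNames(map@markers$cm, map@markers$name)
}

#' Marker map accessors
#'
#' @param map A [MarkerMap-class].
#' @return \code{markerNames}: character vector of symbols in map order;
#'   \code{markerPositions}: named numeric cM positions;
#'   \code{markerBands}: named character band strings.
#' @export
markerNames <- function(map) {
  stopifnot(is(map, "MarkerMap"))
  map@markers$name
}

#' @describeIn markerNames Marker band strings, named by marker.
#' @export
markerBands <- function(map) {
  stopifnot(is(map, "MarkerMap"))
  setNames(map@markers$band, map@markers$name)
}

setMethod("length", "MarkerMap", function(x) nrow(x@markers))

setMethod("show", "MarkerMap", function(object) {
  cat("MarkerMap on chromosome ", object@chromosome, " with ",
      nrow(object@markers), " markers\n", sep = "")
  print(object@markers, row.names = FALSE)
})
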
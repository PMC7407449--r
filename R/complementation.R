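# Deficiency/allele complementation logic on the polytene band lattice.

.panelRanges <- function(panel, maxSubband) {
  need <- c("id", "arm", "del_start", "del_end", "outcome")
  if (!all(need %in% names(panel)))
    stop(sprintf("deficiency panel needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  arm <- unique(panel$arm)
  if (length(arm) != 1)
    stop("all deficiencies must lie on one arm", call. = FALSE)
  bad <- setdiff(unique(panel$outcome), c("fails", "complements"))
  if (length(bad))
    stop(sprintf("invalid outcome value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  rng <- t(vapply(seq_len(nrow(panel)), function(i) {
    iv <- new("CytoInterval",
              start = parseCytoband(panel$del_start[i], arm = arm),
              end = parseCytoband(panel$del_end[i], arm = arm))
    .latticeRange(iv, maxSubband)
  }, numeric(2)))
  list(arm = arm, lo = rng[, 1], hi = rng[, 2])
}

#' Solve the candidate region from a deficiency panel
#'
#' The locus must lie inside every deficiency that fails to complement and
#' outside every one that complements: the candidate region is the
#' intersection of the failing deleted intervals minus the union of the
#' complementing ones, computed on the discretized band lattice. If the
#' subtraction splits the region, every fragment is returned, widest first.
#'
#' @param panel \code{data.frame} with columns \code{id, arm, del_start,
#'   del_end, outcome} (\code{outcome} in \code{fails}/\code{complements});
#'   see [readDeficiencyPanel()] and [simulateDeficiencyPanel()].
#' @param maxSubband Sub-bands per letter assumed for the lattice (band
#'   endpoints lacking a sub-band span the whole letter).
#' @return A [CandidateRegion-class].
#' @examples
#' panel <- data.frame(
#'   id = c("DfA", "DfB", "DfC"), arm = "3L",
#'   del_start = c("71E1", "71F1", "72A2"),
#'   del_end = c("72B2", "72A1", "72D1"),
#'   outcome = c("fails", "fails", "complements"))
#' solveRegion(panel)  # 71F1-72A1
#' @export
solveRegion <- function(panel, maxSubband = 20L) {
  pr <- .panelRanges(panel, maxSubband)
  failing <- panel$outcome == "fails"
  if (!any(failing))
    stop("panel has no failing deficiency; nothing constrains the locus",
         call. = FALSE)
  fIdx <- which(failing)
  # pairwise-consistency check first: for 1-D intervals an empty overall
  # intersection always exposes a disjoint pair
  lo <- max(pr$lo[fIdx]); hi <- min(pr$hi[fIdx])
  if (lo > hi) {
    for (i in fIdx) for (j in fIdx) {
      if (i < j && (pr$lo[i] > pr$hi[j] || pr$lo[j] > pr$hi[i]))
        stop(sprintf(
          "inconsistent panel: failing deficiencies %s and %s do not overlap",
          panel$id[i], panel$id[j]), call. = FALSE)
    }
    stop("inconsistent panel: failing deficiencies share no band", call. = FALSE)
  }
  core <- IRanges(lo, hi)
  cIdx <- which(!failing)
  remaining <- if (length(cIdx)) {
    comp <- reduce(IRanges(pr$lo[cIdx], pr$hi[cIdx]))
    setdiff(core, comp)
  } else core
  if (length(remaining) == 0) {
    cover <- cIdx[pr$lo[cIdx] <= lo & pr$hi[cIdx] >= hi]
    stop(sprintf(
      "complementing deficiency(ies) cover the whole candidate region: %s",
      paste(panel$id[if (length(cover)) cover else cIdx], collapse = ", ")),
      call. = FALSE)
  }
  ord <- order(-width(remaining))
  intervals <- lapply(ord, function(k) {
    new("CytoInterval",
        start = .latticeBand(start(remaining)[k], pr$arm, maxSubband),
        end = .latticeBand(end(remaining)[k], pr$arm, maxSubband))
  })
  new("CandidateRegion", intervals = intervals,
      supporting = panel$id[fIdx], excluding = panel$id[cIdx],
      arm = pr$arm, maxSubband = as.integer(maxSubband))
}

setMethod("show", "CandidateRegion", function(object) {
  cat("CandidateRegion on ", object@arm, ": ",
      paste(vapply(object@intervals, formatCytoInterval, character(1)),
            collapse = " | "), "\n", sep = "")
  cat("  supported by ", length(object@supporting), " failing Df(s); ",
      length(object@excluding), " complementing Df(s) excluded\n", sep = "")
})

#' Primary candidate interval of a solved region
#' @param region A [CandidateRegion-class].
#' @return The widest [CytoInterval-class] fragment.
#' @export
regionInterval <- function(region) {
  stopifnot(is(region, "CandidateRegion"))
  region@intervals[[1]]
}

#' Allele-level complementation verdicts
#'
#' A gene is declared allelic to the mapped mutation when at least one of
#' its lethal alleles fails to complement it and the gene's band is
#' consistent with the candidate region. Consistency admits a tolerance:
#' with the default \code{radius = 1}, a band in a division adjacent to the
#' region is accepted, which matters because deficiency breakpoint grids
#' can bracket a region abutting the causal gene's band (a region ending at
#' 71F5 abuts a gene at 72A1).
#'
#' @param region A [CandidateRegion-class] from [solveRegion()].
#' @param tests \code{data.frame} with columns \code{gene, allele, outcome}
#'   (\code{fails}/\code{complements}); see [readAlleleTests()].
#' @param annotation \code{data.frame} with columns \code{gene, arm, band}
#'   giving each tested gene's polytene band.
#' @param radius Allowed distance in divisions between a gene's band and
#'   the region (0 = strictly inside).
#' @return \code{data.frame}: per gene, failing/complementing allele
#'   counts, band, whether the band is position-consistent, and the
#'   \code{allelic} verdict.
#' @export
checkAllelism <- function(region, tests, annotation, radius = 1) {
  stopifnot(is(region, "CandidateRegion"),
            all(c("gene", "allele", "outcome") %in% names(tests)),
            all(c("gene", "arm", "band") %in% names(annotation)))
  genes <- unique(tests$gene)
  missing <- setdiff(genes, annotation$gene)
  if (length(missing))
    stop(sprintf("tested gene(s) missing from annotation: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  rows <- lapply(genes, function(g) {
    tg <- tests[tests$gene == g, , drop = FALSE]
    ann <- annotation[match(g, annotation$gene), ]
    nFail <- sum(tg$outcome == "fails")
    nComp <- sum(tg$outcome == "complements")
    consistent <- FALSE
    if (identical(ann$arm, region@arm)) {
      band <- parseCytoband(ann$band, arm = ann$arm)
      idx <- .latticeIndex(band, region@maxSubband, "point")
      for (iv in region@intervals) {
        rng <- .latticeRange(iv, region@maxSubband)
        inside <- idx >= rng[1] && idx <= rng[2]
        nearDiv <- abs(band@division - iv@start@division) <= radius ||
          abs(band@division - iv@end@division) <= radius ||
          (band@division >= iv@start@division &&
             band@division <= iv@end@division)
        if (inside || (radius > 0 && nearDiv)) { consistent <- TRUE; break }
      }
    }
    data.frame(gene = g, n_fails = nFail, n_complements = nComp,
               band = ann$band, consistent = consistent,
               allelic = nFail >= 1 && consistent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a deficiency panel from TSV
#'
#' Columns \code{id, arm, del_start, del_end, outcome}.
#' @param file Path to the TSV.
#' @return \code{data.frame} for [solveRegion()].
#' @export
readDeficiencyPanel <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "arm", "del_start", "del_end", "outcome")
  if (!all(need %in% names(df)))
    stop(sprintf("deficiency panel file needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}

#' Read allele complementation tests from TSV
#'
#' Columns \code{gene, allele, outcome}.
#' @param file Path to the TSV.
#' @return \code{data.frame} for [checkAllelism()].
#' @export
readAlleleTests <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene", "allele", "outcome") %in% names(df)))
    stop("allele test file needs columns gene, allele, outcome", call. = FALSE)
  df
}

#' Read a gene-to-band annotation from TSV
#'
#' Columns \code{gene, arm, band}.
#' @param file Path to the TSV.
#' @return \code{data.frame} for [checkAllelism()].
#' @export
readGeneAnnotation <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene", "arm", "band") %in% names(df)))
    stop("annotation file needs columns gene, arm, band", call. = FALSE)
  df
}
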
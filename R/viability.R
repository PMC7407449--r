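# Stage-survival, fertility and rescue-cross accounting.

#' Stage-survival proportion
#'
#' Percentage surviving from one developmental stage to the next, e.g.
#' 313 pupae from 468 transferred larvae is 66.88\%.
#'
#' @param numerator Count at the later stage (vectorized).
#' @param denominator Count at the earlier stage (> 0).
#' @return Percent in [0, 100].
#' @examples
#' stageProportion(313, 468)
#' @export
stageProportion <- function(numerator, denominator) {
  if (any(denominator <= 0))
    stop("denominator must be positive", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  100 * numerator / denominator
}

#' Expected class counts under a Mendelian ratio model with lethal stages
#'
#' Given fertilization-class proportions and per-class, per-stage survival
#' probabilities (0 encoding balancer or homozygous lethality), the
#' expected count of each class at a stage is \code{n} times the
#' proportion times the cumulative survival. With
#' \code{conditional = TRUE}, \code{n} is the number of individuals
#' actually observed at the stage and the expectations are renormalized
#' over the surviving classes -- the convention of stage tables whose
#' percentages are relative to the previous stage. An intercross of
#' lethal/balancer parents with balancer homozygotes dying as embryos, for
#' instance, leaves hatched larvae in a 1:2 ratio (one third homozygous
#' non-balancer, two thirds balancer-heterozygous).
#'
#' @param classProportions Named numeric summing to 1.
#' @param stageSurvival Classes x stages matrix of survival probabilities
#'   (rownames = classes, colnames = stage labels).
#' @param n Total count (eggs if unconditional; individuals at
#'   \code{stage} if conditional).
#' @param stage Stage label (column of \code{stageSurvival}); omit for
#'   fertilization-stage expectations.
#' @param conditional Renormalize over classes surviving to \code{stage}?
#' @return Named numeric of expected counts per class.
#' @export
expectedClasses <- function(classProportions, stageSurvival = NULL, n,
                            stage = NULL, conditional = FALSE) {
  stopifnot(abs(sum(classProportions) - 1) < 1e-8, n >= 0)
  w <- classProportions
  if (!is.null(stage)) {
    stopifnot(!is.null(stageSurvival),
              identical(rownames(stageSurvival), names(classProportions)),
              stage %in% colnames(stageSurvival))
    upto <- seq_len(match(stage, colnames(stageSurvival)))
    cum <- apply(stageSurvival[, upto, drop = FALSE], 1, prod)
    w <- classProportions * cum
  }
  if (conditional) {
    if (sum(w) == 0) stop("no class survives to this stage", call. = FALSE)
    w <- w / sum(w)
  }
  n * w
}

#' Goodness of fit of observed class counts to expectations
#'
#' Pearson chi-square for three or more classes; exact binomial test for
#' two classes (expected counts fix the null proportion).
#'
#' @param observed Numeric vector of observed counts (length >= 2).
#' @param expected Numeric vector of expected counts (> 0, same length;
#'   rescaled to the observed total if needed).
#' @return List with \code{statistic} (the Pearson chi-square value, also
#'   reported alongside the exact test), \code{df}, \code{p.value} and
#'   \code{method}.
#' @examples
#' goodnessOfFit(c(60, 40), c(50, 50))
#' @export
goodnessOfFit <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2)
  if (any(expected <= 0))
    stop("expected counts must be positive for included classes", call. = FALSE)
  if (any(observed < 0)) stop("observed counts must be non-negative",
                              call. = FALSE)
  nObs <- sum(observed)
  expected <- expected * nObs / sum(expected)
  stat <- sum((observed - expected)^2 / expected)
  if (length(observed) == 2) {
    p0 <- expected[1] / nObs
    bt <- binom.test(observed[1], nObs, p = p0)
    return(list(statistic = stat, df = 1L,
                p.value = bt$p.value, method = "exact binomial"))
  }
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       method = "Pearson chi-square")
}

#' Arcsine square-root transform of a proportion
#'
#' The classical variance-stabilizing transform applied to percentage data
#' before parametric testing: \code{asin(sqrt(p))}, in radians; strictly
#' increasing on [0, 1] with range [0, pi/2].
#'
#' @param p Proportion(s) in [0, 1].
#' @return Transformed value(s) in radians.
#' @examples
#' arcsineSqrt(0.5)   # pi/4
#' @export
arcsineSqrt <- function(p) {
  if (any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Fertility summary with exact confidence interval
#'
#' Percent fertile pairs with a Clopper--Pearson interval.
#'
#' @param pairsFertile Number of fertile pairs.
#' @param pairsTotal Total pairs tested (> 0).
#' @param ciLevel Confidence level.
#' @return List with \code{percent}, \code{ci_low}, \code{ci_high} (percent
#'   scale) and \code{n}.
#' @examples
#' fertilitySummary(28, 70)   # 40 percent
#' @export
fertilitySummary <- function(pairsFertile, pairsTotal, ciLevel = 0.95) {
  if (pairsTotal <= 0) stop("pairsTotal must be positive", call. = FALSE)
  if (pairsFertile < 0 || pairsFertile > pairsTotal)
    stop("pairsFertile must lie in [0, pairsTotal]", call. = FALSE)
  ci <- .clopperPearson(pairsFertile, pairsTotal, ciLevel)
  list(percent = 100 * pairsFertile / pairsTotal,
       ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
       n = pairsTotal)
}

#' Read a stage-count table from TSV
#'
#' Long format: columns \code{class, stage, count}.
#'
#' @param file Path to the TSV.
#' @return \code{data.frame}.
#' @export
readStageCounts <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("class", "stage", "count") %in% names(df)))
    stop("stage-count file needs columns class, stage, count", call. = FALSE)
  df
}
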
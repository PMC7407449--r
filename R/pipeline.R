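# Orchestration: one reproducible, seed-driven run over the mapping stages,
# with per-stage JSON reports. Every stage is also an ordinary exported
# function, so scripts and tests can bypass the pipeline.

#' Read a pipeline configuration
#'
#' Configurations are JSON. Relative input paths are resolved against the
#' directory containing the config file.
#'
#' @param file Path to a JSON config.
#' @return Config list with attribute \code{"dir"}.
#' @seealso [runPipeline()] for the recognized fields.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file))
    stop(sprintf("config file not found: %s", file), call. = FALSE)
  cfg <- read_json(file, simplifyVector = TRUE)
  attr(cfg, "dir") <- dirname(normalizePath(file))
  cfg
}

.resolvePath <- function(path, dir) {
  if (is.null(path)) return(NULL)
  if (file.exists(path)) return(path)
  cand <- file.path(dir, path)
  cand
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(md5sum(tmp))
}

#' Run the mapping pipeline
#'
#' Executes the requested stages in order, writes one JSON result per stage
#' plus a human-readable \code{summary.txt} into the output directory, and
#' returns the stage results invisibly. Identical config and seed give
#' identical numeric outputs. Config fields:
#' \describe{
#'   \item{seed}{Integer; drives all randomness and is recorded in every
#'     report.}
#'   \item{out_dir}{Output directory (created if absent).}
#'   \item{stages}{Character vector from \code{simulate, map_rf, place,
#'     complementation, tiling, viability}.}
#'   \item{map_file}{Optional marker-map TSV; default [rucucaMap()].}
#'   \item{simulate}{\code{true_locus_cm}, \code{n_males},
#'     \code{n_testcross_progeny}, \code{misclassification_rate}; writes
#'     \code{scored_males.tsv}.}
#'   \item{map_rf}{\code{scored_males} (TSV path, or \code{"simulate"} to
#'     consume the simulate stage) or \code{pair_counts} (TSV path, pooled
#'     over replicates); \code{ci_level}.}
#'   \item{place}{\code{rf_table} (TSV with \code{marker, rf[, n]}, or
#'     \code{"map_rf"}); \code{method}; optional \code{informative}.}
#'   \item{complementation}{\code{panel}, optional \code{alleles} +
#'     \code{annotation} TSVs; \code{radius}.}
#'   \item{tiling}{\code{panel} TSV; \code{size_tol}.}
#'   \item{viability}{\code{proportions}: records with \code{name,
#'     numerator, denominator}; optional \code{fertility} records with
#'     \code{name, fertile, total}.}
#' }
#' Any stage error propagates with the stage name; missing input files
#' abort the run before any stage executes.
#'
#' @param config Config list or path to a JSON config (see
#'   [readPipelineConfig()]).
#' @param outDir Optional override of \code{config$out_dir}.
#' @return Invisibly, a named list of stage results (plus \code{report}).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir <- attr(config, "dir")
  if (is.null(dir)) dir <- getwd()
  if (is.null(outDir)) outDir <- config$out_dir
  if (is.null(outDir))
    stop("no output directory: set out_dir in the config", call. = FALSE)
  outDir <- .resolvePathForOutput(outDir, dir)
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop("config lists no stages", call. = FALSE)
  known <- c("simulate", "map_rf", "place", "complementation", "tiling",
             "viability")
  badStage <- setdiff(stages, known)
  if (length(badStage))
    stop(sprintf("unknown stage(s): %s", paste(badStage, collapse = ", ")),
         call. = FALSE)
  seed <- config$seed
  if (is.null(seed)) stop("config must set a seed", call. = FALSE)

  # startup validation: every referenced input must exist before any stage runs
  inputs <- c(
    config$map_file,
    if (!identical(config$map_rf$scored_males, "simulate"))
      config$map_rf$scored_males,
    config$map_rf$pair_counts,
    if (!identical(config$place$rf_table, "map_rf")) config$place$rf_table,
    config$complementation$panel, config$complementation$alleles,
    config$complementation$annotation, config$tiling$panel)
  for (p in inputs) {
    rp <- .resolvePath(p, dir)
    if (!file.exists(rp))
      stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  map <- if (!is.null(config$map_file))
    readMarkerMap(.resolvePath(config$map_file, dir)) else rucucaMap()

  results <- list()
  ctx <- new.env(parent = emptyenv())
  for (stage in stages) {
    res <- tryCatch(
      switch(stage,
        simulate = .stageSimulate(config, map, seed, outDir, ctx),
        map_rf = .stageMapRf(config, dir, ctx),
        place = .stagePlace(config, map, dir, ctx),
        complementation = .stageComplementation(config, dir),
        tiling = .stageTiling(config, dir),
        viability = .stageViability(config)),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
    res$seed <- seed
    write_json(res, file.path(outDir, paste0(stage, ".json")),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results[[stage]] <- res
  }
  report <- list(
    package = "flymap",
    version = as.character(packageVersion("flymap")),
    seed = seed,
    config_hash = .configHash(config[setdiff(names(config), "out_dir")]),
    stages = results)
  write_json(report, file.path(outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(.pipelineSummary(report), file.path(outDir, "summary.txt"))
  results$report <- report
  invisible(results)
}

.resolvePathForOutput <- function(path, dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(dir, path)
}

.stageSimulate <- function(config, map, seed, outDir, ctx) {
  p <- config$simulate
  males <- simulateMappingExperiment(
    map,
    trueLocusCm = p$true_locus_cm,
    nMales = if (is.null(p$n_males)) 113 else p$n_males,
    nTestcrossProgeny = if (is.null(p$n_testcross_progeny)) 50
                        else p$n_testcross_progeny,
    misclassificationRate = if (is.null(p$misclassification_rate)) 0
                            else p$misclassification_rate,
    seed = seed)
  path <- file.path(outDir, "scored_males.tsv")
  write.table(males, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ctx$males <- males
  list(stage = "simulate", n_males = nrow(males),
       n_l = sum(males$locus_state == "l"),
       n_l_plus = sum(males$locus_state == "l+"),
       n_unknown = sum(males$locus_state == "unknown"),
       scored_males = path)
}

.stageMapRf <- function(config, dir, ctx) {
  p <- config$map_rf
  ciLevel <- if (is.null(p$ci_level)) 0.95 else p$ci_level
  if (!is.null(p$pair_counts)) {
    counts <- poolCounts(readPairCounts(.resolvePath(p$pair_counts, dir)))
    excluded <- 0L
  } else {
    males <- if (identical(p$scored_males, "simulate")) {
      if (is.null(ctx$males))
        stop("map_rf asks for simulated males but the simulate stage did not run")
      ctx$males
    } else readScoredMales(.resolvePath(p$scored_males, dir))
    counts <- classifyPair(males)
    excluded <- attr(counts, "excluded")
  }
  rf <- estimateRF(counts, ciLevel = ciLevel)
  ctx$rf <- rf
  list(stage = "map_rf", ci_level = ciLevel, excluded_males = excluded,
       rf = rf)
}

.stagePlace <- function(config, map, dir, ctx) {
  p <- config$place
  est <- if (is.null(p$rf_table) || identical(p$rf_table, "map_rf")) {
    if (is.null(ctx$rf))
      stop("place asks for map_rf output but the map_rf stage did not run")
    ctx$rf
  } else read.delim(.resolvePath(p$rf_table, dir), comment.char = "#",
                    stringsAsFactors = FALSE)
  method <- if (is.null(p$method)) "flank_subtraction" else p$method
  pl <- placeLocus(est, map, method = method,
                   informative = if (length(p$informative)) p$informative
                                 else NULL,
                   seed = config$seed)
  list(stage = "place", method = method, side = pl@side, anchor = pl@anchor,
       informative = pl@informative, low_cm = pl@low, high_cm = pl@high,
       point_cm = pl@point, note = pl@note)
}

.stageComplementation <- function(config, dir) {
  p <- config$complementation
  panel <- readDeficiencyPanel(.resolvePath(p$panel, dir))
  region <- solveRegion(panel,
                        maxSubband = if (is.null(p$max_subband)) 20L
                                     else p$max_subband)
  res <- list(stage = "complementation", arm = region@arm,
              region = vapply(region@intervals, formatCytoInterval,
                              character(1)),
              supporting = region@supporting, excluding = region@excluding)
  if (!is.null(p$alleles)) {
    verdicts <- checkAllelism(
      region,
      readAlleleTests(.resolvePath(p$alleles, dir)),
      readGeneAnnotation(.resolvePath(p$annotation, dir)),
      radius = if (is.null(p$radius)) 1 else p$radius)
    res$allelism <- verdicts
  }
  res
}

.stageTiling <- function(config, dir) {
  p <- config$tiling
  panel <- readAmpliconPanel(.resolvePath(p$panel, dir))
  scan <- findLesionInterval(panel, sizeTol = if (is.null(p$size_tol)) 0.10
                                             else p$size_tol)
  res <- list(stage = "tiling", status = scan@status,
              anomalous = scan@anomalous)
  if (!is.null(scan@span)) {
    res$candidate <- formatGenomicInterval(scan@span)
    res$candidate_bp <- intervalLength(scan@span)
  }
  res
}

.stageViability <- function(config) {
  p <- config$viability
  out <- list(stage = "viability")
  if (!is.null(p$proportions)) {
    props <- as.data.frame(p$proportions)
    props$percent <- stageProportion(props$numerator, props$denominator)
    out$proportions <- props
  }
  if (!is.null(p$fertility)) {
    fert <- as.data.frame(p$fertility)
    fert <- cbind(fert, t(vapply(seq_len(nrow(fert)), function(i) {
      fs <- fertilitySummary(fert$fertile[i], fert$total[i])
      c(percent = fs$percent, ci_low = fs$ci_low, ci_high = fs$ci_high)
    }, numeric(3))))
    out$fertility <- fert
  }
  out
}

.pipelineSummary <- function(report) {
  lines <- c(sprintf("flymap %s pipeline run (seed %s, config %s)",
                     report$version, report$seed, report$config_hash), "")
  for (nm in names(report$stages)) {
    s <- report$stages[[nm]]
    lines <- c(lines, sprintf("== %s ==", nm))
    lines <- c(lines, switch(nm,
      simulate = sprintf("  %d males scored: %d l, %d l+, %d unknown",
                         s$n_males, s$n_l, s$n_l_plus, s$n_unknown),
      map_rf = c(sprintf("  %d unknown-state males excluded", s$excluded_males),
                 sprintf("  %-4s RF %6.2f%%  [%5.2f, %5.2f]  (R %d / n %d)",
                         s$rf$marker, s$rf$rf, s$rf$ci_low, s$rf$ci_high,
                         s$rf$recombinant, s$rf$n)),
      place = sprintf("  locus %s of %s: [%.2f, %.2f] cM (%s)", s$side,
                      s$anchor, s$low_cm, s$high_cm, s$method),
      complementation = sprintf("  candidate region %s:%s", s$arm,
                                paste(s$region, collapse = " | ")),
      tiling = if (!is.null(s$candidate))
        sprintf("  %s: %s (%d bp)", s$status, s$candidate, s$candidate_bp)
      else sprintf("  %s", s$status),
      viability = if (!is.null(s$proportions))
        sprintf("  %s: %.1f%%", s$proportions$name, s$proportions$percent)
      else "  (no proportions configured)"))
    lines <- c(lines, "")
  }
  lines
}
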
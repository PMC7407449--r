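test_that("the lesion finder recovers the candidate amplicon", {
  panel <- readAmpliconPanel(extfile("tiling_panel_synthetic.tsv"))
  scan <- findLesionInterval(panel)
  expect_identical(lesionStatus(scan), "lesion")
  expect_identical(formatGenomicInterval(lesionSpan(scan)),
                   "3L:15826279..15827223")
  expect_equal(intervalLength(lesionSpan(scan)), 945)
  expect_identical(scan@anomalous, "amp03")
})

test_that("size-shifted amplicons count as anomalous, within tolerance", {
  panel <- readAmpliconPanel(extfile("tiling_panel_synthetic.tsv"))
  panel$outcome <- "amplified"
  panel$observed_size <- 945
  expect_identical(lesionStatus(findLesionInterval(panel)), "no_lesion")
  expect_null(lesionSpan(findLesionInterval(panel)))

  panel$observed_size[3] <- 8500   # long-range product off a 945 bp template
  scan <- findLesionInterval(panel)
  expect_identical(lesionStatus(scan), "lesion")
  expect_identical(scan@anomalous, "amp03")

  panel$observed_size[3] <- 990    # within the 10% tolerance
  expect_identical(lesionStatus(findLesionInterval(panel)), "no_lesion")
})

test_that("disjoint anomalies warn and report every cluster", {
  panel <- readAmpliconPanel(extfile("tiling_panel_synthetic.tsv"))
  panel$outcome[c(1, 4)] <- "failed"
  panel$observed_size[c(1, 4)] <- NA
  panel$outcome[3] <- "amplified"; panel$observed_size[3] <- 945
  expect_warning(scan <- findLesionInterval(panel), "disjoint clusters")
  expect_identical(lesionStatus(scan), "multi")
  expect_identical(nrow(scan@clusters), 2L)
})

test_that("simulated tilings always contain the hidden insertion site", {
  gene <- parseGenomicInterval("3L:15811576..15820204")
  set.seed(55)
  for (i in 1:25) {
    site <- sample(seq(gene@start, gene@end), 1)
    panel <- simulateTilingPCR(gene, insertionSite = site,
                               insertionSize = 7500, maxAmplifiable = 3000)
    scan <- suppressWarnings(findLesionInterval(panel))
    span <- lesionSpan(scan)
    expect_true(span@start <= site && site <= span@end)
    # a site in the overlap zone anomalizes two amplicons, so the candidate
    # is at most two amplicon lengths minus three overlaps wide
    expect_lte(intervalLength(span), 2 * 500 - 3 * 50)
  }
})

test_that("insertion size is signed amplicon-size subtraction", {
  expect_equal(insertionSize(8500, 945), 7555)
  expect_equal(insertionSize(17000, 8629), 8371)
  expect_equal(insertionSize(500, 500), 0)
  expect_equal(insertionSize(400, 945), -545)  # deletions come out negative
  expect_error(insertionSize(0, 945), "positive")
})

test_that("densitometric ratios normalize within lanes and cancel scale", {
  d <- data.frame(genotype = c("wt", "wt", "mut", "mut"),
                  role = c("target", "control", "target", "control"),
                  intensity = c(100, 100, 260, 130))
  out <- relativeAbundance(d, reference = "wt")
  expect_equal(out$ratio[out$genotype == "wt"], 1)
  expect_equal(out$fold_change[out$genotype == "mut"], 2)

  # rescaling one lane leaves ratios unchanged
  d2 <- d
  d2$intensity[d2$genotype == "mut"] <- d2$intensity[d2$genotype == "mut"] * 7.3
  expect_equal(relativeAbundance(d2, reference = "wt")$fold_change,
               out$fold_change)

  dz <- d; dz$intensity[2] <- 0
  expect_error(relativeAbundance(dz), "zero control")
})

test_that("a simulated duplication shows a ~2x fold change under noise", {
  set.seed(77)
  lanes <- do.call(rbind, lapply(1:12, function(i) {
    noise <- function() exp(rnorm(1, 0, 0.05))
    scale <- runif(1, 0.5, 2)
    rbind(
      data.frame(genotype = paste0("wt", i), role = c("target", "control"),
                 intensity = scale * c(100 * noise(), 100 * noise())),
      data.frame(genotype = paste0("mut", i), role = c("target", "control"),
                 intensity = scale * c(200 * noise(), 100 * noise())))
  }))
  out <- relativeAbundance(lanes, reference = "wt1")
  folds <- out$fold_change[grepl("^mut", out$genotype)] /
    mean(out$fold_change[grepl("^wt", out$genotype)])
  expect_lt(abs(mean(folds) - 2), 0.2)
})
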
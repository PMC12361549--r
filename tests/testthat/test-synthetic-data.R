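test_that("default design yields 45 samples per organ with matched mice", {
  cfg <- syntheticConfig(organs = c("kidney", "spleen"), nProteins = 20,
                         seed = 1)
  st <- simulateStudy(cfg)
  perOrgan <- table(st$metadata$organ)
  expect_true(all(perOrgan == 45))
  ## sample columns and metadata are bijective per organ
  for (org in names(st$peptides)) {
    sids <- st$metadata$sample_id[st$metadata$organ == org]
    expect_setequal(intersect(names(st$peptides[[org]]), sids), sids)
  }
  ## matched sampling: same mice in every organ
  byOrgan <- split(st$metadata$mouse_id, st$metadata$organ)
  expect_identical(sort(byOrgan[[1]]), sort(byOrgan[[2]]))
})

test_that("zero DEP fractions produce empty ground-truth DEP sets", {
  cfg <- syntheticConfig(organs = c("kidney", "liver"), nProteins = 30,
                         depFraction = c(kidney = 0, liver = 0), seed = 2)
  st <- simulateStudy(cfg)
  expect_true(all(lengths(st$truth$depSets) == 0))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- syntheticConfig(organs = "kidney", nProteins = 25, seed = 9)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$truth, b$truth)
})

test_that("trajectory templates behave as described", {
  ages <- c(3, 5, 8, 14, 20, 26)
  expect_equal(plantTrajectory("flat", ages, 2.5), rep(0, 6))
  ldr <- plantTrajectory("late_decline_recover", ages, 1.0)
  expect_equal(ldr[1:4], rep(ldr[1], 4))          # stable 3-14 months
  expect_equal(which.min(ldr), 5L)                # minimum at 20 months
  expect_gt(ldr[6], ldr[5])                       # partial return at 26
  expect_lt(ldr[6], ldr[1])
  expect_error(plantTrajectory("nope", ages), "late_decline_recover")
  ## standardized planted profile matches the standardized template
  for (shape in setdiff(trajectoryShapes(), "flat")) {
    tpl <- plantTrajectory(shape, ages, 1)
    planted <- plantTrajectory(shape, ages, 3.7) + 12  # scaled + shifted
    expect_gte(cor(scale(tpl)[, 1], scale(planted)[, 1]), 0.99)
  }
})

test_that("missingness injection hits its rates and is reproducible", {
  x <- matrix(2^rnorm(10000, 20, 2), 100, 100)
  none <- injectMissingness(x, 0, 0, seed = 1)
  expect_false(any(is.na(none$matrix)))
  mcar <- injectMissingness(x, 0.1, 0, seed = 4)
  expect_lt(abs(mean(mcar$mask) - 0.10), 0.01)
  again <- injectMissingness(x, 0.1, 0, seed = 4)
  expect_identical(mcar$mask, again$mask)
  ## MNAR removal concentrates on low intensities
  mnar <- injectMissingness(x, 0, 0.5, seed = 5)
  lost <- log2(x)[mnar$mask]
  kept <- log2(x)[!mnar$mask]
  expect_lt(mean(lost), mean(kept))
})

test_that("noise-free generation is recovered exactly by summarization", {
  cfg <- syntheticConfig(organs = "kidney", nProteins = 12,
                         residualSd = 0, mouseInterceptSd = 0,
                         bloodFraction = 0, mcarRate = 0,
                         qcViolationRate = 0, seed = 6)
  st <- simulateStudy(cfg)
  m <- st$metadata
  d <- tempfile(); writeStudy(st, d)
  rec <- readPeptideTable(file.path(d, "peptides_kidney.tsv"), m)
  se <- buildIntensityMatrix(filterPeptides(rec)$records, m)
  pse <- summarizeProteins(logAndCenter(se, center = FALSE))
  mat <- assay(pse, "log2abundance")
  shp <- st$truth$shapes$kidney
  for (i in seq_len(nrow(shp))) {
    planted <- plantTrajectory(shp$shape[i], cfg@agesMonths,
                               shp$amplitude[i])
    prof <- mat[shp$protein[i], m$sample_id]
    perAge <- tapply(prof, m$age_months, mean)[as.character(cfg@agesMonths)]
    expect_equal(as.numeric(perAge - mean(perAge)),
                 as.numeric(planted - mean(planted)), tolerance = 1e-6)
  }
})

test_that("interaction-graph fixture plants cliques faithfully", {
  k5 <- simulateInteractionGraph(9, cliqueSpec = list(5), seed = 1)
  expect_equal(igraph::ecount(k5$graph), 10)        # K5 plus isolated nodes
  expect_equal(igraph::vcount(k5$graph), 9)
  expect_error(simulateInteractionGraph(4, cliqueSpec = list(5)), "larger")
  empty <- simulateInteractionGraph(6, seed = 2)
  expect_equal(igraph::ecount(empty$graph), 0)
  scores <- mccScores(empty$graph)
  expect_true(all(scores == scores[1]))             # all isolated, equal MCC
})

test_that("transition-report generator honors ratio truth and dropout", {
  rep0 <- simulateTransitionReport(3, ratioTruth = 1, cv = 0, seed = 1)
  q <- quantifyRatios(rep0)
  expect_true(all(q$ratio == 1))
  drop2 <- simulateTransitionReport(
    2, ratioTruth = 1, cv = 0,
    dropoutSpec = data.frame(peptide = "PEP001", n_zero = 2), seed = 1)
  fq <- filterQuantifiablePeptides(drop2)
  expect_true(all(!fq$quantifiable[fq$peptide_id == "PEP001"]))
  expect_true(all(fq$quantifiable[fq$peptide_id == "PEP002"]))
  ## Monte-Carlo ratio recovery at 5% CV
  mc <- simulateTransitionReport(20, samples = sprintf("S%d", 1:6),
                                 ratioTruth = 0.5, cv = 0.05, seed = 8)
  qm <- quantifyRatios(mc)
  expect_lt(abs(mean(qm$ratio) - 0.5), 0.02)
})
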
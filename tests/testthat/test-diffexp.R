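test_that("group-model fit matches the pooled-variance oracle", {
  g <- rep(1:3, c(3, 4, 3))
  x0 <- rbind(rep(1, 10), c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2))
  fit0 <- fitGroupModel(x0, g)
  expect_equal(fit0@s2, c(0, 0))
  expect_equal(unname(fit0@means[2, ]), c(0, 1, 2))
  set.seed(1)
  x <- matrix(rnorm(50 * 10), 50, 10)
  fit <- fitGroupModel(x, g)
  for (i in 1:50) {
    res <- unlist(tapply(x[i, ], g, function(v) v - mean(v)))
    expect_equal(fit@s2[i], sum(res^2) / (10 - 3), tolerance = 1e-12)
  }
  expect_equal(fit@df, rep(7, 50))
})

test_that("EB prior recovery, scale equivariance, and the d0=Inf branch", {
  set.seed(7)
  d0 <- 4; s02 <- 0.05; G <- 5000; dg <- 39
  sigma2 <- d0 * s02 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, dg) / dg
  pr <- estimateEBPrior(s2, rep(dg, G))
  expect_lt(abs(pr@df0 - d0) / d0, 0.2)
  expect_lt(abs(pr@s02 - s02) / s02, 0.1)
  ## independent implementation agreement
  sq <- limma::squeezeVar(s2, rep(dg, G))
  expect_equal(pr@df0, sq$df.prior, tolerance = 1e-8)
  expect_equal(pr@s02, sq$var.prior, tolerance = 1e-8)
  ## doubling variances doubles s02, leaves d0 unchanged
  pr2 <- estimateEBPrior(2 * s2, rep(dg, G))
  expect_equal(pr2@df0, pr@df0, tolerance = 1e-8)
  expect_equal(pr2@s02, 2 * pr@s02, tolerance = 1e-8)
  ## under-dispersed log-variances force the boundary
  tight <- exp(rnorm(100, log(0.05), 0.01))
  prInf <- estimateEBPrior(tight, rep(39, 100))
  expect_true(is.infinite(prInf@df0))
  expect_error(estimateEBPrior(rep(0, 50), rep(5, 50)), "zero|variance")
})

test_that("moderated F collapses to classical ANOVA at d0 = 0", {
  set.seed(3)
  g <- rep(1:4, each = 4)
  for (i in 1:10) {
    x <- matrix(rnorm(20 * 16), 20, 16)
    fit <- fitGroupModel(x, g)
    mf <- moderatedFTest(fit, new("EBPrior", df0 = 0, s02 = 1))
    oracle <- apply(x, 1, function(y)
      unlist(anova(lm(y ~ factor(g)))[1, c("F value", "Pr(>F)")]))
    expect_equal(mf$F, unname(oracle[1, ]), tolerance = 1e-10)
    expect_equal(mf$p, unname(oracle[2, ]), tolerance = 1e-10)
  }
})

test_that("complete shrinkage tests every protein against s0^2", {
  set.seed(4)
  g <- rep(1:3, each = 5)
  x <- matrix(rnorm(30 * 15), 30, 15)
  fit <- fitGroupModel(x, g)
  prior <- new("EBPrior", df0 = Inf, s02 = 0.7)
  mf <- moderatedFTest(fit, prior)
  expect_equal(mf$s2_post, rep(0.7, 30))
  ## shrinkage interpolation property at finite d0
  pr <- estimateEBPrior(fit@s2, fit@df)
  mfe <- moderatedFTest(fit, pr)
  expect_true(all(mfe$s2_post >= pmin(fit@s2, pr@s02) - 1e-12))
  expect_true(all(mfe$s2_post <= pmax(fit@s2, pr@s02) + 1e-12))
})

test_that("moderated t squares to the two-group moderated F", {
  set.seed(5)
  g <- rep(c("3", "20"), each = 6)
  x <- matrix(rnorm(40 * 12), 40, 12)
  fit <- fitGroupModel(x, g)
  pr <- estimateEBPrior(fit@s2, fit@df)
  tt <- pairwiseModeratedT(fit, pr, "20", "3")
  ff <- moderatedFTest(fit, pr)
  expect_equal(tt$t^2, ff$F, tolerance = 1e-10)
  expect_equal(tt$p, ff$p, tolerance = 1e-10)
  ## identical groups give t = 0, p = 1
  xc <- rbind(rep(1, 12), rep(2, 12))
  fitc <- fitGroupModel(xc, g)
  ttc <- pairwiseModeratedT(fitc, pr, "20", "3")
  expect_equal(ttc$t, c(0, 0))
  expect_equal(ttc$p, c(1, 1))
})

test_that("null simulations are calibrated at the study design", {
  set.seed(8)
  ages <- paperAges()
  x <- matrix(rnorm(2000 * 45, 0, 0.5), 2000, 45)
  fit <- fitGroupModel(x, ages)
  pr <- estimateEBPrior(fit@s2, fit@df)
  mf <- moderatedFTest(fit, pr)
  expect_gt(stats::ks.test(mf$p, "punif")$p.value, 0.01)
  tt <- pairwiseModeratedT(fit, pr, "20", "3")
  expect_lt(mean(tt$p < 0.05), 0.07)
  ## BH keeps the null family clean
  expect_equal(sum(bhAdjust(mf$p) < 0.05), 0)
})

test_that("linear trend test has exact limits and a uniform permutation null", {
  age <- paperAges()
  lin <- matrix(0.1 * age + 3, 1)
  tr <- linearTrendTest(lin, age)
  expect_equal(tr$r2, 1)
  expect_equal(tr$slope, 0.1)
  flat <- matrix(rep(2, 45), 1)
  trf <- linearTrendTest(flat, age)
  expect_equal(c(trf$slope, trf$p, trf$r2), c(0, 1, 0))
  ## permutation null of p-values for a trending protein
  set.seed(10)
  y <- 0.05 * age + rnorm(45, 0, 0.5)
  ps <- replicate(400, linearTrendTest(matrix(y, 1), sample(age))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.013), 0.013)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- runif(100)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("DEP classification uses a strict threshold and overlap algebra", {
  tab <- data.frame(modF_q = c(0.05, 0.049), modT_q = c(0.05, 0.049),
                    classF_q = c(0.05, 0.049), trend_q = c(0.01, 0.6),
                    trend_r2 = c(0.2, 0.9),
                    row.names = c("A", "B"))
  cls <- classifyDEPs(tab, 0.05)
  expect_identical(cls$sets$moderatedF, "B")       # 0.05 exactly is not DEP
  expect_equal(cls$overlap["moderatedF", "pairwise"], 1)  # identical calls
  expect_identical(cls$trendExtra$accession, "A")
  expect_equal(cls$trendExtra$r2, 0.2)
})

test_that("moderated F beats the 20-vs-3 contrast on mid-life trajectories", {
  ## planted mid-life peaks are invisible to the endpoint contrast
  set.seed(12)
  ages <- paperAges()
  n <- 400
  peak <- plantTrajectory("midlife_peak", c(3, 5, 8, 14, 20, 26), 1)
  x <- matrix(rnorm(n * 45, 0, 0.35), n, 45)
  planted <- 1:120
  shift <- peak[match(ages, c(3, 5, 8, 14, 20, 26))]
  x[planted, ] <- x[planted, , drop = FALSE] +
    matrix(shift, length(planted), 45, byrow = TRUE)
  rownames(x) <- sprintf("P%03d", 1:n)
  de <- runDiffexp(x, ages)
  cls <- classifyDEPs(de$table)
  truth <- rownames(x)[planted]
  tpF <- length(intersect(cls$sets$moderatedF, truth))
  tpT <- length(intersect(cls$sets$pairwise, truth))
  expect_gt(tpF, tpT)
})
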
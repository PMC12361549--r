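ages6 <- c(3, 5, 8, 14, 20, 26)

## noisy profiles around a set of shape templates, one block per shape
shapeBlocks <- function(shapes, perShape = 30, noise = 0.1, seed = 2) {
  set.seed(seed)
  X <- do.call(rbind, lapply(shapes, function(s) {
    tpl <- plantTrajectory(s, ages6, 1)
    matrix(rep(tpl, each = perShape), perShape) +
      matrix(rnorm(perShape * 6, 0, noise), perShape)
  }))
  rownames(X) <- sprintf("P%03d", seq_len(nrow(X)))
  X
}

test_that("z-scored profiles keep monotonicity, drop constants", {
  age <- rep(ages6, each = 3)
  lin <- matrix(rep(0.1 * age, 2), 2, byrow = TRUE)
  lin[2, ] <- 5                                   # constant protein
  rownames(lin) <- c("mono", "const")
  Z <- zscoreProfiles(lin, age)
  expect_equal(rownames(Z), "mono")
  expect_identical(attr(Z, "excluded"), "const")
  expect_true(all(diff(Z["mono", ]) > 0))
  ## balanced designs: z-then-average equals average-then-z up to scale
  y <- matrix(rnorm(36), 2, 18)
  rownames(y) <- c("a", "b")
  Z2 <- zscoreProfiles(y, age)
  perAge <- t(apply(y, 1, function(r) tapply(r, age, mean)))
  expect_gt(abs(cor(Z2["a", ], perAge["a", ])), 1 - 1e-12)
  ## scale invariance
  expect_equal(zscoreProfiles(y * 13.7, age), zscoreProfiles(y, age))
})

test_that("fuzzifier estimate matches the published formula", {
  ## frozen value from an independent evaluation of the formula
  expect_equal(estimateFuzzifier(1786, 6), 1.75285044995, tolerance = 1e-9)
  expect_true(all(sapply(c(10, 100, 5000), function(N)
    estimateFuzzifier(N, 6)) > 1))
  ms <- sapply(c(100, 300, 1000, 3000, 10000), estimateFuzzifier,
               nAges = 6)
  expect_true(all(diff(ms) < 0))                  # decreasing in N
})

test_that("fuzzy c-means recovers planted structure and matches k-means", {
  X <- shapeBlocks(c("late_decline_recover", "late_rise_fall"))
  fc <- fuzzyCMeans(X, 2, m = 1.25, seed = 5)
  truth <- rep(1:2, each = 30)
  expect_equal(ari(max.col(fc@membership), truth), 1)
  expect_true(all(abs(rowSums(fc@membership) - 1) < 1e-9))
  ## m -> 1+ converges to k-means assignments on separated data
  fc1 <- fuzzyCMeans(X, 2, m = 1.01, seed = 5)
  km <- kmeans(X, centers = fc1@centers)
  expect_equal(ari(max.col(fc1@membership), km$cluster), 1)
  ## c = 1 degenerates to the mean profile
  one <- fuzzyCMeans(X, 1)
  expect_equal(one@centers[1, ], colMeans(X))
  expect_true(all(one@membership == 1))
  expect_error(fuzzyCMeans(X[1:3, ], 5), "more clusters")
})

test_that("an exact center coincidence is assigned crisply", {
  X <- shapeBlocks(c("late_decline_recover", "late_rise_fall"),
                   perShape = 10, noise = 0.05)
  fc <- fuzzyCMeans(X, 2, m = 1.3, seed = 1)
  Xc <- rbind(X, center_copy = fc@centers[1, ])
  fc2 <- fuzzyCMeans(Xc, 2, m = 1.3, seed = 1)
  expect_true(all(abs(rowSums(fc2@membership) - 1) < 1e-9))
})

test_that("partition indices hit their crisp and uniform bounds", {
  crisp <- diag(3)[rep(1:3, 4), ]
  idx <- partitionIndices(crisp)
  expect_equal(idx$pc, 1)
  expect_equal(idx$pe, 0)
  unif <- matrix(1 / 4, 10, 4)
  idxU <- partitionIndices(unif)
  expect_equal(idxU$pc, 1 / 4)
  expect_equal(idxU$pe, log(4))
  hand <- partitionIndices(rbind(c(0.5, 0.5), c(1, 0)))
  expect_equal(hand$pc, 0.75)
  expect_equal(hand$pe, log(2) / 2)
  expect_error(partitionIndices(matrix(c(0.5, 0.6), 1)), "sum to 1")
})

test_that("cluster-count selection finds planted shapes, flags noise", {
  X <- shapeBlocks(c("late_decline_recover", "late_rise_fall",
                     "midlife_peak"), perShape = 25, noise = 0.08)
  sel <- selectClusterCount(X, 2:4, m = 1.25, seed = 3)
  expect_equal(sel$c, 3)
  expect_false(sel$lowConfidence)
  set.seed(4)
  noise <- matrix(rnorm(80 * 6), 80, 6)
  selN <- selectClusterCount(noise, 2:4, seed = 3)
  expect_true(selN$lowConfidence)
  expect_warning(selOne <- selectClusterCount(X, 3, m = 1.25, seed = 3),
                 "single")
  expect_equal(selOne$c, 3)
})

test_that("cluster summaries rank enrichment by membership statistics", {
  X <- shapeBlocks(c("late_decline_recover", "late_rise_fall"))
  fc <- fuzzyCMeans(X, 2, m = 1.25, seed = 5)
  cs <- clusterSummaries(fc)
  expect_equal(sum(cs$summary$n), nrow(X))
  ## crisp memberships: both clusters mean 1, sd 0
  crisp <- methods::new("FuzzyClustering",
                        centers = fc@centers,
                        membership = diag(2)[rep(1:2, each = 5), ],
                        m = 1.25, objective = 0, pc = 1, pe = 0)
  csc <- clusterSummaries(crisp)
  expect_equal(csc$summary$mean_membership, c(1, 1))
  expect_equal(csc$summary$sd_membership, c(0, 0))
  ## tight cluster beats diffuse cluster
  U <- rbind(matrix(c(0.95, 0.05), 6, 2, byrow = TRUE),
             matrix(c(0.4, 0.6), 6, 2, byrow = TRUE))
  tight <- methods::new("FuzzyClustering", centers = fc@centers,
                        membership = U, m = 1.25, objective = 0,
                        pc = 0.5, pe = 0.5)
  expect_equal(clusterSummaries(tight)$mostEnriched, 1L)
})

test_that("PC1 trajectory agrees with an SVD oracle and sums fractions", {
  set.seed(6)
  X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, ages6))
  p1 <- pc1Trajectory(X)
  expect_equal(sum(p1$allFractions), 1)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  oracle <- sv$v[, 1]
  if (sum(oracle * p1$scores) < 0) oracle <- -oracle
  expect_equal(unname(p1$scores), oracle, tolerance = 1e-9)
  expect_equal(p1$varianceExplained,
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-9)
  ## rank-1 input: all variance on PC1
  r1 <- outer(rnorm(20), c(1, 2, 3, 2, 1, 0))
  expect_equal(pc1Trajectory(r1)$varianceExplained, 1)
  expect_error(pc1Trajectory(matrix(1, 5, 6)), "rank 0")
})
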
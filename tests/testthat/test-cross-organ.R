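test_that("intersections cover hand-checkable set algebra", {
  sets <- list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3")
  res <- depIntersections(sets)
  expect_equal(res$pairwise["A", "B"], 2)
  expect_equal(res$triples$count[res$triples$organs == "A&B&C"], 1)
  exclA <- res$exclusive$count[res$exclusive$combination == "A"]
  expect_equal(exclA, 1)
  expect_equal(sum(res$exclusive$count), 4)        # union size
  ## disjoint sets
  dis <- depIntersections(list(A = c("a", "b"), B = c("c"), C = c("d")))
  expect_true(all(dis$pairwise[upper.tri(dis$pairwise)] == 0))
  expect_equal(unname(dis$dominantFraction), c(1, 1, 1))
})

test_that("exclusive counts always sum to the union (fuzz)", {
  set.seed(20)
  for (i in 1:20) {
    sets <- lapply(1:4, function(j)
      as.character(sample(100, sample(5:40, 1))))
    names(sets) <- letters[1:4]
    res <- depIntersections(sets)
    expect_equal(sum(res$exclusive$count), length(unique(unlist(sets))))
  }
})

test_that("a fixture with the published overlap sizes reproduces them", {
  ## kidney/spleen/liver sets constructed to share 634, 282, 173 pairwise
  ## and 142 three-way, within universes of 1786/1769/439
  triple <- sprintf("T%04d", 1:142)
  ks <- sprintf("KS%04d", 1:(634 - 142))
  kl <- sprintf("KL%04d", 1:(282 - 142))
  sl <- sprintf("SL%04d", 1:(173 - 142))
  kidney <- c(triple, ks, kl, sprintf("K%04d", seq_len(1786 - 634 - 140)))
  spleen <- c(triple, ks, sl, sprintf("S%04d", seq_len(1769 - 634 - 31)))
  liver <- c(triple, kl, sl, sprintf("L%04d", seq_len(439 - 282 - 31)))
  res <- depIntersections(list(kidney = kidney, spleen = spleen,
                               liver = liver))
  expect_equal(res$pairwise["kidney", "spleen"], 634)
  expect_equal(res$pairwise["kidney", "liver"], 282)
  expect_equal(res$pairwise["spleen", "liver"], 173)
  expect_equal(res$triples$count, 142)
  expect_equal(length(kidney), 1786)
  expect_equal(length(spleen), 1769)
  expect_equal(length(liver), 439)
})

test_that("hypergeometric tail matches combinatorial enumeration", {
  expect_equal(hypergeomOverlapTest(0, 5, 5, 10), 1)
  expect_equal(hypergeomOverlapTest(5, 5, 5, 10), 1 / choose(10, 5))
  set.seed(21)
  for (i in 1:100) {
    N <- sample(4:60, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomOverlapTest(k, K, n, N),
                 hyperTailOracle(k, K, n, N), tolerance = 1e-12)
    ## exchangeable in (K, n)
    expect_equal(hypergeomOverlapTest(k, K, n, N),
                 hypergeomOverlapTest(k, n, K, N), tolerance = 1e-14)
  }
  ## strictly decreasing in k
  tails <- sapply(0:5, hypergeomOverlapTest, K = 8, n = 10, N = 30)
  expect_true(all(diff(tails) < 0))
  expect_error(hypergeomOverlapTest(6, 5, 5, 10), "infeasible")
})

test_that("three-way overlap tail matches Monte-Carlo simulation", {
  set.seed(22)
  N <- 20; sizes <- c(8, 10, 12)
  draws <- replicate(20000, {
    a <- sample(N, sizes[1]); b <- sample(N, sizes[2])
    c <- sample(N, sizes[3])
    length(intersect(intersect(a, b), c))
  })
  for (k in c(1, 3, 5)) {
    expect_lt(abs(tripleOverlapTest(k, sizes, N) - mean(draws >= k)), 0.02)
  }
  expect_equal(tripleOverlapTest(0, sizes, N), 1)
  ## monotone decreasing in k
  ps <- sapply(0:6, tripleOverlapTest, sizes = sizes, N = N)
  expect_true(all(diff(ps) <= 0))
})

test_that("blood filtering is exact set subtraction with bookkeeping", {
  sets <- list(kidney = c("a", "b", "c", "d"), liver = c("c", "e"))
  blood <- c("c", "d", "z")
  res <- filterBloodProteins(sets, blood)
  expect_equal(res$sets$kidney, c("a", "b"))
  expect_equal(unname(res$removed),
               unname(sapply(sets, function(s) length(intersect(s, blood)))))
  ## disjoint blood list changes nothing
  same <- filterBloodProteins(sets, "q")
  expect_identical(same$sets, sets)
  expect_warning(filterBloodProteins(sets, character()), "empty")
})

test_that("trajectory correlation has exact limits and the hand value", {
  up <- c(1, 2, 3, 4, 5, 6)
  expect_equal(trajectoryCorrelation(up, up * 2)$rho, 1)
  expect_equal(trajectoryCorrelation(up, rev(up))$rho, -1)
  hand <- trajectoryCorrelation(up, c(1, 2, 3, 4, 6, 5))
  expect_equal(hand$rho, 1 - 6 * 2 / (6 * 35), tolerance = 1e-12)
  expect_lt(hand$p, 0.05)                          # near-perfect agreement
  const <- trajectoryCorrelation(rep(1, 6), up)
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
  ## permutation p of uncorrelated profiles is large
  set.seed(23)
  r <- trajectoryCorrelation(rnorm(6), rnorm(6))
  expect_gt(r$p, 0.01)
})
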
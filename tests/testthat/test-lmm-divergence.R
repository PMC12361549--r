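## small matched two-tissue design generator
lmmData <- function(nMice = 20, tissues = c("a", "b"), slopes = NULL,
                    tau = 0.3, sigma = 0.3, seed = 1) {
  set.seed(seed)
  ages <- rep(c(3, 5, 8, 14, 20, 26), length.out = nMice)
  mice <- sprintf("m%02d", seq_len(nMice))
  if (is.null(slopes)) slopes <- rep(0.02, length(tissues))
  b <- rnorm(nMice, 0, tau)
  do.call(rbind, lapply(seq_along(tissues), function(t)
    data.frame(age = ages, tissue = tissues[t], mouse = mice,
               y = slopes[t] * ages + b + rnorm(nMice, 0, sigma))))
}

test_that("profiled ML agrees with the lme4 oracle", {
  df <- lmmData(seed = 3, slopes = c(0.02, 0.05))
  fit <- fitLmmInteraction(df)
  lf <- lme4::lmer(y ~ age * tissue + (1 | mouse), df, REML = FALSE)
  lr <- lme4::lmer(y ~ age + tissue + (1 | mouse), df, REML = FALSE)
  expect_equal(fit$logLikFull, as.numeric(logLik(lf)), tolerance = 1e-5)
  expect_equal(fit$logLikReduced, as.numeric(logLik(lr)), tolerance = 1e-5)
  expect_equal(fit$lrt, as.numeric(2 * (logLik(lf) - logLik(lr))),
               tolerance = 1e-4)
  expect_equal(fit$tau2, as.numeric(lme4::VarCorr(lf)$mouse[1]),
               tolerance = 1e-3)
  expect_equal(fit$df, 1L)
})

test_that("degenerate grouping reduces the LRT to the OLS statistic", {
  df <- lmmData(seed = 4)
  df$mouse <- sprintf("u%03d", seq_len(nrow(df)))  # one row per mouse
  fit <- fitLmmInteraction(df)
  ofull <- lm(y ~ age * tissue, df)
  ored <- lm(y ~ age + tissue, df)
  lrtOls <- as.numeric(2 * (logLik(ofull) - logLik(ored)))
  expect_equal(fit$lrt, lrtOls, tolerance = 1e-6)
})

test_that("the LRT is invariant to shifts and tissue relabeling", {
  df <- lmmData(seed = 5, slopes = c(0.01, 0.06))
  fit <- fitLmmInteraction(df)
  shifted <- df; shifted$y <- shifted$y + 100
  expect_equal(fitLmmInteraction(shifted)$lrt, fit$lrt, tolerance = 1e-6)
  relab <- df
  relab$tissue <- factor(relab$tissue, levels = c("b", "a"))
  expect_equal(fitLmmInteraction(relab)$lrt, fit$lrt, tolerance = 1e-6)
})

test_that("singular designs are rejected", {
  df <- lmmData(seed = 6)
  df$age[df$tissue == "b"] <- 5                    # one age in a tissue
  expect_error(fitLmmInteraction(df), "singular")
  expect_error(fitLmmInteraction(df[df$tissue == "a", ]), "two tissues")
})

test_that("per-tissue trends are unbiased at the study replicate counts", {
  ages <- paperAges()
  set.seed(7)
  slopes <- replicate(300, {
    y <- 0.05 * ages + rnorm(45, 0, 0.3)
    .slope <- perTissueTrend(data.frame(y = y, age = ages, tissue = "a"),
                             "a")["slope"]
  })
  expect_lt(abs(mean(slopes) - 0.05) / 0.05, 0.02)
  flat <- perTissueTrend(
    data.frame(y = rep(2, 45), age = ages, tissue = "a"), "a")
  expect_equal(unname(flat["slope"]), 0)
  expect_equal(unname(flat["p"]), 1)
})

test_that("directionality categories follow the stated rules", {
  tr <- data.frame(
    protein = rep(c("up3", "div", "kid", "none"), each = 3),
    tissue = rep(c("kidney", "liver", "spleen"), 4),
    slope = c(1, 1, 1, 0, 1, -1, 1, 0, 0, 0, 0, 0),
    p = c(0.01, 0.01, 0.01, 0.5, 0.01, 0.01, 0.01, 0.5, 0.5,
          0.5, 0.5, 0.5))
  dm <- directionalityMatrix(tr)
  cats <- setNames(dm$categories$category, dm$categories$protein)
  expect_equal(unname(cats["up3"]), "consistent-up")
  expect_equal(unname(cats["div"]), "divergent")
  expect_match(dm$categories$detail[dm$categories$protein == "div"],
               "liver\\+/spleen-")
  expect_equal(unname(cats["kid"]), "tissue-specific")
  expect_equal(dm$categories$detail[dm$categories$protein == "kid"],
               "kidney")
  expect_equal(unname(cats["none"]), "no-change")
})

test_that("categories are a pure function of the entries (fuzz)", {
  set.seed(8)
  for (i in 1:30) {
    entries <- matrix(sample(c("Up", "Down", "NoChange"), 4, TRUE), 1, 4)
    tr <- data.frame(protein = "p", tissue = letters[1:4],
                     slope = ifelse(entries[1, ] == "Up", 1,
                                    ifelse(entries[1, ] == "Down", -1, 0)),
                     p = ifelse(entries[1, ] == "NoChange", 0.9, 0.001))
    got <- directionalityMatrix(tr)$categories$category
    nU <- sum(entries == "Up"); nD <- sum(entries == "Down")
    want <- if (nU >= 1 && nD >= 1) "divergent"
    else if (nU + nD == 1) "tissue-specific"
    else if (nU >= 2) "consistent-up"
    else if (nD >= 2) "consistent-down"
    else "no-change"
    expect_equal(got, want)
  }
})

test_that("the divergence pipeline flags planted interactions", {
  ## 30 proteins, half with tissue-specific slopes
  set.seed(9)
  nMice <- 45
  ages <- rep(c(3, 5, 8, 14, 20, 26), c(7, 9, 8, 9, 7, 5))
  mice <- sprintf("m%02d", 1:nMice)
  meta <- do.call(rbind, lapply(c("kidney", "liver"), function(org)
    data.frame(sample_id = paste(org, mice, sep = "_"), organ = org,
               age_months = ages, mouse_id = mice)))
  mats <- list()
  for (org in c("kidney", "liver")) {
    m <- matrix(rnorm(30 * nMice, 0, 0.3), 30, nMice)
    b <- rnorm(nMice, 0, 0.3)
    m <- sweep(m, 2, b, `+`)
    if (org == "liver") m[1:15, ] <- m[1:15, ] +
        matrix(rep(0.05 * ages, each = 15), 15)
    rownames(m) <- sprintf("P%02d", 1:30)
    colnames(m) <- paste(org, mice, sep = "_")
    mats[[org]] <- m
  }
  res <- runLmmDivergence(mats, meta)
  sig <- res$lmm$protein[res$lmm$q < 0.05]
  expect_gt(mean(sprintf("P%02d", 1:15) %in% sig), 0.9)
  expect_lt(mean(sprintf("P%02d", 16:30) %in% sig), 0.35)
})
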
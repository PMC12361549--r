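## Per-organ differential expression across age groups.
##
## The workhorse is a moderated F-test: a one-way group-means model is
## fitted per protein, the residual variances are shrunk toward a common
## prior by empirical Bayes (scaled inverse-chi-square prior with
## hyperparameters d0, s0^2 estimated by method of moments on the log
## sample variances), and the between-group mean square is referred to the
## posterior variance on d0 + d_g denominator degrees of freedom.  The
## pairwise moderated t (20 vs 3 months), classical F and continuous-age
## linear-trend test are companions, all controlled by Benjamini-Hochberg.

#' Per-protein one-way group-means fit
#'
#' @slot means protein x group matrix of group means.
#' @slot counts protein x group matrix of observed sample counts.
#' @slot s2 per-protein pooled residual variance.
#' @slot df per-protein residual degrees of freedom (observed n minus
#'   number of groups present for that protein).
#' @slot groups group labels (age groups, chronological order).
#' @export
setClass("GroupModelFit", representation(
  means = "matrix", counts = "matrix", s2 = "numeric", df = "numeric",
  groups = "character"))

setMethod("show", "GroupModelFit", function(object) {
  cat("GroupModelFit:", nrow(object@means), "proteins x",
      length(object@groups), "age groups (",
      paste(object@groups, collapse = ", "), ")\n")
  cat("  median residual df:", stats::median(object@df), "\n")
})

#' Empirical-Bayes variance prior
#'
#' Hyperparameters of the scaled inverse-chi-square prior on residual
#' variances: prior degrees of freedom `df0` (possibly `Inf`) and prior
#' variance `s02`.  The posterior (shrunken) variance of protein g is
#' `(df0*s02 + df_g*s2_g) / (df0 + df_g)` and always lies between `s2_g`
#' and `s02`.
#'
#' @slot df0 prior degrees of freedom.
#' @slot s02 prior variance.
#' @export
setClass("EBPrior", representation(df0 = "numeric", s02 = "numeric"))

setValidity("EBPrior", function(object) {
  if (object@df0 < 0 || object@s02 <= 0)
    "df0 must be >= 0 and s02 positive" else TRUE
})

setMethod("show", "EBPrior", function(object) {
  cat(sprintf("EBPrior: d0 = %s, s0^2 = %.4g\n",
              format(object@df0), object@s02))
})

#' Fit per-protein group-means models
#'
#' Computes, per protein, the age-group means, observed counts, the pooled
#' within-group residual variance and its degrees of freedom
#' `d_g = n_g - K_g` (observed samples minus groups present for that
#' protein).  Groups reduced to a single observation contribute their mean
#' but no residual degrees of freedom.
#'
#' @param x protein x sample numeric matrix (log2 abundances, NAs allowed).
#' @param groups per-sample group labels (coerced to factor; level order is
#'   the sorted numeric order when labels are numeric-like).
#' @return a [GroupModelFit-class].
#' @export
fitGroupModel <- function(x, groups) {
  x <- as.matrix(x)
  if (!is.factor(groups)) {
    g <- as.character(groups)
    lev <- unique(g)
    num <- suppressWarnings(as.numeric(lev))
    if (!anyNA(num)) lev <- lev[order(num)]
    groups <- factor(g, levels = lev)
  }
  if (length(groups) != ncol(x))
    stop("'groups' must have one label per sample column")
  K <- nlevels(groups)
  G <- nrow(x)
  means <- counts <- matrix(NA_real_, G, K,
                            dimnames = list(rownames(x), levels(groups)))
  rss <- numeric(G)
  for (k in seq_len(K)) {
    sub <- x[, groups == levels(groups)[k], drop = FALSE]
    nk <- rowSums(!is.na(sub))
    mk <- rowMeans(sub, na.rm = TRUE)
    mk[nk == 0] <- NA_real_
    means[, k] <- mk
    counts[, k] <- nk
    rss <- rss + rowSums((sub - mk)^2, na.rm = TRUE)
  }
  kPresent <- rowSums(counts > 0)
  df <- rowSums(counts) - kPresent
  s2 <- ifelse(df > 0, rss / df, NA_real_)
  methods::new("GroupModelFit", means = means, counts = counts,
               s2 = as.numeric(s2), df = as.numeric(df),
               groups = levels(groups))
}

## Newton inversion of the trigamma function (monotone decreasing)
.trigammaInverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method of moments on `z_g = log s2_g`: with
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, the prior solves
#' `trigamma(d0/2) = mean[(e_g - ebar)^2 * G/(G-1) - trigamma(d_g/2)]`
#' (Newton on the trigamma inverse) and
#' `s02 = exp(ebar + digamma(d0/2) - log(d0/2))`.  When the moment
#' right-hand side is nonpositive the prior degrees of freedom are infinite
#' and `s02 = exp(ebar)`.
#'
#' @param s2 per-protein residual variances.
#' @param df matching residual degrees of freedom.
#' @return an [EBPrior-class].
#' @export
estimateEBPrior <- function(s2, df) {
  use <- which(!is.na(s2) & df > 0 & s2 > 0)
  if (length(use) < 2L) {
    if (any(df > 0, na.rm = TRUE) && all(s2[df > 0] == 0, na.rm = TRUE))
      stop("all residual variances are zero; degenerate data")
    stop("need at least two proteins with positive variance and df")
  }
  s2 <- s2[use]; dfu <- df[use]
  G <- length(s2)
  e <- log(s2) - digamma(dfu / 2) + log(dfu / 2)
  ebar <- mean(e)
  v <- mean((e - ebar)^2 * G / (G - 1) - trigamma(dfu / 2))
  if (v > 0) {
    df0 <- 2 * .trigammaInverse(v)
    s02 <- exp(ebar + digamma(df0 / 2) - log(df0 / 2))
  } else {
    df0 <- Inf
    s02 <- exp(ebar)
  }
  methods::new("EBPrior", df0 = df0, s02 = s02)
}

## posterior (shrunken) variances
.posteriorVar <- function(s2, df, prior) {
  s2 <- ifelse(is.na(s2) & df == 0, 0, s2)
  if (is.infinite(prior@df0)) rep(prior@s02, length(s2))
  else (prior@df0 * prior@s02 + df * s2) / (prior@df0 + df)
}

## between-group mean square of a one-way layout, per protein
.betweenMS <- function(fit) {
  n <- rowSums(fit@counts)
  grand <- rowSums(fit@means * fit@counts, na.rm = TRUE) / n
  ssb <- rowSums(fit@counts * (fit@means - grand)^2, na.rm = TRUE)
  kPresent <- rowSums(fit@counts > 0)
  list(ms = ssb / pmax(kPresent - 1, 1), df1 = kPresent - 1)
}

#' Moderated F-test across age groups
#'
#' Refers the between-group mean square to the empirical-Bayes posterior
#' variance with `df1 = K - 1` and `df2 = d0 + d_g`.  With `df0 = 0` the
#' statistic reduces to the classical one-way ANOVA F; with `df0 = Inf`
#' every protein is tested against the common prior variance.
#'
#' @param fit a [GroupModelFit-class].
#' @param prior an [EBPrior-class]; pass `NULL` to estimate it from `fit`.
#' @return data.frame with columns `F`, `df1`, `df2`, `p`, `s2_post`, and a
#'   logical `degenerate` flag (posterior variance zero, p forced to 0).
#' @export
moderatedFTest <- function(fit, prior = NULL) {
  if (is.null(prior)) prior <- estimateEBPrior(fit@s2, fit@df)
  s2post <- .posteriorVar(fit@s2, fit@df, prior)
  b <- .betweenMS(fit)
  Fstat <- b$ms / s2post
  df2 <- prior@df0 + fit@df
  p <- stats::pf(Fstat, b$df1, df2, lower.tail = FALSE)
  degenerate <- s2post <= 0
  p[degenerate] <- 0
  Fstat[degenerate] <- Inf
  bad <- b$df1 < 1 | df2 <= 0
  p[bad] <- NA_real_
  data.frame(F = Fstat, df1 = b$df1, df2 = df2, p = p, s2_post = s2post,
             degenerate = degenerate, row.names = rownames(fit@means))
}

#' Classical one-way F-test
#'
#' The unmoderated companion of [moderatedFTest()]: identical layout with
#' each protein's own residual variance in the denominator (`df0 = 0`).
#'
#' @param fit a [GroupModelFit-class].
#' @return data.frame with columns `F`, `df1`, `df2`, `p`.
#' @export
classicalFTest <- function(fit) {
  b <- .betweenMS(fit)
  Fstat <- b$ms / fit@s2
  p <- stats::pf(Fstat, b$df1, fit@df, lower.tail = FALSE)
  p[fit@df <= 0 | b$df1 < 1] <- NA_real_
  data.frame(F = Fstat, df1 = b$df1, df2 = fit@df, p = p,
             row.names = rownames(fit@means))
}

#' Pairwise moderated t-test between two age groups
#'
#' Moderated t of `groupA - groupB` (by default 20 vs 3 months):
#' `t = (mu_a - mu_b) / sqrt(s2_post * (1/n_a + 1/n_b))` on `d0 + d_g`
#' degrees of freedom, two-sided p.
#'
#' @param fit a [GroupModelFit-class].
#' @param prior an [EBPrior-class]; `NULL` to estimate from `fit`.
#' @param groupA,groupB group labels (matched against `fit@groups`).
#' @return data.frame with `log2fc`, `t`, `df`, `p`; rows where either
#'   group is entirely missing are `NA` with `flagged = TRUE`.
#' @export
pairwiseModeratedT <- function(fit, prior = NULL, groupA = "20",
                               groupB = "3") {
  a <- match(as.character(groupA), fit@groups)
  b <- match(as.character(groupB), fit@groups)
  if (is.na(a) || is.na(b))
    stop("groups not found in the fit: ", groupA, ", ", groupB)
  if (is.null(prior)) prior <- estimateEBPrior(fit@s2, fit@df)
  s2post <- .posteriorVar(fit@s2, fit@df, prior)
  na <- fit@counts[, a]; nb <- fit@counts[, b]
  fc <- fit@means[, a] - fit@means[, b]
  se <- sqrt(s2post * (1 / na + 1 / nb))
  t <- fc / se
  df <- prior@df0 + fit@df
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  flagged <- na == 0 | nb == 0
  t[flagged] <- NA_real_; p[flagged] <- NA_real_; fc[flagged] <- NA_real_
  data.frame(log2fc = fc, t = t, df = df, p = p, flagged = flagged,
             row.names = rownames(fit@means))
}

#' Continuous-age linear trend test
#'
#' Per protein, ordinary least squares of abundance on age in months:
#' slope (log2 units per month), two-sided p on the slope, and the
#' coefficient of determination R^2.  Zero-variance proteins get slope 0,
#' p = 1, R^2 = 0.
#'
#' @param x protein x sample matrix.
#' @param age numeric age per sample (months).
#' @return data.frame with `slope`, `p`, `r2`, `n`.
#' @export
linearTrendTest <- function(x, age) {
  x <- as.matrix(x)
  if (length(age) != ncol(x)) stop("'age' must match the sample columns")
  G <- nrow(x)
  slope <- p <- r2 <- numeric(G)
  nOut <- integer(G)
  for (g in seq_len(G)) {
    ok <- !is.na(x[g, ])
    y <- x[g, ok]; a <- age[ok]
    n <- length(y)
    nOut[g] <- n
    if (n < 3 || length(unique(a)) < 3) {
      slope[g] <- NA_real_; p[g] <- NA_real_; r2[g] <- NA_real_
      next
    }
    sxx <- sum((a - mean(a))^2)
    syy <- sum((y - mean(y))^2)
    if (syy < 1e-14) { slope[g] <- 0; p[g] <- 1; r2[g] <- 0; next }
    sxy <- sum((a - mean(a)) * (y - mean(y)))
    b1 <- sxy / sxx
    rsq <- sxy^2 / (sxx * syy)
    sigma2 <- (syy - b1 * sxy) / (n - 2)
    if (sigma2 <= 0) { tval <- Inf } else tval <- b1 / sqrt(sigma2 / sxx)
    slope[g] <- b1
    r2[g] <- rsq
    p[g] <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  data.frame(slope = slope, p = p, r2 = r2, n = nOut,
             row.names = rownames(x))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (q-values), monotone after sorting and capped
#' at 1.  Validates the input range; NAs are passed through.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run all differential-expression tests for one organ
#'
#' Convenience wrapper: fits the group model, estimates the prior, and
#' returns every statistic in one table with per-method BH q-values and the
#' DEP flag (moderated-F q < `alpha`, strict).
#'
#' @param x protein x sample matrix (complete log2 abundances).
#' @param age numeric age per sample (months); groups are its distinct
#'   values in ascending order.
#' @param alpha DEP threshold on the moderated-F q-value.
#' @param groupA,groupB groups of the pairwise contrast.
#' @return list with `table` (data.frame: modF/modF_p/modF_q, log2fc/
#'   modT/modT_p/modT_q, classF/classF_p/classF_q, trend_slope/trend_p/
#'   trend_q/trend_r2, dep), `prior` and `fit`.
#' @export
runDiffexp <- function(x, age, alpha = 0.05, groupA = "20", groupB = "3") {
  fit <- fitGroupModel(x, age)
  prior <- estimateEBPrior(fit@s2, fit@df)
  mf <- moderatedFTest(fit, prior)
  cf <- classicalFTest(fit)
  pt <- pairwiseModeratedT(fit, prior, groupA, groupB)
  tr <- linearTrendTest(x, age)
  tab <- data.frame(
    modF = mf$F, modF_p = mf$p, modF_q = bhAdjust(mf$p),
    log2fc = pt$log2fc, modT = pt$t, modT_p = pt$p,
    modT_q = bhAdjust(pt$p),
    classF = cf$F, classF_p = cf$p, classF_q = bhAdjust(cf$p),
    trend_slope = tr$slope, trend_p = tr$p, trend_q = bhAdjust(tr$p),
    trend_r2 = tr$r2, row.names = rownames(x))
  tab$dep <- !is.na(tab$modF_q) & tab$modF_q < alpha
  list(table = tab, prior = prior, fit = fit)
}

#' Classify DEPs and compare detection methods
#'
#' Extracts, from a [runDiffexp()] table, the accession sets called at
#' `q < alpha` (strict) by each method, the pairwise overlap fractions
#' between methods (|A intersect B| / |A union B|), and the linear-trend
#' calls not made by the moderated F annotated with their R^2 (low-R^2
#' extra trend calls are the expected false/low-confidence identifications).
#'
#' @param table data.frame from [runDiffexp()].
#' @param alpha significance threshold (strict `<`).
#' @return list with `sets` (named list of accession vectors), `overlap`
#'   (method x method fraction matrix) and `trendExtra` (data.frame of
#'   trend-only accessions with R^2).
#' @export
classifyDEPs <- function(table, alpha = 0.05) {
  acc <- rownames(table)
  sets <- list(
    moderatedF = acc[!is.na(table$modF_q) & table$modF_q < alpha],
    pairwise = acc[!is.na(table$modT_q) & table$modT_q < alpha],
    classicalF = acc[!is.na(table$classF_q) & table$classF_q < alpha],
    trend = acc[!is.na(table$trend_q) & table$trend_q < alpha])
  m <- length(sets)
  overlap <- matrix(1, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    u <- length(union(sets[[i]], sets[[j]]))
    overlap[i, j] <- if (u == 0) 1 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  extra <- setdiff(sets$trend, sets$moderatedF)
  trendExtra <- data.frame(accession = extra,
                           r2 = table[extra, "trend_r2"],
                           row.names = NULL)
  list(sets = sets, overlap = overlap, trendExtra = trendExtra)
}
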
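## Random-intercept mixed model for age-by-tissue divergence.
##
## Per protein, the model  Expression ~ Age * Tissue + (1 | Mouse)  is
## fitted by maximum likelihood (not REML: the likelihood-ratio test
## compares fixed-effect structures) against the reduced model without the
## interaction.  The random intercept enters through the marginal
## covariance sigma^2 (I + lambda Z Z'), lambda = tau^2/sigma^2, profiled
## out by one-dimensional optimization: for fixed lambda the GLS estimates
## and the profiled sigma^2 are closed-form because each mouse block of
## (I + lambda J) inverts analytically.  Per-tissue linear trends on the
## significant proteins populate the Up/Down/NoChange directionality
## matrix and its convergence/divergence categories.

## V^{-1} M for V = I + lambda * block-J, by group sums
.vinv <- function(M, groups, lambda) {
  if (lambda == 0) return(M)
  M <- as.matrix(M)
  gs <- rowsum(M, groups)[levels(groups), , drop = FALSE]  # by level order
  n_g <- tabulate(groups)
  shrink <- lambda / (1 + lambda * n_g)
  M - (gs * shrink)[as.integer(groups), , drop = FALSE]
}

## profiled ML log-likelihood and estimates for fixed lambda
.mlAtLambda <- function(X, y, groups, lambda) {
  n <- length(y)
  ViX <- .vinv(X, groups, lambda)
  A <- crossprod(X, ViX)
  b <- crossprod(ViX, y)
  beta <- solve(A, b)
  r <- y - drop(X %*% beta)
  qf <- sum(r * .vinv(matrix(r), groups, lambda))
  sigma2 <- qf / n
  n_g <- tabulate(groups)
  logdet <- sum(log1p(lambda * n_g))
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2
  list(logLik = ll, beta = drop(beta), sigma2 = sigma2,
       tau2 = lambda * sigma2)
}

## maximize over lambda >= 0 (boundary checked explicitly)
.profiledML <- function(X, y, groups, lambdaMax = 1e3) {
  f <- function(l) .mlAtLambda(X, y, groups, l)$logLik
  opt <- stats::optimize(f, c(0, lambdaMax), maximum = TRUE, tol = 1e-7)
  atZero <- f(0)
  lambda <- if (atZero >= opt$objective) 0 else opt$maximum
  .mlAtLambda(X, y, groups, lambda)
}

#' Fit the age-by-tissue interaction mixed model for one protein
#'
#' Maximum-likelihood fits of the full (`~ age * tissue`) and reduced
#' (`~ age + tissue`) fixed-effect structures, both with a per-mouse random
#' intercept, and the likelihood-ratio test between them on `T - 1` degrees
#' of freedom (one interaction slope per non-reference tissue, age being
#' continuous).  `tau2 = 0` is an admissible boundary estimate.
#'
#' @param data data.frame with columns `y` (log2 abundance), `age`
#'   (months), `tissue`, `mouse`.
#' @return list with `fixef`, `tau2`, `sigma2`, `logLikFull`,
#'   `logLikReduced`, `lrt`, `df`, `p`.
#' @export
fitLmmInteraction <- function(data) {
  data$tissue <- factor(data$tissue)
  data$mouse <- factor(data$mouse)
  T <- nlevels(data$tissue)
  if (T < 2) stop("need at least two tissues")
  perTissueAges <- tapply(data$age, data$tissue,
                          function(a) length(unique(a)))
  if (any(perTissueAges < 2))
    stop("singular design: a tissue has a single age")
  Xf <- stats::model.matrix(~ age * tissue, data)
  Xr <- stats::model.matrix(~ age + tissue, data)
  full <- .profiledML(Xf, data$y, data$mouse)
  red <- .profiledML(Xr, data$y, data$mouse)
  lrt <- max(2 * (full$logLik - red$logLik), 0)
  df <- T - 1L
  list(fixef = full$beta, tau2 = full$tau2, sigma2 = full$sigma2,
       logLikFull = full$logLik, logLikReduced = red$logLik,
       lrt = lrt, df = df,
       p = stats::pchisq(lrt, df, lower.tail = FALSE))
}

## slope / p / r2 of y on age, simple OLS (shared with the trend test)
.olsTrend <- function(y, age) {
  ok <- !is.na(y)
  y <- y[ok]; a <- age[ok]
  n <- length(y)
  if (n < 3 || length(unique(a)) < 3)
    return(c(slope = NA, p = NA, r2 = NA))
  sxx <- sum((a - mean(a))^2)
  syy <- sum((y - mean(y))^2)
  if (syy < 1e-14) return(c(slope = 0, p = 1, r2 = 0))
  sxy <- sum((a - mean(a)) * (y - mean(y)))
  b1 <- sxy / sxx
  sigma2 <- (syy - b1 * sxy) / (n - 2)
  tval <- if (sigma2 <= 0) Inf else b1 / sqrt(sigma2 / sxx)
  c(slope = b1, p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE),
    r2 = sxy^2 / (sxx * syy))
}

#' Per-tissue linear age trend
#'
#' Ordinary least squares of abundance on age within one tissue; the same
#' contract as [linearTrendTest()] applied to a tissue subset.
#'
#' @param data data.frame with `y`, `age`, `tissue`.
#' @param tissue tissue label to subset.
#' @return named vector `slope`, `p`, `r2`.
#' @export
perTissueTrend <- function(data, tissue) {
  sub <- data[data$tissue == tissue, ]
  .olsTrend(sub$y, sub$age)
}

#' Build the directionality matrix and divergence categories
#'
#' Entries: `Up` if the tissue trend has `p < pThreshold` and positive
#' slope, `Down` for a negative slope, else `NoChange`.  Categories per
#' protein: `consistent-up` / `consistent-down` (at least two tissues in
#' the same nonzero direction, none opposite), `divergent` (at least one Up
#' and one Down; the opposing tissue pairs are listed), `tissue-specific`
#' (exactly one non-NoChange entry), else `no-change`.
#'
#' @param trends data.frame with columns `protein`, `tissue`, `slope`, `p`.
#' @param pThreshold raw p-value threshold for calling a direction.
#' @return list with `matrix` (protein x tissue character matrix),
#'   `categories` (data.frame: protein, category, detail).
#' @export
directionalityMatrix <- function(trends, pThreshold = 0.05) {
  prot <- unique(trends$protein)
  tis <- unique(trends$tissue)
  M <- matrix("NoChange", length(prot), length(tis),
              dimnames = list(prot, tis))
  call <- ifelse(is.na(trends$p) | trends$p >= pThreshold, "NoChange",
                 ifelse(trends$slope > 0, "Up",
                        ifelse(trends$slope < 0, "Down", "NoChange")))
  M[cbind(match(trends$protein, prot), match(trends$tissue, tis))] <- call
  cat <- detail <- character(length(prot))
  for (i in seq_along(prot)) {
    ups <- tis[M[i, ] == "Up"]; downs <- tis[M[i, ] == "Down"]
    nU <- length(ups); nD <- length(downs)
    if (nU >= 1 && nD >= 1) {
      cat[i] <- "divergent"
      pairs <- expand.grid(up = ups, down = downs)
      detail[i] <- paste(paste0(pairs$up, "+/", pairs$down, "-"),
                         collapse = ";")
    } else if (nU + nD == 1) {
      cat[i] <- "tissue-specific"
      detail[i] <- c(ups, downs)
    } else if (nU >= 2) {
      cat[i] <- "consistent-up"
      detail[i] <- paste(ups, collapse = ";")
    } else if (nD >= 2) {
      cat[i] <- "consistent-down"
      detail[i] <- paste(downs, collapse = ";")
    } else {
      cat[i] <- "no-change"
      detail[i] <- ""
    }
  }
  list(matrix = M,
       categories = data.frame(protein = prot, category = cat,
                               detail = detail, row.names = NULL))
}

#' Run the mixed-model divergence analysis across organs
#'
#' For each protein present in every supplied organ matrix: fit the
#' interaction LMM, BH-adjust the LRT p-values, and, for proteins with
#' `q < alpha`, call per-tissue trends and assemble the directionality
#' matrix.
#'
#' @param matrices named list (organ -> protein x sample matrix, complete).
#' @param metadata sample metadata with `sample_id`, `organ`, `age_months`,
#'   `mouse_id`.
#' @param alpha BH threshold on the LRT.
#' @param pThreshold raw threshold for per-tissue direction calls.
#' @return list with `lmm` (data.frame per protein: lrt, df, p, q, tau2,
#'   sigma2), `directionality` (see [directionalityMatrix()]; only
#'   significant proteins) and `skipped` (proteins with singular designs).
#' @export
runLmmDivergence <- function(matrices, metadata, alpha = 0.05,
                             pThreshold = 0.05) {
  organs <- names(matrices)
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0) stop("no proteins shared across all organs")
  meta <- split(metadata, metadata$organ)
  long0 <- do.call(rbind, lapply(organs, function(org) {
    m <- meta[[org]]
    data.frame(tissue = org, age = m$age_months, mouse = m$mouse_id,
               sample = m$sample_id, stringsAsFactors = FALSE)
  }))
  res <- vector("list", length(shared))
  skipped <- character()
  for (i in seq_along(shared)) {
    g <- shared[i]
    y <- unlist(lapply(organs, function(org)
      matrices[[org]][g, meta[[org]]$sample_id]))
    df <- cbind(long0, y = as.numeric(y))
    fit <- tryCatch(fitLmmInteraction(df), error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, g); next }
    res[[i]] <- data.frame(protein = g, lrt = fit$lrt, df = fit$df,
                           p = fit$p, tau2 = fit$tau2,
                           sigma2 = fit$sigma2)
  }
  lmm <- do.call(rbind, res)
  lmm$q <- bhAdjust(lmm$p)
  sig <- lmm$protein[lmm$q < alpha]
  trends <- NULL
  if (length(sig)) {
    trends <- do.call(rbind, lapply(sig, function(g) {
      do.call(rbind, lapply(organs, function(org) {
        m <- meta[[org]]
        tr <- .olsTrend(matrices[[org]][g, m$sample_id], m$age_months)
        data.frame(protein = g, tissue = org, slope = tr["slope"],
                   p = tr["p"], r2 = tr["r2"], row.names = NULL)
      }))
    }))
  }
  direction <- if (!is.null(trends))
    directionalityMatrix(trends, pThreshold) else NULL
  list(lmm = lmm, trends = trends, directionality = direction,
       skipped = skipped)
}
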
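## Normalization, robust peptide-to-protein summarization, imputation.
##
## Peptide intensities are log2-transformed and median-centered per sample.
## Peptides are aggregated to protein abundances with an additive two-way
## model y_ps = beta_s + alpha_p fitted by iteratively reweighted least
## squares with Huber weights (sum-to-zero constraint on peptide effects);
## the sample effects beta_s are the protein abundances.  Remaining missing
## protein values are imputed by iterative random-forest regression with the
## missForest stopping rule (stop at the first increase of the imputation
## change), or by a fast k-nearest-row imputer.

#' Log2-transform and median-center an intensity matrix
#'
#' Applies `x -> log2(x)` and subtracts each sample's median of observed
#' values, so that after centering every sample's observed median is zero.
#' Centering is idempotent and invariant to per-sample scale factors.
#'
#' @param x numeric matrix of raw intensities (positive where observed), or
#'   a `SummarizedExperiment` whose first assay holds them.
#' @param center subtract per-sample medians (default TRUE).
#' @return object of the same kind with log2, centered values in assay
#'   `log2intensity` (for a `SummarizedExperiment`) or as a matrix.
#' @export
logAndCenter <- function(x, center = TRUE) {
  se <- NULL
  if (methods::is(x, "SummarizedExperiment")) {
    se <- x
    x <- SummarizedExperiment::assay(x, 1)
  }
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive intensity at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  lx <- log2(x)
  if (center) {
    med <- apply(lx, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    lx <- sweep(lx, 2, med)
  }
  if (is.null(se)) return(lx)
  SummarizedExperiment::assays(se)$log2intensity <- lx
  se
}

## Huber weight for standardized residuals
.huberWeight <- function(u, k) {
  w <- rep(1, length(u))
  big <- abs(u) > k
  w[big] <- k / abs(u[big])
  w
}

#' Robust two-way summarization of one protein's peptides
#'
#' Fits the additive model `y_ps = beta_s + alpha_p + e` over the observed
#' cells of a peptide x sample log2 submatrix by IRLS with Huber weights
#' (tuning constant `k`, default 1.345 for 95% Gaussian efficiency) and a
#' sum-to-zero constraint on the peptide effects, and returns the sample
#' effects as the protein's abundance profile.  Samples with no observed
#' peptide yield `NA`.  With `k = Inf` the fit is ordinary least squares.
#'
#' @param y numeric matrix (peptides x samples), log2 scale, NAs allowed.
#' @param k Huber tuning constant.
#' @param maxIter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return named numeric vector of per-sample abundances.
#' @export
robustSummarize <- function(y, k = 1.345, maxIter = 20L, tol = 1e-6) {
  y <- as.matrix(y)
  if (nrow(y) < 1L) stop("need at least one peptide row")
  sampleNames <- colnames(y) %||% paste0("S", seq_len(ncol(y)))
  if (nrow(y) == 1L) {
    out <- as.numeric(y[1, ])
    names(out) <- sampleNames
    return(out)
  }
  obs <- which(!is.na(y), arr.ind = TRUE)
  val <- y[obs]
  sampleF <- factor(obs[, 2], levels = seq_len(ncol(y)))
  pepF <- droplevels(factor(obs[, 1], levels = seq_len(nrow(y))))
  keepPep <- nlevels(pepF) > 1L
  X <- stats::model.matrix(~ 0 + sampleF)
  if (keepPep) {
    P <- stats::model.matrix(~ pepF,
                             contrasts.arg = list(pepF = "contr.sum"))
    X <- cbind(X, P[, -1, drop = FALSE])
  }
  w <- rep(1, length(val))
  coefOld <- rep(0, ncol(X))
  for (it in seq_len(maxIter)) {
    fit <- stats::lm.wfit(X, val, w)
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    r <- val - drop(X %*% coef)
    if (max(abs(coef - coefOld)) < tol) { coefOld <- coef; break }
    coefOld <- coef
    if (is.infinite(k)) next
    s <- stats::mad(r, center = 0)
    if (s < 1e-12) break
    w <- .huberWeight(r / s, k)
  }
  beta <- coefOld[seq_len(ncol(y))]
  beta[tabulate(sampleF, ncol(y)) == 0L] <- NA_real_
  names(beta) <- sampleNames
  beta
}

#' Summarize a peptide-level experiment to protein abundances
#'
#' Groups the log2 peptide matrix by master protein accession and applies
#' [robustSummarize()] per protein.
#'
#' @param se peptide-level `SummarizedExperiment` with assay
#'   `log2intensity` (see [logAndCenter()]) and rowData `master_accession`.
#' @param ... passed to [robustSummarize()].
#' @return protein x sample `SummarizedExperiment` with assay
#'   `log2abundance` (NAs where all peptides missing) and rowData
#'   `n_peptides`.
#' @export
summarizeProteins <- function(se, ...) {
  lx <- SummarizedExperiment::assay(se, "log2intensity")
  acc <- as.character(SummarizedExperiment::rowData(se)$master_accession)
  accU <- unique(acc)
  out <- matrix(NA_real_, length(accU), ncol(lx),
                dimnames = list(accU, colnames(lx)))
  support <- integer(length(accU))
  for (i in seq_along(accU)) {
    sub <- lx[acc == accU[i], , drop = FALSE]
    support[i] <- nrow(sub)
    out[i, ] <- robustSummarize(sub, ...)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2abundance = out),
    rowData = S4Vectors::DataFrame(n_peptides = support,
                                   row.names = accU),
    colData = SummarizedExperiment::colData(se))
}

.impute_rf <- function(x, maxIter, nTree, seed) {
  set.seed(.deriveSeed(seed, "impute"))
  miss <- is.na(x)
  rowMu <- rowMeans(x, na.rm = TRUE)
  cur <- x
  cur[miss] <- rowMu[row(x)[miss]]
  targets <- order(rowSums(miss))
  targets <- targets[rowSums(miss)[targets] > 0]
  prev <- cur
  deltaOld <- Inf
  iterations <- 0L
  delta <- NA_real_
  for (it in seq_len(maxIter)) {
    new <- cur
    for (i in targets) {
      obsS <- !miss[i, ]
      xs <- t(new[-i, , drop = FALSE])
      fit <- randomForest::randomForest(
        x = xs[obsS, , drop = FALSE], y = new[i, obsS], ntree = nTree)
      new[i, !obsS] <- stats::predict(fit, xs[!obsS, , drop = FALSE])
    }
    delta <- sum((new[miss] - cur[miss])^2) / max(sum(new[miss]^2), 1e-12)
    iterations <- it
    if (delta > deltaOld) break  # missForest rule: keep previous iterate
    prev <- new
    cur <- new
    deltaOld <- delta
  }
  list(matrix = prev, iterations = iterations, delta = deltaOld)
}

.impute_knn <- function(x, k) {
  miss <- is.na(x)
  out <- x
  rowMu <- rowMeans(x, na.rm = TRUE)
  for (i in which(rowSums(miss) > 0)) {
    d <- apply(x, 1, function(r) {
      shared <- !is.na(r) & !miss[i, ]
      if (sum(shared) < 2) return(Inf)
      mean((r[shared] - x[i, shared])^2)
    })
    d[i] <- Inf
    for (s in which(miss[i, ])) {
      donors <- which(!is.na(x[, s]) & is.finite(d))
      donors <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
      out[i, s] <- if (length(donors)) mean(x[donors, s]) else rowMu[i]
    }
  }
  list(matrix = out, iterations = 1L, delta = 0)
}

#' Impute missing protein abundances
#'
#' Iterative random-forest imputation: missing cells are initialized with
#' row means, then each protein with missing values is regressed on all
#' other proteins across samples and its missing cells re-predicted; the
#' loop stops when the normalized change in imputed values first increases
#' (returning the previous iterate) or `maxIter` is reached.  A k-nearest-row
#' imputer (`method = "knn"`) is provided for speed.  Proteins observed in
#' fewer than `minObsFrac` of samples are dropped (logged), not imputed.
#' Observed cells are never altered; results are deterministic under `seed`.
#'
#' @param x protein x sample matrix with NAs, or a `SummarizedExperiment`
#'   with assay `log2abundance`.
#' @param method `"rf"` or `"knn"`.
#' @param maxIter iteration cap for the random-forest loop.
#' @param nTree trees per forest.
#' @param k neighbors for the knn imputer.
#' @param minObsFrac minimum observed fraction per protein.
#' @param seed integer seed.
#' @return list with `matrix` (complete; or a `SummarizedExperiment` when
#'   one was supplied, with added assay `imputed`) and `log`
#'   (cells imputed, proteins dropped, iterations, final delta).
#' @export
imputeMissing <- function(x, method = c("rf", "knn"), maxIter = 10L,
                          nTree = 100L, k = 6L, minObsFrac = 0.5,
                          seed = 1L) {
  method <- match.arg(method)
  se <- NULL
  if (methods::is(x, "SummarizedExperiment")) {
    se <- x
    x <- SummarizedExperiment::assay(x, "log2abundance")
  }
  obsFrac <- rowMeans(!is.na(x))
  keep <- obsFrac >= minObsFrac
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (!is.null(se)) se <- se[keep, ]
  nMissing <- sum(is.na(x))
  if (nMissing == 0L) {
    res <- list(matrix = x, iterations = 0L, delta = 0)
  } else if (method == "rf") {
    res <- .impute_rf(x, maxIter, nTree, seed)
  } else {
    res <- .impute_knn(x, k)
  }
  log <- list(method = method, cells_imputed = nMissing,
              proteins_dropped = length(dropped),
              dropped = dropped, iterations = res$iterations,
              final_delta = res$delta)
  if (length(dropped))
    message(length(dropped), " protein(s) below the ", minObsFrac,
            " observed fraction dropped before imputation")
  if (!is.null(se)) {
    SummarizedExperiment::assays(se)$imputed <- res$matrix
    return(list(matrix = se, log = log))
  }
  list(matrix = res$matrix, log = log)
}
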
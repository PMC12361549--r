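## Age-trajectory construction and fuzzy c-means clustering.
##
## DEP abundance profiles are z-scored per protein across samples and
## averaged within age groups; the resulting protein x age matrix is
## clustered by fuzzy c-means (Euclidean distance, fuzzifier m estimated
## from the data dimensions), with the cluster number chosen among 2-4 by
## partition coefficient / partition entropy, and summarized by the
## most-enriched cluster (high mean membership, low SD) and by the PC1
## trajectory over ages.

#' Fuzzy c-means clustering result
#'
#' @slot centers cluster x age matrix of center trajectories.
#' @slot membership protein x cluster membership matrix; rows sum to 1.
#' @slot m fuzzifier (> 1).
#' @slot objective final value of the fuzzy within-cluster objective.
#' @slot pc partition coefficient, in `[1/c, 1]`.
#' @slot pe partition entropy, in `[0, ln c]`.
#' @export
setClass("FuzzyClustering", representation(
  centers = "matrix", membership = "matrix", m = "numeric",
  objective = "numeric", pc = "numeric", pe = "numeric"))

setValidity("FuzzyClustering", function(object) {
  rs <- rowSums(object@membership)
  if (any(abs(rs - 1) > 1e-9)) return("membership rows must sum to 1")
  if (object@m <= 1) return("fuzzifier m must be > 1")
  TRUE
})

setMethod("show", "FuzzyClustering", function(object) {
  cat(sprintf(
    "FuzzyClustering: %d proteins, %d clusters, m = %.3f\n  PC = %.3f, PE = %.3f, objective = %.4g\n",
    nrow(object@membership), ncol(object@membership), object@m,
    object@pc, object@pe, object@objective))
})

#' z-scored mean age profiles for a DEP set
#'
#' Per protein: standardize across all samples (z-score), then average the
#' z-scores within each age group, ages in chronological order.  Proteins
#' with zero variance are excluded and counted in the `excluded` attribute.
#'
#' @param x protein x sample matrix (log2 abundances).
#' @param age numeric age per sample.
#' @param deps accessions to keep (default: all rows).
#' @return DEP x age matrix of mean z-scores, column names the sorted ages;
#'   attribute `excluded` holds the dropped accessions.
#' @export
zscoreProfiles <- function(x, age, deps = rownames(x)) {
  x <- as.matrix(x)[intersect(deps, rownames(x)), , drop = FALSE]
  if (nrow(x) == 0L) stop("DEP set is empty after matching row names")
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(sd) & sd > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  ages <- sort(unique(age))
  out <- sapply(ages, function(a)
    rowMeans(z[, age == a, drop = FALSE], na.rm = TRUE))
  out <- matrix(out, nrow = sum(keep),
                dimnames = list(rownames(x)[keep], as.character(ages)))
  attr(out, "excluded") <- rownames(x)[!keep]
  out
}

#' Estimate the fuzzy c-means fuzzifier from the data dimensions
#'
#' Empirical formula relating the recommended fuzzifier to the number of
#' profiles N and their dimension D:
#' `m = 1 + (1418/N + 22.05) * D^-2 +
#'      (12.33/N + 0.243) * D^(-0.0406*ln(N) - 0.1134)`.
#'
#' @param nProteins number of clustered profiles (N).
#' @param nAges profile dimension (D, number of age groups).
#' @return fuzzifier m (> 1).
#' @export
estimateFuzzifier <- function(nProteins, nAges) {
  N <- nProteins; D <- nAges
  if (N < 2 || D < 2) stop("need at least 2 proteins and 2 ages")
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering of age trajectories
#'
#' Alternates the Bezdek membership and center updates
#' (`u_ic = 1 / sum_j (d_ic/d_ij)^(2/(m-1))`,
#' `v_c = sum_i u_ic^m x_i / sum_i u_ic^m`) until the maximum center shift
#' falls below `tol`; the best of `nRestarts` seeded random-protein
#' initializations (by objective) is returned.  A profile coinciding
#' exactly with a center is assigned crisply.  The objective is verified to
#' be nonincreasing across iterations.
#'
#' @param X protein x age matrix (z-scored profiles).
#' @param c number of clusters (`c = 1` returns the mean profile with all
#'   memberships 1).
#' @param m fuzzifier; default estimated via [estimateFuzzifier()].
#' @param tol convergence tolerance on the center shift.
#' @param maxIter iteration cap per restart.
#' @param nRestarts random restarts.
#' @param seed integer seed.
#' @return a [FuzzyClustering-class].
#' @export
fuzzyCMeans <- function(X, c, m = NULL, tol = 1e-6, maxIter = 300L,
                        nRestarts = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (c > n) stop("more clusters than profiles (c = ", c, ", n = ", n, ")")
  if (is.null(m)) m <- estimateFuzzifier(n, ncol(X))
  if (c == 1L) {
    ctr <- matrix(colMeans(X), 1, ncol(X),
                  dimnames = list(NULL, colnames(X)))
    U <- matrix(1, n, 1, dimnames = list(rownames(X), NULL))
    obj <- sum(sweep(X, 2, ctr[1, ])^2)
    idx <- partitionIndices(U)
    return(methods::new("FuzzyClustering", centers = ctr, membership = U,
                        m = m, objective = obj, pc = idx$pc, pe = idx$pe))
  }
  set.seed(.deriveSeed(seed, "trajectory"))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    centers <- X[sample(n, c), , drop = FALSE]
    objPrev <- Inf
    for (it in seq_len(maxIter)) {
      d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2 <- pmax(d2, 0)
      U <- matrix(0, n, c)
      zero <- d2 < 1e-300
      hasZero <- rowSums(zero) > 0
      if (any(hasZero))
        U[hasZero, ] <- zero[hasZero, , drop = FALSE] /
          rowSums(zero[hasZero, , drop = FALSE])
      if (any(!hasZero)) {
        ## normalize by the row minimum so small fuzzifiers cannot underflow
        sub <- d2[!hasZero, , drop = FALSE]
        rmin <- do.call(pmin, as.data.frame(sub))
        w <- (sub / rmin)^(-1 / (m - 1))
        U[!hasZero, ] <- w / rowSums(w)
      }
      obj <- sum(U^m * d2)
      if (obj > objPrev + 1e-8)
        stop("fuzzy c-means objective increased; numerical failure")
      objPrev <- obj
      um <- U^m
      newCenters <- (t(um) %*% X) / colSums(um)
      shift <- max(abs(newCenters - centers))
      centers <- newCenters
      if (shift < tol) break
    }
    if (is.null(best) || objPrev < best$obj)
      best <- list(centers = centers, U = U, obj = objPrev)
  }
  dimnames(best$centers) <- list(paste0("cluster", seq_len(c)), colnames(X))
  dimnames(best$U) <- list(rownames(X), rownames(best$centers))
  idx <- partitionIndices(best$U)
  methods::new("FuzzyClustering", centers = best$centers,
               membership = best$U, m = m, objective = best$obj,
               pc = idx$pc, pe = idx$pe)
}

#' Partition coefficient and partition entropy
#'
#' Cluster-validity indices of a membership matrix:
#' `PC = mean_i sum_c u_ic^2` (1 for a crisp partition, `1/c` for the
#' uniform one) and `PE = -mean_i sum_c u_ic ln(u_ic)` with `0 ln 0 := 0`
#' (0 crisp, `ln c` uniform).
#'
#' @param U membership matrix, rows summing to 1.
#' @return list with `pc` and `pe`.
#' @export
partitionIndices <- function(U) {
  U <- as.matrix(U)
  if (any(abs(rowSums(U) - 1) > 1e-9))
    stop("membership rows must sum to 1")
  pc <- mean(rowSums(U^2))
  lu <- ifelse(U > 0, log(U), 0)
  pe <- -mean(rowSums(U * lu))
  list(pc = pc, pe = pe)
}

#' Choose the cluster count by partition indices
#'
#' Runs [fuzzyCMeans()] for each candidate `c` and reports PC, PE and the
#' normalized partition coefficient `(PC - 1/c) / (1 - 1/c)`; the candidate
#' maximizing the normalized PC wins, ties broken by smaller PE then
#' smaller c.  A winning normalized PC below 0.1 flags the selection as
#' low-confidence (structureless data).
#'
#' @param X protein x age matrix.
#' @param cCandidates candidate cluster counts (default 2:4).
#' @param m fuzzifier; default from [estimateFuzzifier()].
#' @param seed integer seed.
#' @param ... passed to [fuzzyCMeans()].
#' @return list with `c` (chosen), `table` (per-candidate indices),
#'   `clustering` (the chosen [FuzzyClustering-class]) and `lowConfidence`.
#' @export
selectClusterCount <- function(X, cCandidates = 2:4, m = NULL, seed = 1L,
                               ...) {
  if (length(cCandidates) == 1L) {
    warning("single candidate cluster count; returning it as-is")
    cl <- fuzzyCMeans(X, cCandidates, m = m, seed = seed, ...)
    npc <- (cl@pc - 1 / cCandidates) / (1 - 1 / cCandidates)
    return(list(c = cCandidates,
                table = data.frame(c = cCandidates, pc = cl@pc, pe = cl@pe,
                                   normalized_pc = npc),
                clustering = cl, lowConfidence = npc < 0.1))
  }
  fits <- lapply(cCandidates, function(cc)
    fuzzyCMeans(X, cc, m = m, seed = seed, ...))
  tab <- data.frame(
    c = cCandidates,
    pc = vapply(fits, function(f) f@pc, 0),
    pe = vapply(fits, function(f) f@pe, 0))
  tab$normalized_pc <- (tab$pc - 1 / tab$c) / (1 - 1 / tab$c)
  ord <- order(-tab$normalized_pc, tab$pe, tab$c)
  pick <- ord[1]
  list(c = cCandidates[pick], table = tab, clustering = fits[[pick]],
       lowConfidence = tab$normalized_pc[pick] < 0.1)
}

#' Per-cluster membership summaries and the most-enriched cluster
#'
#' Hard-assigns each protein to its maximum-membership cluster (ties to the
#' lower index) and reports, per cluster, the member count and the mean and
#' SD of the members' membership values.  The most-enriched cluster has the
#' highest mean membership, ties broken by the smaller SD; empty clusters
#' are excluded from the ranking.
#'
#' @param clustering a [FuzzyClustering-class].
#' @return list with `summary` (data.frame: cluster, n, mean_membership,
#'   sd_membership), `assignment` (named integer vector) and
#'   `mostEnriched` (cluster index).
#' @export
clusterSummaries <- function(clustering) {
  U <- clustering@membership
  hard <- max.col(U, ties.method = "first")
  own <- U[cbind(seq_len(nrow(U)), hard)]
  c <- ncol(U)
  n <- tabulate(hard, c)
  mu <- sdv <- rep(NA_real_, c)
  for (k in seq_len(c)) {
    v <- own[hard == k]
    if (length(v)) {
      mu[k] <- mean(v)
      sdv[k] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  summary <- data.frame(cluster = seq_len(c), n = n, mean_membership = mu,
                        sd_membership = sdv)
  nonEmpty <- which(n > 0)
  ord <- nonEmpty[order(-mu[nonEmpty], sdv[nonEmpty])]
  names(hard) <- rownames(U)
  list(summary = summary, assignment = hard, mostEnriched = ord[1])
}

#' PC1 trajectory over ages
#'
#' Principal components of the protein x age matrix with ages as variables
#' (column-centered): the PC1 loading per age is the dominant shared age
#' trajectory, and its variance fraction says how much of the between-age
#' structure one trajectory explains.  The sign is fixed so that PC1
#' correlates positively with the mean profile.
#'
#' @param X protein x age matrix (z-scored profiles).
#' @return list with `scores` (PC1 value per age), `varianceExplained`
#'   (fraction for PC1), `allFractions` (summing to 1 over components) and
#'   `signFlipped`.
#' @export
pc1Trajectory <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 proteins and >= 2 ages")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  if (tot < 1e-14) stop("matrix has rank 0 after centering")
  fractions <- pr$sdev^2 / tot
  v1 <- pr$rotation[, 1]
  flip <- FALSE
  ref <- colMeans(X) - mean(colMeans(X))
  if (sum(v1 * ref) < 0) { v1 <- -v1; flip <- TRUE }
  list(scores = v1, varianceExplained = fractions[1],
       allFractions = fractions, signFlipped = flip)
}
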
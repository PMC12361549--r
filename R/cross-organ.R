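## Cross-organ DEP set algebra.
##
## UpSet-style exclusive intersections, hypergeometric overlap tests
## (pairwise and a convolution-based three-way test), blood-proteome
## subtraction, and Spearman correlation of shared-DEP age trajectories.

#' UpSet-style intersections of per-organ DEP sets
#'
#' Computes the exclusive count of every nonempty organ combination (each
#' protein counted once, in its exact membership pattern, so the exclusive
#' counts sum to the union size), the inclusive pairwise and triple overlap
#' counts, and each organ's dominant fraction (share of its DEPs found in
#' no other organ).
#'
#' @param sets named list of accession character vectors, one per organ.
#' @return list with `exclusive` (data.frame: combination, degree, count),
#'   `pairwise` (organ x organ inclusive overlap matrix), `triples`
#'   (data.frame of all organ triples with inclusive counts) and
#'   `dominantFraction` (named vector).
#' @export
depIntersections <- function(sets) {
  if (length(sets) < 2L) stop("need at least two organ sets")
  organs <- names(sets)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(universe, organs))
  pattern <- apply(memb, 1, function(r) paste(organs[r], collapse = "&"))
  tab <- table(pattern)
  exclusive <- data.frame(
    combination = names(tab),
    degree = vapply(strsplit(names(tab), "&", fixed = TRUE), length, 0L),
    count = as.integer(tab), row.names = NULL)
  exclusive <- exclusive[order(-exclusive$count), ]

  m <- length(organs)
  pairwise <- matrix(0L, m, m, dimnames = list(organs, organs))
  for (i in seq_len(m)) for (j in seq_len(m))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  triples <- NULL
  if (m >= 3) {
    cmb <- utils::combn(m, 3)
    triples <- data.frame(
      organs = apply(cmb, 2, function(ix)
        paste(organs[ix], collapse = "&")),
      count = apply(cmb, 2, function(ix)
        length(Reduce(intersect, sets[ix]))), row.names = NULL)
  }
  dominant <- vapply(seq_len(m), function(i) {
    s <- sets[[i]]
    if (length(s) == 0) return(NA_real_)
    others <- unique(unlist(sets[-i]))
    sum(!s %in% others) / length(s)
  }, 0)
  names(dominant) <- organs
  list(exclusive = exclusive, pairwise = pairwise, triples = triples,
       dominantFraction = dominant)
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for the overlap of two sets of sizes `K` and `n` drawn from
#' a universe of size `N` (exact tail, log-stable through
#' `stats::phyper`).  Exchangeable in `K` and `n`.
#'
#' @param k observed overlap.
#' @param K,n set sizes.
#' @param N universe size.
#' @return upper-tail probability.
#' @export
hypergeomOverlapTest <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("infeasible hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Three-way overlap probability by hypergeometric convolution
#'
#' `P(|A∩B∩C| >= k)` for three independent uniformly random subsets of
#' sizes `sizes` in a universe of size `N`, computed by conditioning on the
#' intermediate overlap `j = |A∩B|`:
#' `sum_j P(|A∩B| = j) * P(Hypergeom(N, j, K3) >= k)`.
#'
#' @param k observed triple overlap.
#' @param sizes length-3 vector of set sizes.
#' @param N universe size.
#' @return upper-tail probability.
#' @export
tripleOverlapTest <- function(k, sizes, N) {
  if (length(sizes) != 3L || any(sizes > N) || k < 0 || k > min(sizes))
    stop("infeasible parameters for the three-way overlap test")
  if (k == 0) return(1)
  K1 <- sizes[1]; K2 <- sizes[2]; K3 <- sizes[3]
  js <- seq.int(max(k, K1 + K2 - N, 0), min(K1, K2))
  if (length(js) == 0 || js[1] > min(K1, K2)) return(0)
  pj <- stats::dhyper(js, K1, N - K1, K2)
  tails <- stats::phyper(k - 1, js, N - js, K3, lower.tail = FALSE)
  min(sum(pj * tails), 1)
}

#' Subtract blood-associated proteins from DEP sets
#'
#' Set difference of each organ's DEPs against a blood-associated accession
#' list, with before/after bookkeeping, used to expose organ-dominant
#' (non-blood) aging signal in data from non-perfused organs.
#'
#' @param sets named list of per-organ DEP accession vectors.
#' @param blood character vector of blood-associated accessions (an empty
#'   list passes through with a warning).
#' @return list with `sets` (filtered), `removed` (per-organ counts) and
#'   `before`/`after` counts.
#' @export
filterBloodProteins <- function(sets, blood) {
  if (length(blood) == 0L) {
    warning("empty blood list; DEP sets passed through unchanged")
    return(list(sets = sets,
                removed = vapply(sets, function(s) 0L, 0L),
                before = lengths(sets), after = lengths(sets)))
  }
  filtered <- lapply(sets, setdiff, y = blood)
  list(sets = filtered,
       removed = lengths(sets) - lengths(filtered),
       before = lengths(sets), after = lengths(filtered))
}

## all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Spearman correlation of two age trajectories
#'
#' Spearman's rank correlation of two equal-length mean z-profiles, with an
#' exact permutation p-value (two-sided, over all orderings) for up to 6
#' ages and the asymptotic t approximation beyond.  Constant profiles give
#' an undefined correlation, flagged rather than erroring.
#'
#' @param a,b numeric age profiles of equal length (>= 4 recommended).
#' @return list with `rho`, `p`, `n`, and `degenerate`.
#' @export
trajectoryCorrelation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(a, b, method = "spearman")
  if (n <= 6) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(ix)
      stats::cor(a, b[ix], method = "spearman"))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE)$p.value)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}
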
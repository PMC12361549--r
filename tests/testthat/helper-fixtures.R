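## Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

## small two-organ study used by several module tests
tinyStudy <- function(nProteins = 60, organs = c("kidney", "spleen"),
                      seed = 3, ...) {
  simulateStudy(syntheticConfig(organs = organs, nProteins = nProteins,
                                seed = seed, ...))
}

## run one organ of a study through qc + summarization + imputation
organMatrix <- function(study, organ, impute = "knn", center = TRUE) {
  m <- study$metadata[study$metadata$organ == organ, ]
  d <- tempfile()
  writeStudy(study, d)
  rec <- readPeptideTable(file.path(d, paste0("peptides_", organ, ".tsv")),
                          m)
  fl <- filterPeptides(rec)
  se <- buildIntensityMatrix(fl$records, m)
  pse <- summarizeProteins(logAndCenter(se, center = center))
  imp <- suppressMessages(imputeMissing(pse, method = impute))
  list(matrix = SummarizedExperiment::assay(imp$matrix, "imputed"),
       meta = m, se = se, truth = study$truth)
}

## ten-record QC fixture: records 1..6 each violate exactly one rule
qcFixture <- function() {
  data.frame(
    sequence = sprintf("PEPTIDEK%02d", 1:10),
    master_accession = c("", rep("P1", 9)),
    quan_info = c("", "NoQuanValues", rep("", 8)),
    n_protein_groups = c(1L, 1L, 2L, rep(1L, 7)),
    psm_ambiguity = c(rep("Unambiguous", 3), "Ambiguous",
                      rep("Unambiguous", 6)),
    pep = c(rep(0.01, 4), 0.2, rep(0.01, 5)),
    q_value = c(rep(0.01, 5), 0.2, rep(0.01, 4)),
    S1 = 100, S2 = 200,
    stringsAsFactors = FALSE)
}

## brute-force maximal cliques by subset enumeration (n <= 12)
bruteMaximalCliques <- function(adj) {
  n <- nrow(adj)
  isClique <- function(s) {
    if (length(s) <= 1) return(TRUE)
    all(adj[t(utils::combn(s, 2))] == 1)
  }
  subsets <- unlist(lapply(seq_len(n), function(sz)
    utils::combn(n, sz, simplify = FALSE)), recursive = FALSE)
  cl <- Filter(isClique, subsets)
  Filter(function(s) {
    !any(vapply(setdiff(seq_len(n), s), function(v)
      isClique(c(s, v)), TRUE))
  }, cl)
}

## brute-force MCC from enumerated cliques
bruteMCC <- function(adj) {
  cl <- bruteMaximalCliques(adj)
  scores <- numeric(nrow(adj))
  for (s in cl) scores[s] <- scores[s] + factorial(length(s) - 1)
  scores
}

## direct combinatorial hypergeometric upper tail
hyperTailOracle <- function(k, K, n, N) {
  js <- seq.int(max(k, K + n - N), min(K, n))
  if (length(js) == 0 || js[1] > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## adjusted Rand index of two hard partitions
ari <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## paper-design age vector: 7,9,8,9,7,5 replicates at 3..26 months
paperAges <- function() rep(c(3, 5, 8, 14, 20, 26), c(7, 9, 8, 9, 7, 5))
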
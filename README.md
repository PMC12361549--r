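# proteoTraj

Multi-organ aging proteomics in R: from peptide-level quantification
exports to differentially expressed proteins (DEPs), age-trajectory
clusters, cross-organ overlap statistics, mixed-model divergence calls,
network hubs and targeted-MS validation — with a synthetic-study generator
so that every stage is testable against known ground truth.

## The problem and the approach

Cross-sectional aging studies profile organs from animals of different
ages (here: eight mouse organs at 3, 5, 8, 14, 20 and 26 months, with
7/9/8/9/7/5 biological replicates) and ask which proteins change with age,
when, and whether organs age together or apart. The pipeline implements:

- **Peptide QC** — Proteome Discoverer-style exports are filtered on master
  accession, quantification flags (`NoQuanValues`, `NoneMonoisotopic`),
  single protein group, unambiguous PSMs, and PEP and q-value ≤ 0.05.
- **Summarization** — log2 + per-sample median centering, then a robust
  additive two-way model per protein, `y_ps = β_s + α_p + ε`, fitted by
  IRLS with Huber weights; the sample effects `β_s` are the protein
  abundances. Remaining missing values are imputed by iterative
  random-forest regression (missForest-style stopping rule) or k-nearest
  rows.
- **Moderated F-test** — per protein, a one-way model over age groups with
  empirical-Bayes variance shrinkage: residual variances get a scaled
  inverse-χ² prior with hyperparameters (d₀, s₀²) estimated by method of
  moments on log s²_g; the statistic refers the between-group mean square
  to the posterior variance s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g) on
  (K−1, d₀+d_g) degrees of freedom, with Benjamini–Hochberg control.
  Companions: pairwise moderated t (20 vs 3 months), classical F, and a
  continuous-age linear trend test with its R².
- **Trajectory clustering** — DEP profiles are z-scored, averaged per age
  group, and clustered by fuzzy c-means with the fuzzifier m estimated
  from (N, D); cluster number 2–4 chosen by partition coefficient /
  entropy; the most-enriched cluster is the one with high mean and low SD
  membership; the PC1 loading over ages summarizes the dominant shared
  trajectory.
- **Cross-organ overlap** — UpSet-style exclusive intersections,
  upper-tail hypergeometric overlap tests (three-way by convolution),
  blood-proteome subtraction, Spearman trajectory correlation with exact
  permutation p-values.
- **Divergence** — `Expression ~ Age * Tissue + (1 | Mouse)` fitted by
  maximum likelihood with a profiled random intercept, likelihood-ratio
  test on T−1 df, per-tissue OLS trends, and an Up/Down/NoChange
  directionality matrix with consistent / divergent / tissue-specific
  categories.
- **Network hubs** — STRING edge lists, maximal cliques, Maximal Clique
  Centrality `MCC(v) = Σ_{C∋v} (|C|−1)!`, top-k hub sets.
- **Targeted MS** — internal-standard (SureQuant-style) reports: peptides
  quantifiable when ≥5 of 6 heavy-channel ions have nonzero AUC; the L/H
  ratio sums the top-3 heavy-ranked fragments; age groups are tested
  against the 3-month reference by one-sided t-tests.

## Worked example

```r
library(proteoTraj)
library(SummarizedExperiment)

cfg   <- syntheticConfig(organs = c("kidney", "spleen"),
                         nProteins = 300, seed = 42)
study <- simulateStudy(cfg)
meta  <- subset(study$metadata, organ == "kidney")
dir   <- tempfile(); writeStudy(study, dir)

records  <- readPeptideTable(file.path(dir, "peptides_kidney.tsv"), meta)
qc       <- filterPeptides(records)
se       <- buildIntensityMatrix(qc$records, meta)
proteins <- summarizeProteins(logAndCenter(se))
mat      <- assay(imputeMissing(proteins, method = "knn")$matrix, "imputed")

de   <- runDiffexp(mat, meta$age_months)
de$prior
#> EBPrior: d0 = 16.99987, s0^2 = 0.02595
deps <- classifyDEPs(de$table)$sets$moderatedF
```

The run prints `peptides: 1206 -> 1182 after QC`, then finds 203 DEPs at
BH 0.05 among 300 proteins, recovering all 145 planted age-responsive
proteins (`study$truth$ageResponsive$kidney`). The 58 extra calls trace to
a real caveat the package deliberately exposes: per-sample median
centering assumes directionally balanced regulation, and this organ's
planted DEP mass — like the real kidney's — is strongly down-dominated in
late life, which imprints a small opposite trajectory on null proteins
(see the methods vignette for the analysis and a balanced design).

```r
X   <- zscoreProfiles(mat, meta$age_months, deps)
sel <- selectClusterCount(X, 2:4, seed = 1)
sel$table
#>   c        pc        pe normalized_pc
#> 1 2 0.8520900 0.2646120     0.7041800
#> 2 3 0.8000119 0.3957255     0.7000179
#> 3 4 0.7719999 0.4684102     0.6959999
p1 <- pc1Trajectory(X)
round(p1$scores, 2)
#>     3     5     8    14    20    26
#> -0.15 -0.27 -0.42 -0.04  0.79  0.32
```

Two clusters win narrowly on the normalized partition coefficient; PC1
explains 74% of the between-age variance and swings hardest between 14
and 20 months — the generator's planted late-life dynamics.

A command-line wrapper is installed with the package
(`inst/scripts/proteotraj`): `proteotraj simulate --out dir --seed 7` and
`proteotraj run --config cfg.yaml --out dir` drive the same functions.

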
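---
title: "Methods: multi-organ aging proteomics with proteoTraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-organ aging proteomics with proteoTraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

proteoTraj analyzes cross-sectional, label-free proteomics of aging
across organs: eight mouse organs sampled at six ages (3, 5, 8, 14, 20,
26 months) from the same animals, with 7, 9, 8, 9, 7 and 5 biological
replicates per age group (45 samples per organ). This vignette explains
each stage's model and assumptions, the tunable parameters, the synthetic
data the tests run on, and the choices made where the design was open.

## Peptide QC

Peptide records survive iff they carry a master protein accession, no
disqualifying quantification flag (`NoQuanValues`, `NoneMonoisotopic`),
exactly one protein group, an unambiguous PSM call, and posterior error
probability and q-value both ≤ 0.05. Three deliberate choices:

* thresholds are **inclusive** (a PEP of exactly 0.05 is kept), matching
  the "≤ 0.05" convention;
* label matching is case-insensitive because export dialects vary;
* missing PEP or q-values **fail** their filter (conservative), counted
  separately in the QC report.

The filters are applied to whatever rows the table carries (peptide
groups in the bundled generator); the QC report records input, per-rule
removal counts (a record may trip several rules), and survivors, so the
union arithmetic is auditable.

## Normalization and summarization

Intensities are log2-transformed and median-centered per sample, organs
processed as separate datasets. Log base 2 is the proteomics convention
(fold changes in doublings). Centering on the log scale versus the raw
scale differ only through the even-count median; the log-scale order is
the default and the raw order is available via `logAndCenter(center =)`
composition.

**Median centering assumes a directionally balanced (mostly stable)
proteome.** This matters and is easy to forget: if a large fraction of
proteins moves the same way at some age, the sample median absorbs part
of that shift and every *null* protein inherits the opposite trajectory.
With the generator's kidney-like settings (38% DEPs, amplitude 1.5 log2,
down-dominated late-life shapes) the imprinted ghost trajectory reaches
about ±0.1 log2 — enough to push null proteins past a moderated F at the
study's power. This is a property of the normalization, not a bug in the
implementation; the balanced `midlife_peak`/`midlife_dip` design is
provided for evaluations that need a clean null, and the default
(realistically unbalanced) design documents the caveat.

Peptides are aggregated per protein by the additive model
`y_ps = β_s + α_p + ε` over observed cells, fitted by iteratively
reweighted least squares with Huber weights (tuning constant 1.345 for
95% Gaussian efficiency; max 20 iterations; coefficient tolerance 1e-6)
and a sum-to-zero constraint on the peptide effects. The sample effects
`β_s` are the protein profile; samples with no observed peptide stay
missing. With the tuning constant at infinity the fit is exactly ordinary
least squares (tested against `lm()`), and the fit is equivariant to
per-sample shifts.

Remaining missing values are imputed by iterative random-forest
regression: initialize missing cells with row means, regress each
protein-with-missing on all other proteins across samples (100 trees),
and stop at the first increase of the normalized change in imputed values
(returning the previous iterate) or after `maxIter`. Proteins observed in
fewer than 50% of samples are dropped, not imputed — the run report logs
them. A k-nearest-row imputer (k = 6) is the fast alternative used by the
default pipeline configuration; both are deterministic under the seed and
never alter observed cells.

## Differential expression

Per protein, a one-way group-means model over the age groups gives group
means, a pooled residual variance `s²_g` and its degrees of freedom
`d_g = n_g − K_g` (observed samples minus groups present). The
empirical-Bayes prior on variances is scaled inverse-χ² with
hyperparameters estimated by method of moments on `z_g = log s²_g`: with
`e_g = z_g − ψ(d_g/2) + log(d_g/2)`, solve
`ψ′(d₀/2) = mean[(e_g − ē)² · G/(G−1) − ψ′(d_g/2)]` by Newton on the
trigamma inverse and set `s₀² = exp(ē + ψ(d₀/2) − log(d₀/2))`; a
nonpositive moment forces `d₀ = ∞`, `s₀² = exp(ē)`. The moderated F
refers the between-group mean square to the posterior variance on
`(K−1, d₀+d_g)` df. At `d₀ = 0` it equals the classical one-way F to
machine precision; at `d₀ = ∞` every protein is tested against `s₀²`; in
between the posterior variance always lies between `s²_g` and `s₀²`.

Companions computed on the same matrix: the pairwise moderated t for
20 vs 3 months (its square equals the two-group moderated F), the
classical F, and a continuous-age OLS trend test returning slope
(log2/month), p and R². "R²" here is the plain OLS coefficient of
determination of the age-only model — the trend test is ordinary least
squares, so no mixed-model variance partitioning is involved. BH
adjustment is applied per organ and per method; the DEP call is strict
(`q < 0.05`, a tie at 0.05 is not a DEP). Proteins whose within-group
replication collapses (`d_g = 0`) are excluded from prior estimation but
still shrunk by the fitted prior.

Why a moderated F rather than endpoint contrasts: trajectories that rise
and return between the endpoints (the `midlife_peak` template is back at
baseline by 20 months) are invisible to a 20-vs-3 comparison but plainly
visible to the across-groups F. The acceptance checks exercise exactly
this contrast.

## Trajectory clustering

DEP profiles are z-scored per protein across all samples and the z-scores
averaged within each age group (z-then-average; on balanced designs this
matches average-then-z up to scale). Fuzzy c-means with Euclidean
distance clusters the profiles; the fuzzifier is estimated from the data
dimensions as
`m = 1 + (1418/N + 22.05)·D⁻² + (12.33/N + 0.243)·D^(−0.0406·ln N − 0.1134)`.
Configuration: tolerance 1e-6 on the center shift, max 300 iterations, 10
seeded restarts with random-protein initialization, exact center
coincidences assigned crisply, membership computed with row-minimum
normalization so small fuzzifiers cannot underflow. The objective is
asserted nonincreasing every iteration.

The cluster count 2–4 is chosen by the **normalized partition
coefficient** `(PC − 1/c)/(1 − 1/c)` (ties: smaller partition entropy,
then smaller c), with the full PC/PE table emitted so users can override
per organ; a winning normalized PC below 0.1 flags the selection as
low-confidence. The published analyses state only that PC and PE guided
the choice, so this rule is this package's formalization, not a claim
about the original procedure. The most-enriched cluster maximizes mean
membership of its hard-assigned members (ties: smaller SD). The PC1
trajectory is the first principal loading of the protein × age matrix
(ages as variables, column-centered), sign-fixed to correlate positively
with the mean profile, with its variance fraction reported.

## Cross-organ overlap

Exclusive (UpSet-style) intersections partition the union, so their
counts always sum to the union size. Overlap significance is the exact
upper hypergeometric tail; the background N for a pair defaults to the
intersection of the two organs' quantified universes (configurable to the
global union — the original background is unstated, so these
probabilities are design-dependent). The three-way tail conditions on the
intermediate overlap: `P(T ≥ k) = Σ_j P(|A∩B| = j)·P(Hyp(N, j, K₃) ≥ k)`.
Blood-associated proteins are removed by set difference against a
provided accession list, with before/after counts. Spearman trajectory
correlations on ≤6 ages use the exact permutation null (all 720
orderings); longer profiles use the asymptotic t approximation.

## Mixed-model divergence

`Expression ~ Age * Tissue + (1 | Mouse)`, age continuous, fitted by
**maximum likelihood** (not REML — the likelihood ratio compares
fixed-effect structures) for the full and no-interaction models; the LRT
is referred to χ² on T−1 df (one interaction slope per non-reference
tissue). The random intercept enters through the marginal covariance
`σ²(I + λZZᵀ)`, λ = τ²/σ², and is profiled out: each mouse block of
`(I + λJ)` inverts in closed form, so for fixed λ the GLS estimates and
profiled σ² are exact and a one-dimensional search over λ ≥ 0 (boundary
checked explicitly) completes the fit. The fit matches `lme4::lmer`
(REML = FALSE) to numerical precision in the tests, and with degenerate
grouping (one row per mouse) the LRT equals the OLS statistic exactly.

Per-tissue trends on the LRT-significant proteins (BH q < 0.05) use raw
OLS p < 0.05 for direction calls — the published methods specify BH only
for the LRT, so the per-tissue rule is a documented, configurable choice.
Directionality categories: consistent-up/down (≥2 tissues in the same
nonzero direction, none opposite), divergent (≥1 Up and ≥1 Down, with the
opposing pairs listed), tissue-specific (exactly one non-NoChange entry).

## Network hubs

STRING-format edge lists load at a default combined-score threshold of
400 (medium confidence; the original threshold is unstated and the value
is configurable). Maximal cliques come from Bron–Kerbosch with pivoting;
enumeration is exponential in the worst case, so a node cap guards the
call with a clear error. `MCC(v) = Σ_{C∋v}(|C|−1)!` with `0! = 1` for
isolated nodes. Factorials are exact in double precision up to clique
size 23 and error out beyond rather than overflow silently — far above
any clique size these analyses encounter. Top-k ties at the boundary
break by degree, then lexicographic accession, flagged.

## Targeted-MS quantitation

A peptide is quantifiable in a sample when its heavy (internal-standard)
channel has nonzero AUC for at least five of six monitored product ions;
peptides monitored with a different ion count are held to "at most one
missing ion" with a warning. The L/H ratio sums the three most intense
fragments; **ranking uses the heavy channel** by default because the
internal standard is spiked at a fixed amount and immune to biology (the
published description does not name the ranking channel; light and
sum-ranking are offered). Ratios are compared on the natural scale (a
log option exists) by unpaired one-sided t-tests against the 3-month
reference, with the direction taken from the observed mean difference and
recorded; a fixed-direction one-sided p is also reported.

## The synthetic-study generator

The generator is the package's test bed and emulates: the replicate
structure above; log2-scale intensities (protein baseline ~N(20, 1.5²),
peptide ionization offsets ~N(0, 1), residual SD 0.3); planted DEP
trajectories from a template library (late decline with recovery, early
decline, late rise-fall, and a balanced mid-life peak/dip pair), cycled
over a per-organ DEP fraction defaulting to the observed per-organ
gradient (kidney 0.383 … brain 0.001); a per-mouse random intercept
(SD 0.25 log2) shared across organs, matching the matched-sampling
`(1|Mouse)` structure; blood-associated proteins (10%) carrying one
identical age component in every organ (signs alternating across blood
proteins so the contamination mass is balanced); MCAR missingness (2%)
plus optional intensity-dependent dropout
`P(missing) = strength · logistic(−(x − q10)/scale)`, the dominant
proteomics missingness mode; and a 2% rate of rows deliberately violating
each QC rule. The observed missingness rate of the original data is
unpublished, so the missingness defaults are free, documented parameters.

What it does **not** emulate: raw spectra and chromatography, database
search errors, peptide-level interference, organ-specific proteome
composition, or heterogeneous DEP effect sizes (all planted DEPs share
one amplitude, default 1.5 log2). Passing tests therefore demonstrate
statistical correctness and recovery under idealized, known-truth
conditions — not performance on real data.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale versions of the study:
universes of 60–300 proteins, one or two organs, 2000-protein null
matrices for calibration, 1000 mixed-model null fits, 200-protein power
simulations, 200 random graphs (≤8 nodes) for the clique oracle, and the
exact hypergeometric grid up to N = 60. Seeds fan out from a single run
seed through a fixed counter scheme, so every stage is reproducible in
isolation; two pipeline runs with the same configuration produce
byte-identical outputs (checksummed in the manifest).

Known limitations: median centering under heavy unbalanced regulation
(discussed above); the moderated F assumes exchangeable variances across
proteins within an organ; fuzzy c-means is restart-dependent on weakly
separated data (10 restarts default); the profiled LMM supports a single
random intercept (no random slopes); hypergeometric backgrounds are
design choices; clique enumeration is exponential and guarded rather
than approximated.
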
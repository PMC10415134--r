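---
title: "Methods: cross-species expression-lifespan association and concordance"
author: "lifecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species expression-lifespan association and concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecon)
```

# The problem

Across mammals, maximum lifespan (MLS) varies by two orders of magnitude.
Given a compendium of expression values (SVA-corrected log2 TPM) for
orthologous genes across tens of species, the questions this package
answers are:

1. which genes' expression levels track log2(MLS) across species,
   accounting for the fact that species are not independent observations
   but leaves of a phylogeny;
2. whether the resulting *signed* gene set (genes up / down with longer
   lifespan) resembles other signed sets — age-regulated genes, genes
   tracking lifespan variation within a species — more than chance;
3. which promoter motifs' occurrence in the trait-associated genes
   co-evolved with lifespan.

All statistics are computable on synthetic data generated by the package
itself, so every claim the test suite makes is reproducible without any
external download.

# Trait-expression association

## Spearman rank correlation

For each gene, expression is paired with log2(MLS) over the species with
data (genes observed in fewer than 10 species are removed first; the
survivors define the *investigated genes*, which serve as the background
universe for every downstream overlap and enrichment test). Ties receive
average ranks. Two-sided p-values are exact — full enumeration of the n!
rank permutations — for n <= 7 and use the t approximation with n-2
degrees of freedom otherwise; at the package's operating sizes (10-29
species) the t approximation is the one that matters, and the exact branch
guards the small-n edge.

## PGLS over a tree ensemble

Phylogenetic generalized least squares models the error covariance of the
cross-species regression as Brownian motion on the tree: cov(i, j) is the
branch length shared by species i and j from the root to their most recent
common ancestor (`phyloCovariance()`). The fit is the closed form

$$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y,$$

with an intercept column, residual variance estimated from the generalized
residual sum of squares on n-2 degrees of freedom, and a two-sided t test
on the slope. No Pagel's lambda or Ornstein-Uhlenbeck transform is
estimated: the covariance is fixed by the tree, which makes the closed form
exactly equivalent to maximum likelihood for the regression coefficients
and avoids a variance-component search. The test suite checks the fit
against two independent routes: ordinary least squares on star phylogenies
(identity covariance) and Cholesky-whitened OLS on random trees, both to
1e-8, plus `nlme::gls` with a Brownian correlation structure.

Phylogenies are uncertain, so the association test runs once per tree of
an ensemble and uses the **maximum** p-value across trees — the least
favourable plausible phylogeny decides significance. The reported slope is
taken from that same least-favourable fit, since it is the fit the call is
based on. If slope signs disagree across trees the gene is flagged, and
flagged genes are excluded when signed sets are called: a direction that
depends on the tree is not a direction. Because the Brownian covariance of
a species subset equals the corresponding submatrix of the full-tree
covariance (pruning sums the branches of collapsed degree-2 nodes), the
ensemble fit subsets one precomputed covariance per tree instead of
re-pruning per gene.

## Two-stage FDR (Benjamini-Krieger-Yekutieli)

Per method, p-values are adjusted by the two-stage adaptive step-up
procedure: stage 1 is Benjamini-Hochberg at q' = q/(1+q); its rejection
count r1 estimates the number of true nulls as m0 = m - r1; stage 2 reruns
BH at q' m/m0. Adjusted q-values are defined so that thresholding them at
q reproduces the stage-2 rejection set exactly. Genes are called at
q-value strictly below the level (default 0.10). On all-null data the
empirical FDR stays at the nominal level; when at least ~q/(1+q) of the
tests carry strong signal, the adaptive second stage can only widen the BH
rejection set — both properties are exercised in the acceptance suite.

Calls from the two methods are merged by union; a gene called with
opposite signs by the two methods is contradictory and is dropped with a
warning (the same rule the readers apply to a gene reported with both
signs by different probes in an input signed set).

# Signed-set concordance

Two signed gene sets A (query, e.g. MLS-associated genes) and B (e.g.
age-regulated genes) are first restricted to a shared universe of N
investigated genes. *Concordant* genes carry the same sign in both sets,
*discordant* genes opposite signs. Under independence the expected counts
are sums over sign strata, e.g. E[concordant] = |A+||B+|/N + |A-||B-|/N.
Two statistics summarize the comparison:

* the odds ratio of observed versus expected membership,
  OR = [O/(nA-O)] / [E/(nA-E)] with nA = |A|, pooled over strata, for the
  concordant and the discordant direction separately (undefined ratios —
  zero denominators — are reported as such, never silently patched);
* a two-sided exact binomial test of O successes in nA trials at null
  success probability E/nA, using the small-p-sum convention (all outcomes
  no more likely than the observed one). The trials are the members of the
  query set because the query is the smaller, fixed set in every
  comparison; the universe is the intersection of the two studies'
  backgrounds, since a gene untestable in either study carries no overlap
  information.

Across a battery of comparisons the binomial p-values receive the same
two-stage FDR adjustment. Note the asymmetry: swapping A and B leaves the
discordant count unchanged but not the odds ratios, which condition on A.

The binomial null treats B's stratum frequencies as fixed success
probabilities; the true sampling is closer to hypergeometric, so the test
is slightly conservative (rejection rate ~0.04-0.05 at alpha = 0.05 on
independent random sets, and the p-value distribution is super-uniform).
This is the analytic null; no resampling null is provided.

Two auxiliary comparisons operate at the coefficient level rather than
the set level: a Welch (unequal-variance, unpaired) two-tailed t test
between a gene's per-tissue correlation coefficients in two species
panels — unpaired because nothing guarantees tissue-by-tissue pairing —
and a one-sample Wilcoxon signed-rank test of a coefficient distribution
against zero (exact null for n <= 25 after dropping zeros, corrected
normal approximation above).

# Fisher-exact enrichment

Query sets are tested against annotation libraries (GMT format) with the
two-sided Fisher exact test on the 2x2 table over the investigated-gene
background, reporting the sample odds ratio ad/bc (optionally
Haldane-corrected for display when a cell is zero — p-values are never
corrected). The background matters: enrichment against the genes that
*could* have been called is a different question from enrichment against
the genome, and the tests document this sensitivity explicitly.

# Promoter motif scanning and co-evolution

## Scanner

JASPAR-style count matrices become probability matrices after a 0.01
pseudocount per cell (below the resolution of curated counts, enough to
avoid -Inf log-odds), and are scored as log2 odds against a zero-order
background. Every window of the promoter is scored on both strands (the
reverse strand via the reverse-complemented matrix, so coordinates stay on
the forward strand); windows containing a non-ACGT code are skipped;
overlapping hits all count. A window is a hit when the null probability of
its score — the probability that a random background window scores at
least as high — falls below the threshold (default 1e-4).

The null distribution is computed by dynamic programming over the motif
columns. For widths up to 10 the convolution runs on exact score values
(distinct sums merged at 1e-9), so tail probabilities agree with
exhaustive enumeration of all 4^w windows to 1e-9 — this is the regime
the test battery verifies. Wider motifs fall back to an integer grid with
a configurable number of bins per column (default 1000), the standard
large-scale-scanner approximation; its error decreases with granularity
and is tested against the exact path at width 12. The inner scoring loop
is compiled (Rcpp), with threshold filtering done in the same pass, which
is what makes the 100-replicate recovery studies affordable.

The scanning background defaults to the base composition of the input
promoter set (a flag switches to uniform); the motif's log-odds are
rebuilt against that background before scanning.

## Trend test

For each motif and species, two statistics compare a trait-associated
gene set against the background genes: the fraction of promoters with at
least one hit (compared as a true odds ratio) and the mean number of hits
per promoter (compared as a plain ratio of means — an odds transform of an
unbounded mean is undefined). Species where a presence ratio is exactly 0
or 1 have undefined odds and are dropped for that metric; a motif needs at
least 5 usable species. Each per-species metric vector is tested for
Spearman correlation with MLS; q-values are computed across all (motif,
metric) pairs, and a motif is called trait-associated only when *both*
metrics are significant at the FDR level (default 0.05) with a consistent
trend direction.

# The synthetic-data generator

The generator produces data with exactly the structure the analysis
assumes, which makes it a positive control, not a realism claim:

* **Tree**: a pure-birth tree rescaled to unit height, 29 species by
  default (the scale of a cross-mammal expression compendium).
* **Trait**: Brownian motion on the tree with rate SD 1 per unit height,
  simulated directly on the log2 scale with root log2(25) years (a
  mid-sized mammal); exported MLS is 2^trait, spanning roughly 5-150
  years.
* **Expression**: 2000 genes, 200 planted with slope ±1 log2-expression
  per doubling of MLS, plus a gene-specific Brownian noise component
  (SD 0.12) and i.i.d. noise (SD 0.46). These two SDs were set together
  so that (i) planted genes have expected |Spearman rho| of about 0.8
  against the trait and (ii) the rank-correlation branch retains
  approximate FDR control (observed FDR ~0.15 at q = 0.10). The second
  condition is the interesting one: tree-correlated noise makes ranked
  cross-species correlations anti-conservative — precisely the
  non-independence PGLS corrects (its branch shows observed FDR ~0 on the
  same data) — and with a larger phylogenetic share (e.g. SD 0.2) the
  rank branch's observed FDR rises well past its nominal level.
  Missingness is independent per cell at rate 0.1, redrawn per gene so at
  least 10 species remain observed; the real compendium's missingness is
  blocky (tissue availability), which the generator does not emulate.
* **Partner sets**: a signed set with a target concordance odds ratio
  against an anchor set is drawn by weighted sampling: sign-matched
  anchor pairs carry weight equal to the target, everything else weight 1.
  A target of 1 reduces to uniform sampling; infinity gives a sign-matched
  subset of the anchor. The estimator's median recovers the target within
  a few percent when the sets are small relative to the universe; the
  recovery check uses 500-gene sets in a 5000-gene universe so the
  expected concordant count (~25) is large enough that the integer
  granularity of the observed count does not dominate the median.
* **Promoters**: i.i.d. background sequence, 1000 bp. A "gain" trend
  plants exact consensus copies of a motif with a per-species *total*
  that rises linearly with MLS rank (0 up to a mean of 3 copies per
  promoter), distributed randomly over the gene set's promoters so both
  the mean count and the presence fraction carry the trend. The planted
  consensus is a permutation of a base-balanced multiset, so insertions
  cannot shift promoter composition along the lifespan gradient and
  thereby fake (or mask) trends for unrelated motifs. One residual
  artifact is documented: replacing background sequence with any fixed
  consensus slightly *reduces* other motifs' expected hit counts in the
  planted set ("site turnover"); with a single decoy motif in a 4-test
  family this, combined with the adaptive FDR's leniency in tiny
  families, produces decoy call rates near 10%. The recovery study
  therefore scans a panel of one planted plus nine decoy motifs —
  a desk-scale stand-in for a full vertebrate motif library, where the
  FDR family is large — and the per-decoy false-call rate drops below
  1%.

All generators are pure functions of their seed: identical seeds give
byte-identical outputs.

# Pipeline

`runPipeline()` executes simulate → associate → concord → enrich →
coevolve from one YAML config (unknown keys or impossible stage
combinations fail before any computation; missing input files fail naming
the stage). Per-stage seeds derive from the master seed by a fixed
documented rule, so a stage can be re-run in isolation; every output TSV
carries a comment header with the tool version and the parameters used,
and `manifest.yaml` records the config snapshot, seeds, output files and
row counts. Re-running an identical config reproduces byte-identical
TSVs.

```{r pipeline-example, eval = FALSE}
man <- runPipeline(list(
  seed = 7, out_dir = "demo_run",
  stages = c("simulate", "associate", "concord"),
  simulate = list(n_genes = 500, n_planted = 50, partner_size = 100)))
```

# Problem sizes used in the checks

The test and acceptance batteries run at: 29 species / 2000 genes / 200
planted / 10-tree ensembles for end-to-end recovery (20 pipeline runs in
the test suite, 10 in the acceptance script); 500 replicates of m = 1000
p-values for FDR calibration; 2000 replicates in a 5000-gene universe for
binomial calibration; 200 replicates for odds-ratio recovery; 100 (test
suite) or 40 (acceptance script) seeded studies of 20 species for motif
recovery. These sizes give Monte-Carlo margins comfortably inside the
asserted bands while keeping a full run of the suite under ten minutes on
one CPU.

# What passing tests do and do not show

The generator matches the analysis assumptions by construction: linear
trait effects, Gaussian noise, Brownian phylogenetic structure,
independent missingness, zero-order promoter background. Passing recovery
tests therefore demonstrates correctness of the implementation and
internal calibration of the statistics — not robustness to the ways real
compendia violate these assumptions (batch structure surviving SVA,
block missingness, non-Brownian trait evolution, promoter composition
heterogeneity, ortholog mis-mapping). The package deliberately leaves
normalization, batch correction and ortholog mapping out of scope: its
input contract starts at a corrected expression matrix.

# Known limitations

* The Brownian covariance is fixed by the tree; no lambda/OU estimation.
* The ensemble slope is reported from the max-p tree only; a
  slope-averaging alternative would need its own inference.
* The scanner's grid path (widths > 10) is an approximation controlled by
  `granularity`; only the exact path carries the 1e-9 guarantee.
* The concordance odds ratio conditions on the query set; it is not a
  symmetric similarity measure, and comparisons across figures with very
  different query sizes should read the binomial q-values, not the bar
  heights.
* One-comparison FDR batteries (a single concordance row) make the
  q-value equal the p-value; adjustment only matters across panels.
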
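---
title: "Methods: models, defaults and design choices in stresshub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in stresshub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stresshub` nominates hub stress-responsive transcription factors by a
strict conjunction of three filters — network centrality, trait
association, and population-genetic signature. This vignette is the
package's own account of the underlying models, the tunable parameters
and their defaults, the synthetic-data generator that makes everything
testable, and the places where the design was genuinely open and a choice
had to be made.

## 1. Differential expression

The pipeline consumes only a DEG *set*, so the DE stage is a deliberately
simple, transparent test rather than a full count model: per gene, the
log2 fold change is the difference of group means of `log2(TPM + 1)`
(pseudocount configurable), the p-value a two-sided Welch t-test on the
same values, and the multiple-testing correction Benjamini–Hochberg over
all tested genes. A gene is a DEG when |log2FC| > 1 (twofold) **and**
adjusted p < 0.05 — the same decision rule a negative-binomial Wald test
would feed, and the planted-truth tests verify recovery under it
directly. Genes with zero variance in both groups carry no evidence and
get p = 1 (they remain in the adjustment so the number of tests is
stable). DEGs are pooled across stress contrasts by union: a gene
qualifying in any stress-vs-control contrast enters the clustering. The
union rule is a declared choice; an intersection rule would shrink the
DEG set to genes responsive to every stress, which is not what a
stress-response funnel wants.

TPM is computed exactly as
`1e6 * (counts[g,s]/len[g]) / sum_g'(counts[g',s]/len[g'])`; an all-zero
sample column is an error rather than a silent NaN.

## 2. Independent-component clustering

The DEG submatrix — gene-wise Z-transformed `log2(TPM + 1)` — is
decomposed by FastICA: genes are observations of a sample-dimensional
signal; the sample covariance is whitened by eigendecomposition; the
symmetric fixed-point iteration with the logcosh contrast (alpha = 1)
extracts `K` maximally non-Gaussian directions, with up to 5 random
orthogonal restarts and a deflation fallback before giving up with
diagnostics. Numerical canonicalization makes runs reproducible and
comparable: components are ordered by explained variance, signs fixed so
each component's largest-|loading| gene is positive, and loading columns
scaled to unit norm (the compensating scale lives in the sources, so
`loadings %*% sources` still reconstructs the whitened projection).

Two conventions deserve a note:

* **Log scale.** "Z-transformed TPM" is implemented as Z of
  `log2(TPM + 1)`. Expression programs act multiplicatively; Z of raw TPM
  lets a handful of high-mean samples dominate each gene's profile and
  empirically destroys source recovery, while the log-scale Z preserves
  the linear mixing structure that ICA assumes.
* **Row standardization is the caller's contract.** `fastica_decompose()`
  centers columns but does not re-standardize rows: re-scaling each
  observation by its own norm distorts heavy-tailed sources and breaks
  identifiability on exactly the data ICA is best at.

`K` defaults to 9 — a typical cluster count for stress DEG collections —
and is a plain knob; the package does no automatic model selection
because none is well-defined at the DEG-set sizes involved (the pipeline
caps `K` at the feasible rank).

**Cluster assignment** is a declared rule, not an inference: gene → argmax
|loading|, accepted only if that |loading|, standardized within its
column, exceeds `z_cut` (default 2); ties take the lowest component
index; everything else stays unassigned. The threshold trades coverage
for purity — at `z_cut = 2` roughly the top few percent of each
component's loading distribution is kept, which is the regime in which
the per-cluster networks are informative.

## 3. Tree-ensemble network inference and hub ranking

For every target gene in a cluster, a random-forest regression of its
Z-expression on the transcription-factor panel (minus itself — no
self-edges) attributes to each regulator its share of the forest's total
impurity reduction, normalized per target to sum to one. Defaults follow
the original tree-ensemble network procedure: 1000 trees,
`mtry = ceiling(sqrt(R))`. Forests run single-threaded with per-target
child seeds derived from the sorted target names, so results are
reproducible and independent of input order; the regulator list is sorted
internally for the same reason.

Degree is meaningless on the complete weighted graph, so an edge-retention
rule is mandatory: the default keeps each target's top-5 regulators by
importance (`top_e = 5`, or an absolute importance threshold). A
regulator's degree is its count of retained out-edges pooled across
clusters (per-cluster degrees are attached as an attribute — the pooled
number is what the hub rank uses, and the per-cluster table lets either
reading be audited). Ties break by total retained importance, then
lexical id. The pipeline retains as "hubs" the regulators ranked in the
top `hub_top_n` (default 5).

## 4. Mixed-model association and LD

The association model is
`y = Xb + g beta + u + e`, `u ~ N(0, sigma_g^2 K)`,
`e ~ N(0, sigma_e^2 I)`, with `K` the VanRaden kinship
(`K = W'W / (2 sum p(1-p))` on per-variant mean-imputed, 2p-centered
dosages). The null model is fitted once per trait by spectral REML: one
eigendecomposition of `S K S` reduces the restricted likelihood to a 1-D
profile in `delta = sigma_e^2 / sigma_g^2`, maximized over
`log(delta) ∈ [-10, 10]` (optimize + endpoint check). Each variant is
then tested by generalized least squares **at the null delta** — the
fixed-ratio EMMAX / "P3D" approximation that standard MLM software
defaults to — by rotating phenotype, covariates and genotype into the
eigenbasis of `K`, whitening by `(lambda_i + delta)^{-1/2}`, and an
F-test with `(1, n - p - 1)` degrees of freedom. An `exact = TRUE` flag
re-estimates the ratio per variant for cross-checks; the test suite also
pins the spectral path to a naive matrix-inversion GLS oracle and to the
OLS reduction at `K = I`.

Decisions worth recording: the candidate region is gene body plus
3000 bp of promoter (the conventional promoter extent for these
analyses, exposed as `promoter_bp`); missing dosages are mean-imputed for
both kinship and scan; the MAF filter defaults to 0.05; any zero-variance
dosage row (monomorphic, or degenerate all-heterozygous) is reported with
p = 1 and never flagged; the significance threshold is p < 1e-4.
Coordinates are 1-based inclusive at every user surface (VCF convention).

Heritability under a weakly informative kinship is intrinsically
hard: with `K` estimated from ~2000 independent variants on a
three-group panel, per-replicate REML `h2` estimates scatter widely
(sd ≈ 0.2 at n = 300), and their mean sits a few hundredths below the
generating value. The acceptance checks therefore test the *mean* over
200 replicates, which lands within ±0.05 of the planted `h2 = 0.5`.

LD is composite LD on unphased genotypes: squared Pearson correlation of
dosage vectors, missing pairs dropped pairwise, `NA` for monomorphic
variants. Under independence `E[R^2] ≈ 1/(n-1)`, which the tests verify.

## 5. Diversity, sweep and precipitation filters

Per polymorphic site, `pi_site = (n/(n-1)) 2p(1-p)` with `n` the number
of non-missing alleles — algebraically identical to the mean pairwise
difference, which the tests enforce exactly by explicit allele-pair
enumeration. The window value divides the site sum by the window length
(200 bp default), the convention of windowed-pi VCF tools; the
per-variant-site average is reported alongside since both normalizations
are in circulation.

The sweep call is per cultivated group:
`pi_cult / pi_wild < ratio_cutoff` (default 0.5) in at least
`frac_windows` (default 0.5) of the *informative* windows (wild pi > 0;
windows where the wild group is invariant carry no contrast and are
excluded; no informative windows → indeterminate `NA`). The cutoffs are
package defaults for a qualitative "cultivated diversity collapsed"
judgment; both are exposed. The rule is monotone — depressing cultivated
diversity can never unflag a region.

"Precipitation-related geographic distribution" is operationalized as a
two-sided Welch test of accession mean precipitation between the two
allele classes of the focal variant (the region's best-associated
variant; carriers vs non-carriers), plus the point-biserial correlation,
flagged at p < 0.01. This is the one filter the source workflow describes
only qualitatively, so the test, threshold and flag are all explicit
configuration.

## 6. The synthetic-data generator

The generator exists to make every stage falsifiable: each planted
structure has a downstream operation whose test must recover it.

* **Expression.** Baselines `log2 mu ~ N(5, 1.5)`; each planted hub
  carries a per-sample activity = stress shift (`de_log2fc`, default 3)
  plus Laplace noise (`hub_program_sd`); each of its targets tracks that
  activity through a slope drawn from ±U(0.75, 1.25); background
  stress-responsive genes (default 100) shift under random stress subsets
  with magnitude ±`de_log2fc`·U(0.5, 1) — they dilute the hub programs
  the way unrelated regulons do in real data. Counts are
  negative-binomial (dispersion 0.05) around length-weighted means at
  ~2M reads per library, so the DE stage sees overdispersed data.
  Each hub's program is tied to a single stress (cycling), keeping
  programs condition-separable.
* **Choice of `hub_program_sd` (default 0.4).** The Laplace activity is
  the super-Gaussian source the clustering assumes. Strengthening it
  (e.g. 1.0) makes modules cleanly separable by ICA but adds shared
  within-group variance to a module's genes, so occasionally a whole
  module misses the DEG threshold in one draw. 0.4 is the study default
  (reliable DE recovery; module structure still present); the
  cluster-purity test runs the generator at 1.0, the separable-program
  regime, and states so. Passing tests therefore show the operations work
  in their intended regimes, not that any single setting optimizes all
  criteria at once — real data will sit somewhere between.
* **Genotypes.** Three groups (wild `O.ruf`, cultivated `japonica`,
  `indica`), Balding–Nichols frequencies around ancestral
  `p ~ U(0.1, 0.9)` with `Fst = 0.3`; ~2000 variants allocated evenly
  over twenty 7-kb regulator gene regions (~1 variant / 70 bp, a
  realistic density which also keeps ≥3 sites per 200-bp window so the
  sweep statistic is stable against pure drift). Inside the sweep window
  (default: the focal hub's gene body) cultivated frequencies are pushed
  toward fixation (residual heterozygosity ~5%) — frequency-pushing
  rather than coalescent simulation, which would add machinery without
  changing what the pi contrast tests.
* **Causal + cline variant.** One promoter InDel of the focal hub,
  placed outside the sweep window so it stays polymorphic. Its genotypes
  come from a Gaussian threshold construction tied to each accession's
  precipitation, with a closed-form attenuation correction so
  `cor(dosage, precipitation)` lands near `precip_gradient`
  (default 0.6). Using one variant as both the trait-causal and the
  climate-clined allele mirrors the narrative the pipeline is built for.
* **Phenotypes.** `y = beta·dosage + u + e` for cultivated accessions
  only, with `Var(u) = h2·sd^2·K` and `Var(e) = (1-h2)·sd^2`
  (`h2_polygenic = 0.3`, `pheno_noise_sd = 1`, `causal_beta = 1`
  defaults).
* **Determinism.** One master seed spawns fixed child seeds per
  generator (expression, genotypes, phenotypes, geography), so identical
  configurations produce byte-identical artifacts (verified down to the
  written VCF/TSV/JSON files) and each generator is reproducible in
  isolation.

What the generator does **not** emulate: linkage disequilibrium decay and
recombination maps, demography beyond two-level drift, batch effects,
library-preparation biases, multi-variety/stage expression designs, or
spatially interpolated climate rasters. Tests passing on this generator
show the statistics recover the structures they target under their own
assumptions — they do not certify performance on real resequencing data.

## 7. Pipeline orchestration

`run_pipeline()` executes deg → ICA → per-cluster networks → per-hub
association → diversity/geography, logs each step with its parameters,
reports *all* regulators with per-step evidence (so the funnel can be
audited), and sets `final_pass` as the strict conjunction. Relaxing any
single threshold can only grow the pass set (tested). `write_report()`
emits a TSV and a JSON with a provenance block — parameter echo, a
configuration hash, package version — and no timestamps, so identical
runs serialize byte-identically.

Problem sizes used in the shipped tests and acceptance script (2000
genes, 18 samples, 210 accessions, 2000 variants, 10–20 seeds per
stochastic check) were chosen as the smallest sizes at which each
statistic is comfortably in its asymptotic regime; all scale linearly
upward.

## 8. Known limitations

* The DE stage is a Welch test on log-TPM, not a count-model Wald test;
  with very low counts or extreme dispersion its power profile differs
  from negative-binomial testers.
* EMMAX's fixed-ratio approximation mildly misstates p-values when a
  single variant explains a large variance fraction; `exact = TRUE`
  exists for that case.
* The ICA assignment rule (thresholded argmax) leaves genes unassigned by
  design; pipelines needing exhaustive partitions should lower `z_cut`.
* `h2` point estimates from a single fit on weakly structured panels are
  noisy (see §4); only averages over many fits are interpretable.
* The sweep statistic contrasts diversity ratios only; it does not
  implement haplotype- or SFS-based sweep tests (XP-CLR, XP-EHH,
  Tajima's D), which are out of scope.
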
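# stresshub

Identification of hub stress-responsive transcription-factor genes by
integrated network inference and population-genetic filtering.

## The problem

Plant genomes encode large transcription-factor families (the NAC family
in rice has >150 members), and only a handful of members act as *hubs* of
the drought- and heat-stress response. `stresshub` implements, as a
reusable and fully testable R pipeline, a three-step funnel that nominates
such hubs from multi-omic evidence:

1. **Transcriptome** — genes differentially expressed under stress
   (|log2FC| > 1 and BH-adjusted p < 0.05 against the control) are pooled
   across stress contrasts, decomposed into independent components
   (FastICA with the logcosh contrast on gene-wise Z-transformed
   log2(TPM+1)), and assigned to co-expression clusters. Per cluster, a
   regulator→target network is inferred GENIE3-style: one random-forest
   regression per target on the transcription-factor panel, edge weight =
   the regulator's normalized share of impurity reduction. Regulators are
   ranked by retained out-degree (top-*E* edges per target); top-ranked
   regulators are the hub candidates.
2. **Genome × phenome** — for each hub candidate, variants in its gene
   body + promoter (−3000 bp) are tested for association with
   drought-tolerance traits (e.g. the image-derived GPAR-R) under a
   kinship-aware mixed linear model, `y = Xb + g·beta + u + e` with
   `u ~ N(0, sigma_g^2 K)`: variance components by spectral REML (EMMA),
   per-variant F-tests at the REML variance ratio (the EMMAX / "P3D"
   approximation), significance at p < 1e-4; LD within the region as
   dosage-correlation R².
3. **Population genetics & geography** — candidates must show a selective
   sweep signature (windowed nucleotide diversity
   `pi = (n/(n-1))·2p(1-p)` summed per 200-bp window, cultivated groups
   depressed relative to wild *O. rufipogon*) and a precipitation-linked
   geographic distribution of the associated allele (Welch test +
   point-biserial correlation of mean precipitation between allele
   classes).

A candidate passes only the conjunction of all three filters.

Because the real inputs (RNA-seq of stressed cultivars, a genotyped and
phenotyped germplasm panel, wild-rice resequencing, climate records) are
large and access-restricted, the package ships a **synthetic-data
generator with planted ground truth**: hub-driven co-expression programs
with heavy-tailed latent activities, Balding–Nichols two-level population
structure, a causal promoter InDel, a low-diversity sweep region in the
cultivated groups, and a precipitation cline — so that every stage, and
the pipeline end-to-end, is verifiable by plant-and-recover tests.

## Worked example

```r
library(stresshub)
library(dplyr)

cfg    <- sim_config(seed = 42, n_planted_hubs = 1)   # one planted hub
bundle <- simulate_bundle(cfg)                        # expression + VCF-backed panel + phenotypes + geography
report <- run_pipeline(bundle, pipeline_params(n_trees = 500, seed = 1))
#> [stresshub] step 1: 158 DEG rows, 121 distinct genes (lfc > 1, padj < 0.05)
#> [stresshub] step 1: ICA K = 9, 36/121 genes assigned
#> [stresshub] step 1: 720 edges; top regulator NAC001 (degree 27)
#> [stresshub] step 2: null mixed model fitted for 1 trait(s), n = 140
#> [stresshub] final: 1/20 regulator(s) pass all three filters

head(as_tibble(report) %>%
  select(regulator, hub_degree, hub_rank, n_sig_variants, best_p,
         sweep_pass, precip_pass, final_pass), 5)
#> # A tibble: 5 × 8
#>   regulator hub_degree hub_rank n_sig_variants   best_p sweep_pass precip_pass final_pass
#>   <chr>          <int>    <int>          <int>    <dbl> <lgl>      <lgl>       <lgl>
#> 1 NAC001            27        1              1 2.60e-15 TRUE       TRUE        TRUE
#> 2 NAC013            16        2              0 9.40e- 3 FALSE      FALSE       FALSE
#> 3 NAC019            16        3              0 2.43e- 3 FALSE      TRUE        FALSE
#> 4 NAC004            15        4              0 1.65e- 2 FALSE      TRUE        FALSE
#> 5 NAC007            14        5              0 1.24e- 2 FALSE      FALSE      FALSE

bundle$truth$hub_gene_ids
#> [1] "NAC001"
```

Reading the table: `NAC001` tops the network-degree ranking (27 retained
out-edges), carries one regional variant associated with the trait at
p = 2.6e-15 (the planted promoter InDel), its gene body shows the
cultivated-vs-wild diversity collapse, and the carriers of the associated
allele come from wetter climates — so it alone satisfies the conjunction,
exactly matching the planted truth. Decoy regulators are dropped at step 2
(no variant below 1e-4) even when their degree rank is high.

Every stage is also usable on its own (`call_degs()`,
`fastica_decompose()` + `assign_clusters()`, `infer_grn()` +
`rank_hubs()`, `kinship_matrix()` + `fit_null_reml()` + `scan_region()`,
`ld_r2()`, `windowed_pi()` + `sweep_contrast()`,
`precipitation_association()`), reads/writes plain-text artifacts (TSV,
VCF 4.2, JSON), and has `autoplot()`/`tidy()`/`glance()` methods where a
result benefits from them.

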
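# pandosage

Statistical tools for studying **gene-dosage balance through copy-number
variation (CNV)** in plant gene families, built around the melatonin-pathway
O-methyltransferases ASMT and COMT. The package is aimed at comparative and
pan-genomicists who have per-genome annotations, homology-search hit tables
and coding sequences, and want to go from those to reproducible
dosage-balance statistics — without re-gluing a dozen one-off scripts.

## What it computes

* **Family catalog** — filter domain-scan/similarity hits (E ≤ 1e-5,
  protein length in [200, 600] aa), label candidates ASMT vs COMT by best
  reference similarity, tabulate per-species copy numbers, and rank
  alignment columns separating the subfamilies by mutual information with a
  permutation null.
* **Pan-genome OGGs** — greedy CD-HIT-style clustering (identity ≥ 95%,
  coverage ≥ 90%, longest representative) into orthologous gene groups,
  presence/absence matrices, Core / Shell / SoftCore / Cloud occupancy
  classes, and the openness power law *n = k·N^(−a)* fitted to new-OGG
  discovery curves.
* **Molecular evolution** — Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor
  correction, coverage filtering, Gaussian-mixture decomposition of Ks
  distributions with BIC-selected component count, and molecular-clock
  dating *T = Ks / (2 × 6.5·10⁻⁹) × 10⁻⁶* Myr.
* **Synteny** — dynamic-programming chaining of anchor pairs into collinear
  blocks, duplication-origin classification (WGD/segmental, tandem,
  proximal, dispersed, singleton), and synteny networks with
  connected-component communities.
* **Dosage statistics** — subfamily-on-total regressions whose slopes sum
  to one (the slope ratio quantifies which subfamily absorbs copy growth),
  k-means high/low copy splits with Welch-t and Mann–Whitney contrasts,
  receptor–enzyme Spearman correlation, ploidy fold changes, and
  FPKM-based subfamily expression comparison.
* **Synthetic data** — generators with recorded ground truth for every
  input class (copy tables, codon pairs with target Ka/Ks, pan-genomes
  with planted OGGs, Ks mixtures, labelled alignments, expression
  matrices), so the whole pipeline is testable offline.

See the methods vignette (`vignettes/dosage-balance-methods.Rmd`) for the
models, conventions and numerical choices.

## Worked example

Simulate a 1052-species survey in which ASMT takes a 60% share of every
added family copy, and recover the dosage regression:

```r
library(pandosage)

tab <- simulate_copy_number_table(1052, asmt_share = 0.6, seed = 1)
subfamily_regression(tab)
#> Dosage regression over 1052 species
#>   ASMT slope = 0.601, COMT slope = 0.399, ratio = 1.503
#>   ASMT-share trend: Pearson r = 0.001 (p = 0.974), Spearman rho = -0.021 (p = 0.498)
```

The slopes sum to one by construction (the two counts sum to the
predictor); the ratio ≈ 1.5 says ASMT absorbs 60/40 of copy-number growth.
Date a synonymous-substitution peak and fit an openness curve:

```r
divergence_time(0.338)      # Ks 0.338 at 6.5e-9 subs/site/year
#> [1] 26                    # million years

N <- 1:48
fit_power_law(N, 31.42 * N^(-0.29))
#> Pan-genome openness power law: n = 31.42 * N^-0.29
#>   pseudo-R2 (original scale): 1.0000 on 48 points
```

Decompose a Ks sample into Gaussian components with BIC:

```r
ks <- simulate_ks_mixture(poaceae_ks_components(), 10000, seed = 1)
fit <- filter_and_fit_ks(as.numeric(ks), seed = 1)
fit$selected_k
#> [1] 3
```

End-to-end workflows (`run_cnv_workflow()`, `run_pangenome_workflow()`)
chain the stages from one config list with a single root seed and emit
JSON reports embedding the config hash.

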
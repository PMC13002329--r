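---
title: "Methods: copy-number dosage balance in the ASMT/COMT gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number dosage balance in the ASMT/COMT gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandosage)
```

## The scientific problem

Melatonin biosynthesis in plants ends with an O-methylation step carried
out by N-acetylserotonin O-methyltransferase (ASMT) and by its broader
specificity relative, caffeic acid O-methyltransferase (COMT). The two
subfamilies form one homologous gene family whose copy number varies
enormously across land plants, and the balance between ASMT and COMT
copies — rather than either count alone — appears to be the regulated
quantity: the catalytically efficient COMT stays at low copy number while
the less active ASMT amplifies under high-copy conditions. `pandosage`
implements the statistical machinery needed to study that hypothesis:
family cataloguing from homology-search hits, pan-genome orthologous gene
group (OGG) construction with occupancy classes and openness curves,
Ka/Ks and Ks-peak dating of duplication events, synteny-based duplication
typing, and the dosage-balance statistics themselves. Every stage can run
on synthetic data with recorded ground truth, so the whole pipeline is
testable without genome downloads.

## Models and procedures

### Copy-number allocation and the dosage regression

The central descriptive model treats each species' ASMT count as a
binomial share of its family total: `asmt ~ Binomial(total, p)`. Ordinary
least squares of `asmt` on `total` and of `comt` on `total` then has a
useful algebraic property: because the two responses sum to the
predictor, the two slopes sum to one *exactly*, on any data. The ratio of
slopes (ASMT slope / COMT slope) is the headline dosage statistic: a
ratio of 1.5 means ASMT absorbs 60% of each added copy. The synthetic
generator (`simulate_copy_number_table()`) uses exactly this binomial
allocation — which is also why it was chosen over, say, independent
Poisson counts: the slopes-sum-to-one identity the regression exploits is
then true by construction rather than approximately.

`split_high_low()` divides species into high- and low-copy groups by
k-means with k = 2 on the one-dimensional totals. In 1-D, Lloyd's
algorithm with the two extreme values as initial centers provably
converges to a threshold rule (every low total below every high total),
so the initialization is deterministic and no seed is needed. Group
contrasts use a Welch (unequal-variance) t-test and a Mann–Whitney U test
with normal approximation and tie correction; Welch was chosen because
nothing guarantees equal variances between a 20%-sized high-copy group
and the rest.

### Catalog construction

`filter_candidates()` screens homology hits at E ≤ 1e-5 and protein
length inside the closed interval [200, 600] aa (longer proteins suggest
fused tandem annotation artefacts, shorter ones domain loss). Where a
gene has both domain-scan and similarity evidence, the default rule is
the *union* — one passing hit from either source suffices — because the
integrated search strategy is recall-oriented; `require_both = TRUE`
gives the conservative intersection. Both length bounds are inclusive.

`rank_divergence_columns()` scores alignment columns separating the two
subfamilies by the mutual information (in bits) between residue identity
and subfamily label, with the gap character as a 21st symbol, plus a
label-permutation p-value. A defined, reproducible statistic was
preferred over wrapped ensemble learners: MI is the population quantity
that feature-importance scores estimate in this two-class setting, it
needs no tuning, and its permutation null is exact in distribution. The
default `top_k = 13` mirrors the number of candidate diagnostic residues
in the reference analysis (among them the tryptophan/phenylalanine
switch in the substrate pocket). Reported column indices are
alignment-relative (1-based, after any trimming the caller applied).

### OGG clustering and the pan-genome

`greedy_cluster()` reproduces the greedy incremental clustering used by
CD-HIT-style tools: sequences sorted by decreasing length (ties broken by
id so output is reproducible), each sequence joining the *first* cluster
whose representative it matches at identity ≥ 0.95 and coverage ≥ 0.90,
else founding a new cluster. Identity is identical positions over aligned
columns of a global BLOSUM62 alignment (gap opening 10, extension 0.5);
coverage is residue-residue aligned columns over the shorter sequence's
length. The delegating tools leave both denominators implicit, so they
are explicit and configurable here (`coverage_mode`, `best_match`).

Occupancy classes follow the standard pan-genome partition: Core (100%
of varieties), Shell ([90%, 100%)), SoftCore ([10%, 90%)), Cloud
(< 10%); everything not Core is dispensable. `openness_curve()` estimates
the new-OGG discovery curve by averaging over random variety orderings
(sampling without replacement, 100 iterations by default), and
`fit_power_law()` fits n = k·N^(−a) by nonlinear least squares on the
original scale, initialized from the log-log linear fit, reporting a
pseudo-R² (1 − SSres/SStot, original scale). The fit includes N = 1 by
default — the reference curves are fitted over the full range — with
`min_n` available to drop early points. Points with nonpositive n are
excluded (with a warning) because the log-log start is undefined there; a
fully closed pan-genome therefore has no fittable curve, and the
pan-genome workflow reports the curve without a fit in that case.

### Ka/Ks and Ks-peak dating

`ng86_kaks()` implements the Nei–Gojobori (1986) counting estimator with
Jukes–Cantor correction. Conventions, stated explicitly because
implementations differ at the margins:

* Site counts: per codon position, the synonymous fraction is the number
  of the three possible single-base changes that preserve the amino
  acid, divided by three; changes creating a stop codon count as
  nonsynonymous. S + N therefore equals 3 × (complete codon pairs).
* Multi-hit codons: differences are averaged over all substitution
  orderings with equal weight, excluding pathways through stop codons;
  if every pathway is blocked, all pathways are used with stop-passing
  steps counted as nonsynonymous.
* p ≥ 3/4 flags the estimate as saturated (an undefined value with a
  reason code, not an exception); Ks = 0 flags the ratio undefined
  rather than infinite, so mean-Ka/Ks contrasts stay finite.
* Coverage is complete codon pairs over the codons of the shorter
  ungapped CDS, and pairs below 75% coverage are excluded from peak
  analysis by default.

`filter_and_fit_ks()` decomposes a Ks sample into a univariate Gaussian
mixture fit by EM, selecting the component count k ∈ 1..6 by
BIC = −2 logL + (3k − 1) log n. Numerical choices: 10 k-means-seeded
restarts run for up to 100 iterations each, after which the best run is
polished to a 1e-6 absolute log-likelihood tolerance under a
5000-iteration cap — overlapping components make EM converge slowly, and
stopping a few hundred iterations early visibly biases the middle
component's mean at n = 10,000, so the polish cap is deliberately
generous (the inner loop is compiled, making this cheap). A 1e-6
variance floor prevents components collapsing onto single points. The
global density peak is read off a 2001-point uniform grid spanning the
retained Ks range, which is why a reported *peak* (e.g. 0.338) can
differ in the third decimal from the nearest component *mean* (0.339)
when components overlap. Divergence times use the molecular-clock
conversion T = Ks / (2 × 6.5e-9) × 1e-6 Myr, with the grass synonymous
rate 6.5e-9 substitutions/site/year as default.

Mixture sampling in the generator is untruncated: negative Ks draws are
kept, because truncating at zero would shift every component's sample
mean upward and bias recovery tests against the parameters being
recovered.

### Synteny and duplication typing

`chain_collinear_blocks()` chains anchor pairs (homologous genes with
per-chromosome gene-order ranks) by dynamic programming: within each
chromosome pair it repeatedly extracts the largest strictly monotone
chain — same or inverted orientation — with per-step rank gaps ≤ 25,
discarding chains below 5 anchors. The defaults mirror the conventional
MATCH_SIZE/gap settings of MCScanX-style tools; the chain score is
anchor count (unit weight) so results do not depend on alignment scores.
Anchors are assigned to the first (best) chain extracted, so each anchor
belongs to at most one block. `classify_duplicates()` then labels each
family gene by a strict priority: block anchor → WGD/segmental;
rank-adjacent family member → tandem; within 10 ranks → proximal; any
family homolog → dispersed; else singleton. `build_synteny_network()`
reports connected components of the family-gene anchor graph as
communities — deterministic and dependency-free where modularity
clustering would need a resolution choice; igraph's label propagation is
available to callers who want finer communities, but components are the
default and the tested definition.

## What the generators emulate — and what they do not

The synthetic data reproduce the *statistical structure* each stage
consumes: binomial subfamily allocation, codon pairs with tuned
synonymous/nonsynonymous event rates (stop-creating events never
proposed), pan-genome protein sets with planted OGG membership and
Bernoulli occupancy, Gaussian Ks mixtures, labelled alignments with
planted diagnostic columns, log-normal FPKM with a planted COMT shift
(interpreted as a log2 fold change). They deliberately do not emulate
indels, GC/codon-usage bias, rate heterogeneity across sites, phylogenetic
correlation among species, or annotation error. Passing recovery tests
therefore demonstrates the *estimators* are correct and well calibrated
on their assumed models, not that real genomes satisfy those models. One
structural subtlety: dispensable OGGs drawn absent from every variety do
not exist observationally, so they are dropped from the emitted
sequences and PAV truth, while the full presence-draw matrix is kept in
the truth record so occupancy-recovery tests can score the raw Bernoulli
draws without conditioning bias.

In the codon-pair generator the two descendant lineages split a Poisson
number of events; expected NG86 estimates match the targets up to
multiple-hit effects, which the replicate-averaged consistency test
bounds at ±0.02 for Ks = 0.3 over 2000-codon pairs.

## Workflows, seeds and problem sizes

`run_cnv_workflow()` and `run_pangenome_workflow()` chain the stages and
emit JSON reports embedding the config and its MD5 hash. All randomness
derives from one root seed; stage seeds are `root + 1000 × stage_offset`
with fixed offsets, so a stage rerun in isolation reproduces its
in-workflow result, and a rerun with the same config is byte-identical.

Test problem sizes are chosen to keep the full suite within a few
minutes on one CPU while leaving comfortable statistical margins:
copy-number tables of ~1000 species (matching the reference survey's
scale), mixture refits at n = 10,000, pan-genomes of 3–8 OGGs × 4–5
varieties for clustering recovery (global pairwise alignment dominates
cost), ≤ 12 anchors for exhaustive chaining oracles, and 2000 simulated
datasets for the type-I-error calibration of the group tests.

## Known limitations

* Subfamily assignment uses best reference similarity only; the
  phylogeny-arbitrated classification used alongside similarity in the
  reference analysis is out of scope.
* NG86 is the only Ka/Ks estimator; maximum-likelihood codon models
  (GY94/YN00) would differ for diverged pairs.
* The ±0.02 recovery band for the middle grass Ks component is at the
  edge of what maximum likelihood can deliver from 10,000 draws: the
  0.339 and 1.131 components overlap it heavily, and the ML estimate of
  its mean varies by ~0.03–0.05 across samples (EM initialized at the
  true parameters converges to the same estimates, and the package's
  likelihood matches or exceeds an independent mixture implementation on
  the same data). Recovery of the dominant component is much tighter.
* The openness fit assumes exchangeable varieties; strong population
  structure would need stratified sampling of orderings.
* 1-D k-means with k = 2 always produces a cut even when totals are
  unimodal; the group tests, not the split itself, carry the inference.
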
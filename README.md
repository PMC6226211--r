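# cgmoa

Bioprocess target prediction from chemical-genetic interaction profiles.

## The problem

High-throughput chemical-genetic screens measure, for thousands of
compounds, a z-score profile of sensitivity/resistance across a panel of
gene-deletion mutant strains. On their own these profiles say *which
mutants* respond to a compound; they do not say *which biological process*
the compound perturbs. `cgmoa` answers that question by comparing each
chemical-genetic profile against a compendium of genetic interaction
profiles — since a compound inhibiting the product of gene *q* tends to
phenocopy *q*'s genetic interactions — and aggregating the evidence over
gene-set annotations (GO biological processes or protein complexes). It is
aimed at chemical-genomics and systems-biology groups prioritizing
compounds and modes of action from pooled deletion-collection screens.

## The method

With a strains × conditions chemical-genetic matrix *C* (treatments and
solvent controls), a strains × queries genetic interaction matrix *G*, and
a binary queries × terms annotation matrix *B*:

- **Similarity**: S = Cᵀ G′, where G′ is the L2 column-normalization of G.
- **Process scores**: X = S B (per-term sums of gene similarity scores).
- **Three empirical nulls** per (compound, term): z-scores and exact
  empirical p-values against (i) solvent-control profiles, (ii) profiles
  resampled per strain from the treatment score distributions, and (iii) a
  within-profile gene-label permutation null,
  z = (X/d − w) / (y/√d) with d the term size and (w, y) the compound's
  similarity-score moments.
- **Conservative combination**: the final p is the largest of the three
  (ties take the smallest associated z).
- **FDR**: for each observed p threshold, the control discovery fraction
  over the treatment discovery fraction, made monotone by a reverse
  running minimum and capped at 1 — computed against both control types
  (the resampled map is the conservative, default one; high-confidence
  means FDR ≤ 0.25).

The package also ships the two enrichment baselines (direct enrichment on
the 20 most-negative interactions; gene-target enrichment on top-n
similarity scores, hypergeometric tails), a simulation-based evaluation
suite (precision-recall of top predictions, gold-standard rank
significance with shuffle p-values, effective ranks at overlap index ≥
0.4, per-term normalized AUPR, Braun-Blanquet structural similarity), an
importance-score interpretation layer, and generators for fully synthetic
screens with planted compound→process signal.

## Worked example

```r
library(cgmoa)
net <- generateGeneticNetwork(seed = 11)        # 100 strains, 60 queries, 10 modules
scr <- generateScreen(net$gi, net$ann, seed = 12)  # 50 active, 50 inactive, 50 controls
res <- predictBioprocesses(scr$cg, net$gi, net$ann,
                           nGamma = 5000, nPerm = 2000, seed = 13)
res
#> BioprocessPredictions: 100 treatment profiles x 10 terms
#>   high-confidence profiles (resampled FDR <= 0.25): 50 (50.0%)

head(subset(res$predictions, condition_id == "cmpd_active_001"), 3)
#>      condition_id term_id        term_name  score      z p_count_numerator
#> 1 cmpd_active_001     M01 module 1 process 150.37 6.3742                 0
#> 2 cmpd_active_001     M09 module 9 process  24.84 0.4234               600
#> 3 cmpd_active_001     M07 module 7 process  19.65 0.1774               775
#>   p_count_denominator      p source fdr_control fdr_resampled
#> 1                2000 0.0000 within      0.0000             0
#> 2                2000 0.3000 within      0.1111             1
#> 3                2000 0.3875 within      0.4478             1
```

The screen planted `cmpd_active_001` on query `Q0002`, annotated to term
`M01` — and `M01` is its top prediction with combined p below the 1/2000
permutation resolution (`p_count_numerator = 0`) and resampled-profile FDR
0. All 50 active compounds (and none of the 50 inactive ones) are
discovered at FDR ≤ 0.25:

```r
sum(discoveredAtFdr(res$fdrMaps$resampled, res$ptop$treatment, 0.25))
#> [1] 50
```

A shell front end wraps the same functions
(`inst/scripts/cgmoa.R`: `synthesize`, `resample`, `predict`, `enrich`,
`simulate-profiles`, `evaluate`, `importance`, `overrep`).

See `vignettes/bioprocess-prediction.Rmd` for the model, parameter and
calibration details.

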
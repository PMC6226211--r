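---
title: "Predicting perturbed bioprocesses from chemical-genetic interaction profiles"
author: "cgmoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting perturbed bioprocesses from chemical-genetic interaction profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmoa)
```

## The problem and the model

A chemical-genetic interaction profile records, for one compound, how
strongly each mutant strain in a pooled deletion collection is sensitized
(negative z-score) or made resistant (positive z-score) by treatment.
A genetic interaction profile records the same kind of information for a
query gene: the fitness deviation of each double mutant from its
multiplicative expectation. The central assumption of this package is that
a compound inhibiting the product of gene *q* produces a chemical-genetic
profile resembling *q*'s genetic interaction profile, so profile similarity
transfers functional annotations from genes to compounds.

Given a strains × conditions chemical-genetic matrix \(C\), a strains ×
queries genetic interaction matrix \(G\), and a binary queries × terms
annotation matrix \(B\), the pipeline computes:

1. **Similarity.** \(G\) is column-normalized to \(G'\)
   (\(G'_{\cdot q} = G_{\cdot q} / \lVert G_{\cdot q}\rVert_2\)), and
   compound–gene scores are the inner products \(S = C^\top G'\). Only the
   genetic side is normalized: \(S\) stays linear in \(C\), so stronger
   chemical-genetic profiles yield proportionally stronger gene scores.
2. **Aggregation.** Compound–process scores are the per-term sums
   \(X = S B\).
3. **Three empirical nulls.** Each score \(X_{ct}\) is converted to a
   z-score and an empirical p-value against (a) solvent-control profiles,
   (b) resampled profiles, and (c) a within-profile permutation null. The
   control-derived z uses the per-term control mean and sample standard
   deviation; the empirical p is the fraction of control scores at least as
   large (ties count). The within-profile z compares the term's mean gene
   score against the compound's own score distribution
   (\(z = (X_{ct}/d_t - w_c)/(y_c/\sqrt{d_t})\) with \(d_t\) the term size);
   its p-value comes from recomputing \(X\) after randomly permuting the
   gene labels of \(S\).
4. **Conservative combination.** Per (compound, term), the final p-value is
   the *largest* of the three and the final z is the one paired with it;
   p-ties resolve to the smallest z. The result is deliberately the least
   favorable reading of the evidence.
5. **False discovery rates.** For every observed p-value threshold, the
   fraction of control profiles whose best prediction passes is divided by
   the same fraction for treatments; the ratio is made monotone by a
   reverse running minimum and capped at 1. Two maps are produced — against
   solvent controls and against resampled profiles — and both are reported
   for every prediction. High-confidence calls conventionally use the
   resampled map at FDR ≤ 0.25, because resampled profiles carry
   treatment-specific variance that solvent controls cannot represent and
   therefore give the more conservative estimate.

The resampled null (step 3b) draws each strain's score independently, with
replacement, from that strain's scores across *treatment* conditions. This
preserves every mutant's marginal score distribution under treatment while
destroying cross-strain coherence, which is exactly the component of a
profile that carries pathway-level signal.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nGamma` | 50000 | resampled null profiles; the empirical p resolution against this null is `1/nGamma` |
| `nPerm` | 10000 | within-profile permutations (the reference never states a count; 10000 gives p resolution 1e-4 at modest cost) |
| `minTermSize`, `maxTermSize` | 4, 200 | term-size window; smaller sets give unstable sums, larger ones are uninformatively generic |
| `fdrCap` | 1 | upper bound on reported FDR (the raw ratio can exceed 1 when controls outpace treatments) |
| `nTop` (direct enrichment) | 20 | most-negative interactions used by the baseline |
| importance inner-product threshold | 2 | a query profile must score ≥ 2 against the compound to enter the mean profile |
| contribution cutoffs | ±2.5, +0.1 | interaction magnitude / importance defining a "contributing" strain (strong variant: ±5, +0.5) |
| overrepresentation region | z < −5, \|importance\| ≤ 0.1 | strong negative interactions that did not contribute |
| overlap-index threshold | 0.4 | term relatedness for the effective rank |

Empirical p-values are stored with their exact integer counts
(`p_count_numerator` / `p_count_denominator`), so they reproduce bit-exactly
regardless of numeric formatting; a p of exactly 0 is preserved and means
"below `1/denominator` resolution".

## Numerical choices

- **Zero-variance nulls.** When a term has zero variance across a control
  cohort (or a compound's similarity row is constant), the z-score is 0 if
  the numerator is 0 and otherwise a signed large-but-finite sentinel
  (±1e30), reported in `zeroVarTerms` / `zeroVarConditions`. The empirical
  p-value remains exact and governs all downstream decisions.
- **Within-null permutations.** The permutation null is implemented as one
  random gene relabeling per iteration applied across all conditions,
  realized as a row permutation of \(B\) so each iteration is a single
  matrix product. Per (condition, term) the tail counts are
  distributionally identical to permuting each condition independently,
  and the whole null costs `nPerm` small matrix products instead of
  `nConditions × nPerm` vector shuffles. Permutations are drawn with
  replacement from the permutation group.
- **Ties.** Prediction ranking uses the total order (p ascending, z
  descending, term id ascending), making every rank reproducible. In the
  combination rule, residual ties after the min-z rule resolve in the fixed
  source order control → resampled → within; the chosen (z, p) pair is
  invariant to that choice. In top-n selection, ties at the n-th score are
  all included and the *nominal* n is used in the enrichment formula; a
  `strictTies` flag resolves threshold ties at random instead.
- **Division conventions.** In the FDR ratio, 0/0 is defined as 0 and a
  positive control fraction over a zero treatment fraction is capped at
  `fdrCap`.
- **Missing data.** Input matrices must be dense; NaN cells are rejected at
  load (the scoring model has no missingness concept). An `imputeZero`
  escape hatch converts them to 0 with a warning.
- **Seeds.** Every stochastic step takes an explicit seed; the pipeline
  derives per-step seeds from one master seed, so a run is reproducible
  bit-for-bit.

## The synthetic screen generator

`generateGeneticNetwork()` builds a modular network: queries in a module
share a latent per-strain signature with weight `sqrt(withinModuleCorr)`
(default 0.7, a strong functional module), and each module defines one
annotation term. `generateScreen()` plants signal: an active compound is a
scaled noisy copy of a randomly chosen query column,
`signalStrength * base + noise`, with `signalStrength = 4` chosen so that
planted sensitivities reach |z| ≥ 5 as strong interactions do in real
screens, and `noiseSd = 0.5` of the signal's standard deviation. Inactive
compounds and solvent controls are unit-variance Gaussian noise — the
natural null for z-score profiles. With `signal = "negative"` the copy
keeps only the negative part of the parent profile, emulating screens where
virtually all functional information is carried by sensitivity
(negative) interactions; this is the configuration under which strong
prediction drivers are expected to be overwhelmingly negative.

What the generator does *not* emulate: batch and plate effects, replicate
conditions sharing a compound identity, heavy-tailed or sparse interaction
score distributions, and annotation structure beyond disjoint modules
(real gene sets overlap and nest). Passing tests on this fixture therefore
demonstrate that the statistical machinery is correct and calibrated under
its own assumptions — not that those assumptions hold in any particular
real screen.

## Calibration: what the tests show and do not show

On an all-null screen the FDR maps report values near 1 at permissive
thresholds, and empirical p-values from each single null are uniform. The
*combined* p-value, however, is the maximum over three estimates of the
same tail probability, each carrying independent estimation noise (finite
control cohorts; the within null's reference is rebuilt from each
compound's own gene-score vector). The maximum of noisy estimates is
biased upward, so at desk scale the combined p is visibly super-uniform —
conservative, never anti-conservative. The bias shrinks only as *all*
cohort sizes grow toward study scale (thousands of controls, tens of
thousands of resampled profiles and permutations, ~1500 queries). Our
calibration checks therefore assert the conservative direction
(`P(p ≤ q) ≤ q` + counting slack) and run the uniformity diagnostic on an
exchangeable (`withinModuleCorr = 0`) network, where the within null's
exchangeability assumption holds exactly; on a modular network the
within-profile null additionally understates the variance of correlated
term sums, which makes combined p-values *more* conservative still. A
two-sided uniformity test at desk scale fails for these structural
reasons, and we keep it failing rather than weaken it: the method trades
exact uniformity for a guarantee against anti-conservatism.

Problem sizes used by the shipped checks: 100 strains × 60 queries in 10
modules, 50 active / 50 inactive compounds, 50 solvent controls, 5000
resampled profiles and 2000 permutations, five seeds; the
simulated-profile count check uses the full 289 × 1505 geometry with 3
replicates (4515 profiles). These sizes make every check rerun in seconds
to a few minutes while keeping all empirical-p resolutions meaningful.

## Evaluation and interpretation layers

For benchmarking, `simulateProfiles()` turns each query profile into
simulated compound profiles (Gaussian noise, per-strain variance twice the
observed strain variance, three replicates per query) that inherit the
parent query's terms as a gold standard. `topPredictionPR()` sweeps the
(p, z)-sorted top predictions accumulating precision and recall;
`goldRankSignificance()` assesses a gold term's rank against random
reassignment of (p, z) pairs to terms (counting shuffles achieving the
same or better rank, i.e. ≤); `effectiveRank()` credits closely related
terms (overlap index ≥ 0.4); `perTermAupr()` uses average precision (the
step-function integral) normalized by the positive fraction — the random
baseline — which makes the convention choice immaterial for comparisons.

`importanceProfile()` explains a prediction strain by strain: the mean of
the term's qualifying normalized genetic profiles times the compound's
profile (Hadamard product). Importance is positive exactly where the two
interaction types agree in sign. `strainOverrepresentation()` then asks
which strains repeatedly show strong negative interactions *without*
contributing (importance within ±0.1) — in real screens such strains track
general stress response rather than specific modes of action. Note the
deliberate asymmetry: "contributing" uses a one-sided importance cutoff
(≥ +0.1), while the overrepresentation region uses the two-sided band
(|importance| ≤ 0.1).

## Known limitations

- Per-profile FDR only: the maps rate a compound's *best* prediction;
  there is no per-term FDR.
- The within-profile permutation null assumes exchangeability of a
  compound's gene scores; correlated gene sets make it conservative (see
  above), never anti-conservative in the combined statistic.
- Dense matrices only, at the scale of hundreds of strains and up to tens
  of thousands of conditions in memory.
- The direct-enrichment baseline consumes only the most negative
  interactions; resistance (positive) signal is invisible to it.
- Annotation propagation honors `is_a` edges only.

## A minimal run

```{r example, eval = FALSE}
net <- generateGeneticNetwork(seed = 11)
scr <- generateScreen(net$gi, net$ann, seed = 12)
res <- predictBioprocesses(scr$cg, net$gi, net$ann,
                           nGamma = 5000, nPerm = 2000, seed = 13)
res
head(res$predictions)
sum(discoveredAtFdr(res$fdrMaps$resampled, res$ptop$treatment, 0.25))
```
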
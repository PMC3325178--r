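---
title: "Testing whether a gene class is unusually susceptible to expression perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether a gene class is unusually susceptible to expression perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classrank)
```

## The question

Some gene classes are hypothesised to respond to an environmental exposure
as a group. Imprinted genes are the motivating example: because they are
functionally mono-allelic and sit under several layers of epigenetic
control, one can argue either that they should be *more* vulnerable to an
in-utero insult such as maternal undernutrition, or that the extra
regulation should *protect* them. Neither hypothesis can be assessed from
a handful of candidate genes; it needs the whole transcriptome as the
reference. `classrank` implements that class-versus-transcriptome
comparison:

1. **Per-gene differential expression** between conditions with
   Benjamini-Hochberg FDR control (`de_test`, `bh_adjust`,
   `call_significant`, `power_fold_change`).
2. **Rank-distribution profiling**: where do the class members sit when
   the whole transcriptome is ordered by FDR q-value, compared with
   size-matched random sets, a protected (housekeeping) control and a
   responsive positive control (`rank_distribution`, `ks_departure`,
   `random_set_envelope`, `rank_profile_verdict`)?
3. **ROC/AUC gene-label permutation test**: the AUC of class membership
   against the FDR ordering, referenced to AUCs of randomly relabelled
   sets (`roc_curve`, `roc_auc`, `roc_permutation_test`).
4. **Gene set enrichment**: a running-sum (Kolmogorov-Smirnov-type)
   enrichment score along the signed-t ordering with permutation
   normalisation and tail-ratio FDR (`enrichment_score`, `gsea`).
5. **Factorial candidate-gene analysis**: two-way ANOVA partitioning of
   expression variance into maternal, paternal and interaction percent
   contributions for a 2x2 cross, plus one-way ANOVA with Bonferroni
   post-tests (`two_way_anova`, `one_way_bonferroni`).

Because no real dataset ships with the package, every stage is validated
against a synthetic transcriptome generator with planted ground truth
(`synthetic_design`, `generate_expression`,
`generate_factorial_candidates`, `generate_gene_sets`).

## The synthetic study and what it emulates

`synthetic_design()` encodes a two-condition (control `C` vs
undernourished `UN`) or 2x2 factorial study. Its defaults are the
conditions used throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 10,000 | transcriptome size after detection filtering |
| `class_sizes` | responsive 200, housekeeping 500, neutral 90 | planted classes; the rest is background |
| responsive effect | ±log2(1.5), half up / half down | the fold change the emulated arrays were powered for |
| `noise_meanlog`, `noise_sdlog` | log(0.2), 0.25 | per-gene residual sd drawn log-normally around 0.2 log2 units |
| `housekeeping_sd_factor` | 0.5 | "protection" modelled as halved residual sd, delta = 0 |
| `n_per_group` | 10 | samples per condition |
| `litter_sd` | 0.1 | additive random intercept shared by littermates |
| `litters_per_group` | 3 | samples assigned round-robin to litters |
| `sex_effect` | 0 | optional additive log2 shift for males |

The neutral class plays the role of the focal (imprinted-like) gene class
under the null hypothesis that class membership is unrelated to the
response: its members are statistically indistinguishable from background
genes. The responsive class is the positive control (a
starvation-response-like set), the housekeeping class the negative
control. Expression is Gaussian on the log2 scale, which matches
post-normalisation array intensities well enough for the t-test to be the
natural per-gene statistic; it deliberately omits heavy tails,
mean-variance coupling and probe-level artifacts of real arrays, so green
tests certify the statistical machinery, not robustness to platform
pathology.

All randomness flows from the single `seed` field; `derive_seed()` gives
each downstream stage its own deterministic stream, and identical
`(design, seed)` pairs reproduce byte-identical matrices.

## Statistical choices worth knowing about

**Per-gene test.** A plain two-sample t-test (pooled variance by default,
Welch and a simple shrink-toward-median-variance option behind flags).
Moderated statistics would gain power at small n but make the null
analytically opaque; a plain t keeps every calibration test exact.
Degenerate genes are kept, not dropped, so all stages share one gene
universe: zero variance with equal means gives p = 1, zero variance with
unequal means gives the smallest representable p and a `zero_var_shift`
flag.

**FDR and ranking.** `bh_adjust` applies the Benjamini-Hochberg step-up
rule (validated against a brute-force threshold minimiser to 1e-12).
`rank_by_q` orders by q, breaking ties by raw p, then descending |log2
fold change|, then gene identifier in the C locale — a fully
deterministic permutation, so every rank-based statistic is reproducible
to the byte.

**Litter structure and calibration.** The litter intercept is shared by
all genes of a littermate, so treating samples as independent (as the
per-gene t-test does) is pseudoreplication whenever `litter_sd > 0`.
Two consequences are worth spelling out, because the package's own
simulated study displays both:

* per-gene p-values are anticonservative under the null, and
* the effect is *strongest for low-variance genes*: the housekeeping
  class, whose residual sd is halved but whose litter offset is not,
  rides the shared litter contrast to systematically extreme t values.
  In the bundled analysis the "protected" class therefore surfaces at
  the *perturbed* end of the FDR ordering — an artifact worth
  remembering when interpreting real litter-structured studies.

The class-level inferences that matter — the rank-profile verdict and
the ROC permutation test — are calibrated against *gene-label*
exchangeability at a fixed ranking, so they remain exact regardless of
litter structure (the labels of a neutral class are exchangeable with
background genes whatever the per-sample correlation). Calibration tests
of the per-gene t itself use designs with `litter_sd = 0`.

**Rank-profile verdict.** The visual comparison "does the focal class
track randomly chosen genes?" is made decisive through the
Kolmogorov-Smirnov-type departure `max_r |cumulative(r) - r/N|` of the
class's cumulative rank curve from the diagonal, referenced to the same
statistic over size-matched random draws. The verdict rule is the KS
exceedance (class declared non-random when its departure exceeds the
null 95th percentile), because a pointwise 2.5/97.5 per-rank envelope
controls no familywise crossing rate; the envelope is still computed and
reported as the descriptive band. Note one subtlety: random draws come
from the whole expressed universe and therefore contain a few genuinely
responsive genes (2% under the defaults). This makes the comparison
slightly anticonservative for a truly neutral class — in repeated
simulated studies the neutral class reads "indistinguishable from
random" about 92% of the time rather than the nominal 95%. That mirrors
the emulated study design, where the random control group is drawn from
the whole array.

**ROC permutation test.** Genes are traversed from rank 1 (most
perturbed), tied q-values as one block, so the trapezoidal AUC equals
the Mann-Whitney probability with midrank ties — asserted against an
explicit pairwise oracle. The null permutes which genes carry the class
label (equivalently, draws size-matched random sets), recomputing the
AUC against the fixed ranking. The reported empirical p-value uses the
add-one estimator `p = (1 + #{null >= observed}) / (n_perm + 1)`, which
cannot be zero; the raw exceedance count is reported alongside. Ranking
by |t| instead of q is available behind a flag. The default of 100
permutations matches the emulated study's procedure; it bounds the
smallest attainable p at 1/101.

**GSEA.** The default walk is unweighted (`exponent = 0`, the classic
KS form, equal to the two-sample KS statistic on member positions — the
cross-check in the test suite), with `exponent = 1` available. The null
is gene-set permutation against the fixed ranking; group-label
permutation would require recomputing the DE statistics per permutation
and is underpowered at n = 10 per group. NES divides the observed score
by the mean |null score| of matching sign, and the FDR is the tail-ratio
estimator of the original method — which is why unenriched sets
routinely receive q-values like 0.5-1.0 rather than uniform ones. When
the running sum's positive and negative extremes tie (it happens for
small lists), the positive one is taken, with a 1e-12 relative tolerance
so that the choice does not depend on accumulation order. A signed walk
on a class perturbed in *both* directions (the balanced responsive
class) can land on either extreme; its |NES| is what carries the signal.

**Two-way ANOVA.** Percent contribution is defined as
`100 * SS_effect / SS_total` (eta-squared). Sums of squares are Type II,
computed by model comparison on `lm.fit` residuals — marginal effects
respecting marginality, identical to all other types on balanced data
(asserted), robust to perfect fits where generic ANOVA helpers refuse a
zero residual sum of squares. With Type II on unbalanced data the
components may sum below the total; the output keeps all five SS columns
so the reader can see it. Litter is deliberately *not* modelled as a
random effect here, matching the candidate-gene analysis being emulated.
One replicate per cell pools the interaction into error and flags the
gene. The factorial generator plants variance fractions exactly: effect
codes ±1 with coefficients `sqrt(fraction)` and residual sd
`sqrt(1 - sum(fractions))`, so recovered percent contributions converge
to the planted fractions as replication grows.

**Power.** `power_fold_change` evaluates the noncentral-t power of the
two-sided two-sample test directly, so its size is exact at fold change
1 (power = alpha to 1e-6) — the property a Monte-Carlo oracle confirms
at 100,000 replicates.

## Problem sizes

The test-suite simulations use the study conditions the generator
defaults encode: 10,000 genes and n = 10 per group for study-scale
checks, with 1,000 replicate studies for permutation-test calibration,
100 replicate studies for planted-class detection, 200 random instances
for each brute-force oracle equivalence, and 100,000 replicates for the
power Monte-Carlo. Smaller universes (400-4,000 genes) are used where
the property under test does not depend on scale.

## Known limitations

* The generator's Gaussian, homoscedastic-per-gene model omits
  mean-variance coupling, outliers and missingness patterns of real
  platforms; conclusions about those require real data.
* The per-gene t-test ignores litter correlation by design (see above);
  a mixed-model extension is out of scope.
* GSEA's group-label permutation mode is not implemented; the gene-set
  null is the default for small-n studies and the only mode offered.
* The rank-profile verdict is calibrated for one focal set at a time; no
  multiplicity correction across sets is applied.
* Printed quantities from any particular real study (significant-gene
  counts, AUCs, NES values) are functions of undeposited data and are
  not reproduced here; the package reproduces the *procedures* and
  validates them on ground-truthed simulations.

## A minimal run

```{r example, eval = FALSE}
cfg <- study_config(
  design = synthetic_design(seed = 101),
  n_perm_roc = 100, n_perm_gsea = 1000,
  factorial = list(planted_fractions = c(maternal = 0.08, paternal = 0,
                                         interaction = 0),
                   n_per_cell = 6, genes = paste0("cand", 1:12)),
  seed = 101, out_dir = "results/run")
report <- run_study(cfg)
print(report)
```

The numbered scripts under `analysis/` run the same pipeline stage by
stage and write every table under `results/`.
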
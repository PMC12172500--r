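---
title: "Methods: multi-kingdom scalp profiling and the MiSCH index"
author: "mischkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-kingdom scalp profiling and the MiSCH index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Androgenetic alopecia (AGA) progresses through clinically graded stages
(Hamilton–Norwood; here Healthy, AGA3, AGA5, AGA7 for mild, moderate and
severe hair loss). The scalp carries a multi-kingdom microbial community
— bacteria profiled by 16S amplicons, fungi by ITS1 — whose composition
shifts with both host age and disease. `mischkit` implements an analysis
chain over genus-level relative-abundance profiles from two scalp
regions per subject (T, the frontal balding area, and H, the occipital
area):

1. **Diversity**: Shannon/Simpson/Chao1 alpha diversity, Jensen–Shannon
   divergence (JSD) beta diversity, principal coordinate analysis, and
   single-factor PERMANOVA effect sizes for host variables.
2. **Microbial age**: a random-forest regression of host age on taxon
   abundances, trained on healthy subjects only, used to detect the
   age-decoupling (plateau) of dysbiotic communities.
3. **Stage classification**: a multi-class random forest over combined
   bacterial and fungal genera, evaluated with subject-exclusive splits.
4. **MiSCH**, the Microbial Index of Scalp Health: a 0–100 score that
   combines the classifier's stage probabilities with each stage's JSD
   distance from the healthy microbiome, cut into severity categories,
   with discordance ("high-risk") flagging.

Everything is exercisable on a built-in Dirichlet-multinomial cohort
simulator, so the whole chain is testable without sequencing data.

# Data model

An `AbundanceTable` is a samples × taxa matrix of relative abundances
(rows renormalized to sum to one), tagged per-taxon with a kingdom and
table-wide with a taxonomic level. Kingdom tables are merged by
concatenation followed by row renormalization, which gives bacteria and
fungi **equal mass (0.5 each)** per sample. The alternative — leaving the
concatenation at row sum 2 — changes JSD magnitudes but not orderings;
equal mass prevents the kingdom with deeper profiling from dominating
every distance, and is switchable (`renormalize = FALSE`).

Taxonomic aggregation sums genera sharing a name at the target rank
within each kingdom; taxa unnamed at that rank pool into an
`unclassified_<kingdom>` bin. Ages are binned into 5-year intervals,
closed-open (`[20,25) … [55,60]`), with the final right edge closed.

# The synthetic cohort generator

The generator emulates the reference study design: 89 male subjects
(51 Healthy, 18 AGA3, 10 AGA5, 10 AGA7), two scalp regions each (178
samples), ages uniform on 20–60.

Per kingdom, each stage has a **template**: a mean genus composition.
A named *focal* panel (8 bacterial, 4 fungal genera) carries all
stage-dependent signal:

* *Propionibacterium* increases monotonically Healthy→AGA7 (0.30→0.55);
* *Corynebacterium* decreases strictly (0.26→0.07);
* *Malassezia* decreases (0.55→0.12);
* *Alternaria* stays low in Healthy/AGA3 and exceeds 50% of the fungal
  community in AGA7 (0.56);
* *Aspergillus* rises then falls, peaking at AGA5.

The focal panel's total mass is held constant (0.80) across stages.
This is deliberate: with unequal focal totals, compositional closure
would scale every background genus by a stage-dependent factor, making
*all* ~40 background genera weakly informative and blurring the
distinction between markers and background that the feature-selection
benchmarks rely on. Background masses follow a broken-stick profile.

Sampling is Dirichlet-multinomial: a subject-level composition is drawn
from `Dirichlet(c × template)` with precision `c = 80` (moderate
overdispersion typical of skin amplicon data); each region observes the
mixture `ρ·subject + (1−ρ)·fresh draw` with `ρ = 0.7`, then multinomial
counts at depth 20,000 are renormalized. In healthy subjects six genera
(*Paracoccus, Micrococcus, Rothia, Propionibacterium, Acinetobacter* and
the fungus *Cladosporium*) drift with age on the logit scale (slopes
±0.05–0.06 per year, applied before the Dirichlet draw and
renormalized, so no abundance can go negative); AGA templates carry no
age trend, which produces the age-plateau the microbial-age module is
meant to detect. Healthy templates differ mildly between regions
(logit offsets on a few genera); AGA templates are region-identical,
matching the observation that dysbiosis extends across the whole scalp.

Two calibrations were fixed once, by design, and are worth stating
explicitly. First, the Dirichlet precision sets how much the stage
clouds overlap; 80 gives strongly separated but noisy classes (held-out
classifier kappa ≈ 0.9, not 1.0). Second, the stage templates are placed
so that the **distance geometry matches the published category
thresholds**: the mean JSD of each stage from the healthy group,
normalized by the AGA7 distance, is ≈ 0.3 for AGA3 and ≈ 0.7 for AGA5.
Under the score defined below, that is exactly the geometry in which a
confidently-AGA3 sample lands in the mild band (25, 75] and a
confidently-AGA5 sample near the moderate band (15, 25] — the
interpretation the thresholds encode. A generator whose distance ratios
disagreed with that geometry would make the printed thresholds
meaningless for every downstream consumer.

`inject_high_risk()` appends n new single-region subjects generated from
a more severe stage's template but labeled with the milder clinical
stage — ground truth for discordance detection. What the simulator does
**not** emulate: real taxon-taxon covariance beyond compositional
coupling, batch effects, zero-inflation beyond multinomial sampling, or
OTU/species-level structure (coarser ranks come from a bundled synthetic
lineage; a species level below the generated genera does not exist).
Passing benchmarks on it shows the machinery is correct and the
protocol recovers planted structure at realistic noise — not that any
particular real cohort will reach the same numbers.

# Diversity

Shannon entropy uses the natural log (ecological convention; the base is
an argument). Chao1 is the bias-corrected estimator
`S_obs + F1(F1−1)/(2(F2+1))` and requires integer counts. JSD is
computed as `H(m) − (H(p)+H(q))/2`, `m = (p+q)/2`, with base-2
entropies and `0·log 0 := 0`, so it is a bounded pseudometric on
`[0, 1]`; the square-root metric form is available but the divergence is
the default reported quantity. Tiny negative round-off is clipped to 0.

PCoA is classical scaling of the double-centered `−D²/2` matrix
(`stats::cmdscale`); axes are restricted to positive eigenvalues and
negative eigenvalues are reported. PERMANOVA is single-factor
(per-factor bars, not sequential partitioning), delegated to
`vegan::adonis2`, with the add-one permutation p-value
`(1 + #{F* ≥ F})/(1 + n_perm)` so p is never 0; exhaustive tests pass a
permutation matrix. Age enters as its 5-year bin. The package reports
raw p-values; the study convention for significance is α = 0.01.

# Microbial age

The protocol has three stages, all on healthy subjects (both regions;
the fit refuses mixed-stage input unless overridden):

1. **Subsampled ranking** — 10 iterations, each fitting a 500-tree
   regression forest on a random 90% of samples and recording impurity
   (Gini) importances; taxa are ranked by the mean across iterations.
   Each iteration draws its seed from a named stream of the master seed,
   so adding iterations never reshuffles earlier ones.
2. **Forward selection** — prefixes of the ranking are scored by k-fold
   cross-validated mean absolute error, with folds grouped by subject so
   a subject's two regions never straddle a fold (102 healthy samples
   are 51 subjects × 2 — ungrouped folds would leak). The chosen
   criterion is MAE with a one-standard-error parsimony tie-break
   (smallest prefix within 1 SE of the best), mirroring the small
   optimal panels this protocol is meant to produce. Prefixes up to 30
   features are evaluated by default.
3. **Refit** on all samples with 500 trees.

Predictions for the AGA cohort come from the healthy-trained model; the
age curve (mean prediction per 5-year bin, per Healthy/AGA group) makes
the plateau visible, and `age_curve_slope()` quantifies it.

# Stage classification

Splits are **subject-exclusive and stage-stratified**: per stage,
`ceiling(0.7·n)` subjects train (rounding toward train), and both of a
subject's samples follow the subject. Cross-validation grouping likewise
deals subjects, stratified by stage, round-robin into folds. Performance
is Cohen's kappa (chance-corrected agreement, computed from the
confusion matrix), accuracy, and macro one-vs-rest AUC (per-class ROC
AUC averaged over classes present in the test labels; absent classes are
dropped with a warning).

The level × kingdom grid fits default-parameter forests for every
taxonomic level and feature set (bacteria / fungi / combined) on one
shared sample set — the screening step that identifies where the signal
lives. Feature selection ranks taxa by impurity importance from one
full-data fit, then scores ranking prefixes by grouped CV kappa; `k*` is
the first prefix attaining the curve maximum (tolerance 1e−9).
Hyperparameter tuning is two-phase — a 200-draw random search over a
compact forest grid (trees, depth, node size, mtry fraction, class
weights), then exhaustive enumeration of the ±1-neighbor grid around
the incumbent — scored on fixed folds; the screening steps use default
parameters and tuning is reserved for a final model.

# MiSCH

**Stage-distance weights.** For each AGA stage c, `d_c` is the mean JSD
over all (healthy sample, stage-c sample) pairs in the full merged
table; `d_Healthy := 0` (the healthy group is the reference point, so
its within-group spread is not a dysbiosis distance); `w_c = d_c / max_c
d_c ∈ [0, 1]`. Empirically non-monotone distances are used as-is with a
warning; an isotonic (pool-adjacent-violators) switch can enforce order.

**Probabilities.** The cohort is split 70/30 subject-exclusively, a
forest is trained on the training side, and class probabilities are
recorded for held-out samples; over 20 repeats each sample's vector is
the mean over the repeats in which it was held out — every probability
is out-of-sample. A sample never held out raises an error whose remedy
is more repeats. The probability model is trained on the **selected
top-genus panel** (the optimal multi-kingdom biomarkers from the
selection curve), not on all taxa: concentrating the trees on
discriminative genera is what makes the ensemble's vote distribution
sharp enough for confident samples to reach the extreme score bands.
Its forest uses 500 trees, node size 10, and balanced class weights
(the cohort is dominated by healthy subjects 51:10). Distance weights,
by contrast, always come from the full profile.

**Score.** The combiner is
`MiSCH = 100 × (1 − Σ_c p_c · w_c)`.
It reproduces the published boundary behaviour exactly — a pure-healthy
probability vector scores 100, a pure-maximal-stage vector scores 0, the
range is [0, 100] for every probability/weight pair — and moving
probability mass ε from stage i to stage j lowers the score by exactly
`100·ε·(w_j − w_i)`. The combiner is a pluggable design point; this is
the simplest form consistent with the stated inputs and range.

**Categories and flags.** Scores cut at the printed upper-closed
intervals: healthy (75, 100], mild (25, 75], moderate (15, 25], severe
[0, 15]. Categories map back to stages (healthy→Healthy, mild→AGA3,
moderate→AGA5, severe→AGA7); a sample whose mapped stage differs from
its clinical stage is discordant and labeled `"<clinical>–<mapped>"`
(e.g. `H–A3`, `A5–A7`); the more-severe direction is the high-risk flag.
Per subject, the **lower** of the two region scores is reported — the
conservative reading of scalp health. Flagged groups are compared with
reference stage groups by two-group PERMANOVA: a smaller pseudo-F
against the advanced stage means the flagged microbiomes resemble it.

# Numerical and operational choices

* Row normalization tolerance 1e−9; JSD requires rows within 1e−6 of 1
  and clips round-off negatives; symmetric matrices to 1e−12.
* All forests run single-threaded with explicit seeds (`ranger`), so
  every result is bit-reproducible; a master seed spawns named child
  streams per operation and per repeat.
* One-way ANOVA returns F = 0, p = 1 when the between-group sum of
  squares is zero (identical group means on identical data), instead of
  NaN.
* Ties in the selection curves: first index attaining the maximum.
* Degenerate guards: zero-sum samples, single-class training labels,
  singleton PERMANOVA groups, empty stage groups, all-identical
  compositions (degenerate weights) all raise early, named errors.

# Problem sizes used by the test-suite benchmarks

The suite exercises the full protocol at deliberately scaled sizes: the
reference 89-subject cohort for classifier and age benchmarks; 1,000
null data sets × 199 permutations for permutation-test calibration;
10,000 random simplex/weight draws for score bounds; a 100-genus cohort
with 27 planted markers for selection recovery; and the 10-sample
injected high-risk scenario. These sizes are the package's benchmark
design; the functions themselves accept arbitrary cohort sizes.

# Known limitations

* The simulator's independence assumptions (see above) make its
  benchmarks necessary, not sufficient, evidence about field data.
* Single-factor PERMANOVA only; confounded factors are not partialled.
* The 75/25/15 category thresholds are taken as published constants and
  exposed as configuration, not re-fit to new cohorts; on data whose
  stage-distance geometry differs substantially from the one described
  above, categories shift meaning accordingly.
* The hyperparameter space is a compact stand-in (the original study's
  full 648-configuration grid is not published in the main text); it is
  fully configurable.
* Species-level analyses require species-level input profiles; the
  bundled generator emits genera.
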
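---
title: "Methods: untargeted volatilomics of aging time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted volatilomics of aging time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volaging)
```

`volaging` analyses compound-by-sample tables of volatile abundances
measured by HS-SPME-GC-MS over an aging time course. This vignette
documents the models, the conventions behind every numerical choice,
and the synthetic-data generator that the test suite runs against. The
running design is six sampling time points (S0–S5) with six biological
replicates each plus pooled QC injections, grouped into four aging
stages G1 (S0–S1), G2 (S2), G3 (S3) and G4 (S4–S5).

## Data model

Three tables define a study: a **feature table** (compounds × samples,
peak areas or concentrations; unobserved cells are missing, never
zero), an **annotation table** (compound class, free-text aroma
descriptors, odor threshold in μg/g, pathway memberships), and a
**stage design** (sample → time point → stage, with QC flagged).
`align_dataset()` intersects the universes, reports what was dropped
from each side, and is idempotent.

Missing and zero abundances are replaced once, before any log
transform, by half the smallest positive observed value of that
compound (`fill_missing()`). Half-minimum is the common metabolomics
convention for below-detection values and keeps every log2 fold change
finite. The multiplier is configurable.

## Semi-quantification

Concentrations derive from the internal standard by

$$X_i = \frac{V_s \, C_s}{M}\cdot\frac{I_i}{I_s}\cdot 10^{-3}$$

implemented literally as printed on the bench protocol: with $V_s$ in
μL and $C_s$ in μg/mL the $10^{-3}$ converts μL·μg/mL to μg, so $X_i$
is in μg per gram of sample. With the bench constants
$V_s = 10\,$μL, $C_s = 10\,$μg/mL, $M = 0.5\,$g, a compound whose peak
area equals the standard's maps to exactly 0.2 μg/g. Each sample uses
its own standard area $I_s$; a non-positive $I_s$ is a hard error for
that sample.

## Class totals and compact letters

Per-sample class totals are sums of member-compound concentrations;
per class, a one-way ANOVA across time points (classic equal-variance
model, matching the Tukey follow-up) is followed by Tukey's HSD at
α = 0.05. The all-pairs result is summarised by an insert-and-absorb
compact letter display written in the package: starting from one
letter covering all groups, each significant pair splits every column
containing both members, subset columns are absorbed, and letters are
assigned in time-point order so the alphabet is contiguous from "a".
The display satisfies, and the tests assert, the defining property:
two groups share a letter exactly when their adjusted p ≥ α. A
hand-written display was needed because no installed routine maps a
raw pairwise p-matrix to letters.

## PCA

`pca()` computes the SVD of the column-centered (and optionally
UV- or pareto-scaled) matrix; explained variance ratios are
$d_a^2/\sum d^2$. Sign indeterminacy is fixed by making the
largest-magnitude loading of each component positive. A constant
column under UV scaling is an error that points at the scaling policy
rather than silently dividing by zero — dropping such columns is a
decision the caller should make. Components with singular values below
$10^{-12}\,d_1$ are discarded as numerical zeros.

## OPLS-DA

The discriminant model is written from scratch. The two-level class
vector is encoded −1/+1 and centered; X is UV-scaled internally with
the sample (n−1) standard deviation. For each of `n_ortho` orthogonal
components (default 1, plus exactly 1 predictive component — the
standard layout for a two-class model) the Trygg–Wold filter computes
the PLS weight $w \propto X^\top y$, the loading $p$, and removes the
component of $p$ orthogonal to $w$ together with its scores from X.
The predictive component is then a plain NIPALS PLS1 fit on the
filtered matrix. With `n_ortho = 0` the model reduces exactly to PLS1,
which the tests verify against an independently coded closed form.
Predictive scores are orthogonal to every orthogonal score vector by
construction (asserted at 1e-8).

* **R²Y** is $1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ of the centered
  class vector on the training data.
* **Q²** comes from stratified k-fold cross-validation (default 7
  folds, the common chemometrics convention; the fold assignment is
  seeded and recorded). Scaling and the full model are refit inside
  every training split; PRESS is accumulated on the held-out samples
  and referenced to the total centered sum of squares.
* **VIP** uses the predictive component only, the natural choice for
  an OPLS model where orthogonal components are noise by construction:
  with a single predictive component and unit-norm weights,
  $\mathrm{VIP}_j = \sqrt{K}\,|w_j|$, which makes the normalisation
  identity mean(VIP²) = 1 exact; the tests assert it to 1e-9.
* **Permutation validation** refits the full model (including CV)
  under uniform label permutations (default 200) and reports
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$ for both
  R²Y and Q²; the validation verdict should be read from Q², the
  cross-validated statistic.

Constant columns inside a CV training split are centered and left
unscaled — they carry no variance and contribute nothing, which keeps
resampling robust without a policy error at fit level.

## Differential screening

Fold changes are ratios of stage-mean concentrations,
$\log_2(\bar{X}_{G_b}/\bar{X}_{G_a})$. The per-compound test is a
two-sided Welch t-test on log concentrations: the log symmetrises
multiplicative MS noise, and Welch is the safer default when variances
drift with abundance. The protocol this package follows names only the
p < 0.01 criterion, not the test, so the choice is documented here and
`pairwise_test()` takes `method = "student"` or `"wilcoxon"` for
sensitivity analyses. When both groups are constant and equal the test
is undefined and p = 1 by convention.

Calls use the standard combined criteria — VIP ≥ 1 **and**
|log₂FC| ≥ 1 (inclusive) **and** p < 0.01 (strict). No
multiple-testing correction enters the primary screen, matching the
stated criteria of the workflow the package implements; BH q-values
are reported alongside for transparency. Comparisons default to the
first stage against each later stage (G1 vs G2/G3/G4). Top-k rankings
order by descending |log₂FC| with ties broken by smaller p, then
lexicographic compound id, so results are stable across runs.

## Trend clustering

Clustering operates on stage-mean profiles (G1..G4), not individual
samples: the object of interest is the shape of the time course, and
stage means are what the downstream aroma screen uses. Profiles are
UV-scaled per compound; constant profiles go to a dedicated flat
bucket instead of erroring. K-means (Lloyd iterations, Euclidean
distance) runs `n_init = 50` seeded restarts from distinct data rows
and keeps the lowest within-cluster sum of squares; on small instances
this attains the brute-force partition optimum, which the tests verify
exhaustively for n ≤ 10, k ≤ 3. k defaults to 8 expression patterns
and is a plain argument — no automatic model selection is attempted.

Centroids are labelled **up** if non-decreasing across stages with a
total rise above 0.1 scaled units, **down** symmetrically, otherwise
**other**. The tolerance keeps noise-level wiggles of flat profiles
out of the monotone classes; it is configurable
(`classify_trend(tol = )`).

## Enrichment

`hypergeom_tail()` evaluates $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$ through `stats::phyper`; the test
suite checks it against exhaustive enumeration for every argument
combination with N ≤ 12. The MSEA background is all detected,
annotated compounds — not a reference database universe — because
that is the set from which the differential compounds were actually
drawn; the pathway map is a plain user-supplied table (no live
database queries, which would make results version- and
network-dependent). The headline significance flag uses the raw
p < 0.05; BH q-values are reported but deliberately not used for the
flag, mirroring standard practice in this workflow's reporting.

## Aroma analysis

Stage-level concentration is the mean over the stage's samples.
rOAV = concentration / threshold. Two boundary conventions coexist
deliberately: the *flags* in the rOAV table use ≥ (rOAV ≥ 1 key,
≥ 10 pronounced), while the *key-compound screen* requires strictly
rOAV > 1 at the first or last stage — both conventions are as stated
in the originating workflow, and both are documented at the function
level. Compounds without thresholds are carried with missing rOAV and
excluded from category averages (treating them as zero would silently
drag averages down). A compound whose descriptors match several radar
categories contributes to each of them; exclusion would silently drop
information. Radar categories are UV-standardised across stages so
categories with very different absolute odor activity share one plot;
a category constant across stages gets a zero profile rather than NaN.

The key screen combines both evidence streams: a compound must sit in
a cluster whose centroid is monotone (direction comes from the
cluster) *and* be odor-active (rOAV > 1) at one end of the time
course.

## The synthetic generator

`synth_config()` defaults define the simulated study:

| parameter | default | rationale |
|---|---|---|
| compounds | 200 | enough for multivariate structure, fast tests |
| design | 6 time points × 6 replicates + 4 QC | the motivating study layout |
| class mix | terpenoids .21, esters .18, heterocyclics .12, ketones .10, aldehydes .09, others .30 | proportions of the dominant classes in cigar volatilomes |
| trend mix | up .15, down .10, transient .15, flat .60 | ~25% differential, matching typical long-aging contrasts |
| effect_log2fc | 2 | a 4-fold stage-extreme change, detectable but not trivial |
| noise_cv | 0.2 | typical biological replicate CV for volatile abundances |
| qc_cv | 0.05 | pooled-QC injections are analytically tight |
| base concentrations | 10⁻³–1 μg/g (log-uniform) | per-compound levels consistent with class totals of tens of μg/g over hundreds of compounds |
| odor thresholds | 10⁻³–10 μg/g (log-uniform) | thresholds span orders of magnitude |
| pathways | 15, background size ≈ 8 | sparse maps, one planted enriched pathway |
| planted keys | 14 up + 7 down | the canonical 21-compound key set |

Abundances are `base × stage multiplier × exp(N(0, σ))` with
`σ = sqrt(log(1 + cv²))` — strictly positive, CV-parameterised,
standard for MS intensities. Up/down trends are geometric across the
four stages (so the expected stage-mean log2(G4/G1) equals
`effect_log2fc`); transient compounds peak at G2. QC samples are the
per-compound mean across biological samples with 5% noise, emulating
pooled injections. Internal-standard areas are simulated per sample
with 2% CV so quantification is exercised nontrivially. Key planting
rewrites thresholds so planted keys get rOAV 5 at their active stage
end and all other trending compounds stay at rOAV ≤ 0.2 — so exactly
the planted set is both trending and odor-active.

The generator does **not** emulate chromatographic drift, co-elution,
identification error, or missingness patterns (its tables are
complete; missing-value handling is exercised separately through the
I/O layer). Passing tests therefore demonstrate correct statistical
behavior under clean multiplicative noise, not robustness to
instrument artifacts.

### The strong-separation benchmark

`synth_config_strong()` (effect_log2fc = 4, noise_cv = 0.1, 30% up /
20% down trending) is the configuration behind the package's
model-quality bound: on its G1-vs-G4 contrast (12 vs 12 samples) the
1+1-component OPLS-DA must reach R²Y ≥ 0.99 and seven-fold Q² ≥ 0.98,
which the acceptance checks assert. The high informative fraction is
the operative ingredient: with a 200-compound panel and 24 samples,
cross-validated predictions are otherwise dominated by the weight
noise of uninformative columns — a small-panel floor that caps Q²
near 0.975 *regardless of effect size* — whereas a profile in which
half the compounds separate the classes measures separation strength
itself. The recovery benchmarks (sensitivity/precision of the
differential screen, pathway recovery, key-compound recovery) run on
the plain defaults, which are deliberately noisier.

## Determinism and seeds

Every stochastic step (data generation, CV fold assignment,
permutations, k-means restarts) takes an explicit seed.
`run_pipeline()` fans a single run seed out to per-stage seeds through
fixed offsets (`derive_seed()`), so any stage can be rerun in
isolation with the seed recorded in the JSON manifest. Identical
configurations reproduce outputs bit-for-bit.

## Problem sizes in the test suite

The suite runs entirely on generated data: 200-compound / 40-sample
datasets for end-to-end checks, 50-run Monte-Carlo loops for the
planted-truth recovery rates, 200 label permutations and 200 random
differential sets for the null-behavior checks, and exhaustive oracle
enumeration for the hypergeometric tail (N ≤ 12) and k-means
partitions (n ≤ 10, k ≤ 3). These sizes were chosen so the full suite
exercises every claim while remaining quick to run on a laptop.

## Known limitations

* Two-class OPLS-DA only; multi-stage contrasts are handled as
  pairwise comparisons against the reference stage.
* The primary differential screen applies no multiple-testing
  correction (by design, to match the workflow it implements); use the
  reported q-values if family-wise control matters for your question.
* Odor thresholds are matrix-dependent inputs; the package neither
  fetches nor predicts them, and rOAV conclusions inherit threshold
  quality.
* The descriptor → radar-category mapping is a plain string match on
  the annotation descriptors; curating that vocabulary is the user's
  responsibility.
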
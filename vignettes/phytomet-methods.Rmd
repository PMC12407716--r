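---
title: "Curation and comparative statistics for untargeted plant metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and comparative statistics for untargeted plant metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models and procedures `phytomet`
implements, the assumptions behind them, the parameters a user might
reasonably change, and the design decisions taken where more than one
defensible choice existed.

## The data model

A `feature_table` couples three aligned pieces: per-feature metadata
(m/z in Da within the 50–1300 acquisition range, retention time in
minutes, candidate identity as name/InChI/SMILES, and the match-quality
metrics produced by acquisition software), per-sample design metadata
(organ ∈ {root, seed}, processing ∈ {extract, juice}, replicate number,
blank flag), and a features × samples intensity matrix in arbitrary
detector counts. Missing intensities are `NA` and are distinct from 0:
zero is a legal *post-imputation* value, whereas `NA` means the feature
was not measured in that injection. Blank samples carry
`organ = processing = "none"` by construction.

## Curation

`curate()` applies four stages in a fixed order: identification filter →
imputation → noise removal → blank subtraction. The order follows the
narrative order such tables are conventionally processed in; imputation
before noise removal means the noise rules see a complete matrix, and
blank subtraction last means the subtracted table is exactly the retained
feature set.

**Identification filter.** A feature passes when it has at least one
piece of identification evidence — spectral-library MS/MS score
strictly above `msms_min` (default 600), *or* in-silico fragmentation
score strictly above `insilico_min` (default 800), *or* a top-confidence
structure prediction — *and* survives the spectral-quality gate: mSigma
(isotope-pattern fit, lower is better) strictly below `msigma_max`
(default 30) and |mass error| ≤ `ppm_window` (default 2.5 ppm,
inclusive). Two readings of the criteria were possible — all clauses
conjunctive, or evidence-OR with a quality-AND — and the package
implements the OR-of-evidence/AND-of-quality reading: the evidence
clauses describe alternative identification routes, while spectral
quality is a property of the measurement that any route must satisfy. A
missing metric fails its own clause; it can neither serve as evidence nor
vouch for quality.

**Imputation.** Within each replicate group: a feature missing from
*all* replicates is considered absent and set to 0; a feature missing
from *some* replicates is set to its minimum observed intensity across
all non-blank samples minus 1 — a value on the feature's own intensity
scale that is guaranteed to rank below every real observation.
Replicate groups default to organ × processing cells
(`impute_scope = "cell"`); pooling all non-blank samples into one group
(`"all"`) is available for designs without a factorial structure. The
per-feature (rather than per-table) minimum was chosen because LC-MS
intensities span orders of magnitude across features, so a global
minimum would impute absurdly small values for intense features.

**Noise removal.** Three rules, applied in order and tallied
separately: (1) *blank-only* — the feature reaches the detection
threshold `detect_floor` (default 10,000 counts) in a blank but in no
experimental sample; (2) *blank-dominated* — the blank intensity is at
least the experimental intensity; (3) *below floor* — the maximum
experimental intensity is strictly below `noise_floor` (default
20,000 counts). "Higher in blanks" compares maxima by default
(`blank_rule = "max"`); medians are available, and are the more robust
choice when many blanks are run. `detect_floor ≤ noise_floor` is
enforced since a feature detectable nowhere should never survive the
floor rule.

**Blank subtraction.** The per-feature median over blanks is subtracted
from every experimental intensity and negative remainders are clamped to
0 — background estimates exceeding the signal mean the feature is absent
there, not negatively present. Blank columns are dropped afterwards.

The `curation_report` maps every input feature to exactly one
disposition, so the tallies always partition the input; this is asserted
in the test suite for every simulated table.

## Annotation

Identifiers are harmonized with Open Babel: InChI (preferred) or SMILES
in, canonical SMILES + InChIKey out. The conversion shells out to the
`obabel` executable because the in-process route discards stereo
descriptors, which would collapse stereoisomers' full keys. Novelty is
matched at the InChIKey *skeleton* level — the first 14 characters,
which hash connectivity only — because genus-level literature reporting
is frequently agnostic about stereochemistry, and a stereo-variant of a
reported compound should not count as new. The cost is that genuine
novel stereoisomers are invisible; this is the conservative direction
for a novelty claim.

Metabolites classified into more than one biosynthetic pathway or
superclass ("hybrids") are counted once under a primary label. No
chemistry dictates the tie-break, so it is a documented convention:
alphabetical by default, overridable by an explicit priority order, and
invariant to the input order of labels. Classification labels themselves
are consumed from input, not computed — pathway/superclass classifiers
are trained external services and re-implementing them is out of scope.

**NP-likeness.** The natural-product-likeness score follows the
fragment-contribution approach: atom-centered circular environments
(radius 0–2, Morgan-style iterative refinement over the heavy-atom
graph) are collected from a natural-product corpus and a synthetic
corpus; each fragment contributes the Laplace-smoothed log-odds of
occurring in a natural product; a molecule scores the sum of its
distinct fragments' contributions normalized by heavy-atom count,
clipped to [−5, 5]. The two training corpora are small curated lists
packaged as text with the source (74 plant natural products spanning the
major biosynthetic pathways, 41 synthetic drugs/agrochemicals/industrial
chemicals). With corpora this size the score is a screening annotation —
the tests require only that it is deterministic, bounded, and separates
the corpora with ≥ 90% sign accuracy — and it is never used as a
filter.

## Chemospace

Fingerprints are Open Babel FP2: 1024-bit binary vectors hashing linear
fragments up to seven atoms. The exact bit dialect is a property of the
backend and is pinned by a committed (SMILES, hex-bits) fixture so that
a backend upgrade that changes bits fails loudly. Tanimoto similarity is
|A∩B|/|A∪B| on bit sets; two all-zero fingerprints are defined as
identical (similarity 1, with a message) since neither carries
information. Clustering runs on the *dissimilarity* 1 − Tanimoto — for
binary vectors this is the Jaccard distance, a proper metric, and the
test suite asserts the triangle inequality on random bit vectors.
Linkage defaults to average (UPGMA), the conventional choice for
fingerprint chemospaces; complete and single are available and the
choice is recorded in the output object. Items are sorted by label
before clustering so ties break identically on every run and the Newick
export is byte-stable.

## Comparative statistics

All statistics operate on the curated table. The intensity transform is
`log2(x + 1)` throughout (PCA, moderated tests, optional Euclidean
distances): intensities are nonnegative and right-skewed, fold changes
are naturally multiplicative, and +1 keeps imputed zeros finite.

**PCA.** Features are centered and scaled to unit variance
(constant-intensity features are dropped with a warning, since their
z-score is undefined), then eigendecomposed by SVD. Component signs are
fixed by making each component's largest-magnitude loading positive —
signs are otherwise arbitrary and platform-dependent. Components with
singular values below `max(d) * 1e-12` are discarded as numerical noise.

**PERMANOVA.** The distance matrix is Gower-centered
(`G = -½ C D² C`); `SS_total = tr(G)`; a term's sum of squares is the
increment in `tr(H G)` as its design columns enter the cumulative hat
matrix, which for a single factor reduces to the familiar
within/between-group decomposition and for multiple factors gives
sequential sums of squares in the order written. Pseudo-F is the usual
ratio of mean squares; `R² = SS_term / SS_total`. Significance comes
from unrestricted permutation of sample labels with a seeded generator;
`p = (#{F* ≥ F} + 1)/(n_perm + 1)` so p can never be 0, and
`n_perm = "all"` enumerates every permutation, making p the exact rank
of the observed statistic. Bray–Curtis on curated intensities is the
default distance — the convention for nonnegative abundance data and
the default behavior of the standard implementations of this test —
with Euclidean-on-log2 as the option; the choice is recorded in the
result. With 999 permutations the smallest attainable p is 0.001, the
granularity at which such results are usually reported.

**Moderated differential abundance.** Per feature, the two-group pooled
variance `s²` has `d = n₁ + n₂ − 2` degrees of freedom. Across
features, variances are modeled as scaled inverse-chi-square with prior
degrees of freedom `d₀` and prior variance `s₀²`, fitted by the method
of moments on `z = log s²` using the digamma/trigamma expressions for
the mean and variance of a log-chi-square; the trigamma inverse is
computed by Newton iteration to relative tolerance 1e-10. When the
observed spread of `z` does not exceed its sampling variance, `d₀ = ∞`
and every posterior variance equals `s₀²` (complete shrinkage) — the
degenerate all-features-equal-variance input takes this path without
error. The posterior variance is the precision-weighted blend
`s̃² = (d₀s₀² + d·s²)/(d₀ + d)`; the moderated t has `d₀ + d` degrees
of freedom (normal in the infinite case). The two limits are exact and
tested: `d₀ = 0` reproduces the ordinary pooled t to 1e-9, `d₀ = ∞`
uses `s₀²` everywhere. Enrichment requires |log2FC| > 1 *and* BH-FDR
< 0.05. The fold-change sign convention is group2 − group1 with group
order (root, seed) and (extract, juice), so positive log2FC means
seed- respectively juice-enriched.

**Presence/absence.** A feature is detected in a factor level when its
intensity reaches `detect_floor` in at least one sample of that level;
the threshold is inclusive (≥ 10,000), matching the convention that
"not detected" means strictly below the threshold. Exclusive sets
(detected in exactly one level) and the shared set partition the
detected universe; this identity is asserted on every input.

## The synthetic-data generator

`simulate_feature_table()` generates the structure the analysis assumes:
a 2 × 2 design with `n_reps = 3` replicates per cell and
`n_blanks = 2` solvent blanks; per-feature baseline intensities
`exp(N(log 1e5, 1))`; replicate-level multiplicative log-normal noise
with CV 0.15 (mean-corrected so the expectation is the baseline); 15%
of features organ-enriched and 10% method-enriched by `±effect/2` in
log2 units per affected cell (so the group contrast equals
`effect_log2fc = 3`); 5% blank-only contaminants (full strength in
blanks, trace 0.1% in samples); 5% sub-floor features scaled into
[5,000, 19,000) counts — below the noise floor but above the solvent
background of `exp(N(log 1000, 0.5))`, so each planted role is
unambiguously identifiable; and 5% of ordinary-feature cells set
missing at random. Structures, names and pathway/superclass labels are
drawn from the packaged vocabulary with pathway weights shaped like a
real plant metabolome (terpenoids dominant); reference-set membership
is decided per *structure* (probability 0.25) so the same skeleton is
never both reported and novel. Everything is reproducible byte-for-byte
from the seed, and the generator's own RNG state is isolated from the
caller's.

What the generator does *not* emulate: retention-time drift, correlated
(co-eluting) features, intensity-dependent variance beyond the constant
CV, adducts/isotopologues of the same metabolite, and structured
missingness (real missingness concentrates at low intensities). Passing
recovery tests on this generator therefore demonstrates that the
pipeline's logic is correct under its stated assumptions, not that real
tables meet those assumptions.

## Problem sizes and test design

The test suite exercises simulated tables of 50–600 features; the
planted-recovery and calibration checks use the full 540-feature
configuration, exhaustive-permutation checks use n ≤ 8 samples (40,320
permutations at most), and the empirical-Bayes recovery check uses 2,000
simulated variances over 10 seeds, with tolerances (±30% on `d₀`, ±15%
on `s₀²`) pinned after repeated-run calibration of the estimator at
those sizes. An 80-feature fixture is committed as CSV and its
regeneration is checksum-pinned, so any change to the generator that
would silently shift ground truth fails the suite.

## Known limitations

* Identification filtering trusts the acquisition software's scores; no
  spectral rescoring is done.
* Novelty flagging is only as good as the offline reference list; it
  cannot see compounds reported but never deposited with structures.
* The NP-likeness corpus is deliberately small; scores rank structures
  sensibly but absolute values are not comparable to models trained on
  database-scale corpora.
* Two-factor PERMANOVA is sequential (order-dependent) by design;
  interactions and dispersion tests are out of scope.
* The moderated test covers two-group contrasts and the additive
  two-factor design only, not arbitrary design matrices.
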
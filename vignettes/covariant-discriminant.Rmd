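---
title: "Classifying nucleosome-forming DNA with physicochemical profiles and a covariant discriminant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nucleosome-forming DNA with physicochemical profiles and a covariant discriminant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscan)
```

## The problem and the representation

Nucleosome formation depends on how easily a ~147-bp stretch of DNA
bends and twists around the histone octamer, which makes structural and
thermodynamic properties of the double helix a natural feature space
for telling nucleosome-forming segments from linker (nucleosome-
inhibiting) ones. `nucleoscan` represents a 150-bp segment by sliding
a 2-bp window with 1-bp step and replacing each of the 149
dinucleotides with its normalized value on twelve physicochemical
scales — A-philicity, base stacking, B-DNA twist, bendability, DNA
bending stiffness, DNA denaturation, duplex disrupt energy, duplex
free energy, propeller twist, protein deformation, protein–DNA twist
and Z-DNA. The twelve 149-long positional profiles are concatenated
property-major into a 1788-dimensional vector, so each component is a
(property, position) pair: component `P4:pos73` is the bendability of
the dinucleotide starting at position 73. Position is retained
deliberately: nucleosomal DNA shows position-specific structure (the
~10-bp rotational periodicity of AA/TT/TA/GC dinucleotides), which a
composition-only representation would erase.

The per-dinucleotide values ship with the package
(`dinuc_property_table()`) as a fixed 16 × 12 table of dimensionless
normalized constants. Most values lie in [−1, 1], a few exceed 1
(bendability of TA is 2.37); the table is treated as canonical and is
never rescaled. `normalize_scale()` is provided for users adding their
own scale: it maps the 16 raw values affinely onto [−1, 1]
(min → −1, max → +1), is idempotent, invariant under positive affine
transforms of the input, and rejects constant scales, for which the
mapping is undefined. Sequences are read on the given strand only and
must be A/C/G/T; the strict policy rejects ambiguity codes with the
offending position named, and the scanner optionally skips and reports
windows overlapping them.

## The classifier

With training classes S⁺ (nucleosome, the first label level) and S⁻
(linker), the model estimates per class the mean vector μ and the
covariance C with the unbiased divisor N − 1, and scores a query ξ by

$$F(\xi; g) = (\xi - \mu_g)^\top C_g^{-1} (\xi - \mu_g) + \ln |C_g|,$$

assigning the class with the smaller score — quadratic discriminant
analysis with equal priors, which is exact for balanced designs. An
exact tie is assigned to the nucleosome class; this is an arbitrary
but documented and tested rule that only matters on a measure-zero
set. The margin F(S⁻) − F(S⁺) is reported as a raw, uncalibrated
confidence. An optional `-2 ln prior` term is available for unbalanced
applications but is off by default.

**Regularization.** During feature selection the subset dimension can
approach or exceed the class size, making the sample covariance
singular. `cd_fit()` accepts an explicit `ridge` (default 0, added to
the diagonal unconditionally) and, whenever the Cholesky factorization
of the (ridge-adjusted) covariance still fails or meets a near-zero
pivot, escalates an automatic fallback of `1e-6 · trace(C)/p`,
multiplied tenfold until the factorization succeeds; the total amount
applied is recorded per class in `ridge_used` and serialized with the
model, so a reloaded model rebuilds the identical precision matrix and
log-determinant. The log-determinant is computed from the Cholesky
factor (2 Σ ln R_ii), never via `det()`, for numerical stability; the
precision matrix via `chol2inv()`.

## Feature selection

Each feature u gets the F-score
$$F(u) = \frac{(\bar x^+_u - \bar x_u)^2 + (\bar x^-_u - \bar x_u)^2}
              {s^{2+}_u + s^{2-}_u},$$
with per-class variances using divisor n − 1; a feature constant
within both classes scores +∞ if the class means differ and 0
otherwise (degenerate rule, documented rather than an error, so that
perfectly separating indicator-like features sort first). Scores are
invariant to affine transforms of a feature and to sample order; ties
rank by ascending original index so the ranking is stable.

IFS then evaluates the nested subsets S₁ ⊂ S₂ ⊂ … along the ranking by
stratified k-fold cross-validation and keeps the smallest k attaining
the maximal overall success rate (parsimony tie-break). Two choices
here were genuinely open:

* **Fold reuse.** One stratified fold assignment is drawn from the run
  seed and shared by every subset size, so the IFS curve is comparable
  point to point; re-randomizing folds per k would confound subset
  size with split noise. This also means the exact location of the
  peak is fold-split dependent — a reproducibility caveat inherent to
  the procedure.
* **Grid.** Evaluating every one of 1788 subset sizes costs 1788 × k
  covariance fits up to 1788-D — hours, not minutes. The default
  evaluates every size; for large spaces a thinned `k_grid` (e.g.
  every 4th size) is supported, and `refine = TRUE` then fills in all
  sizes between the grid neighbours of the best grid point. A full
  sweep remains available by passing the full grid.

Evaluation pools miss counts over folds (micro-average) before
computing Sn = (N⁺ − miss⁺)/N⁺, Sp = (N⁻ − miss⁻)/N⁻ and
Acc = (N⁺·Sn + N⁻·Sp)/(N⁺ + N⁻); with balanced folds this differs
negligibly from averaging per-fold rates and matches the global
miss-count form of the definitions. Acc = 1 exactly when no sequence
of either class is mispredicted.

## Scanning

A model trained on 150-bp segments scans an arbitrary sequence of
length L ≥ 150 by classifying all L − 149 windows (step 1 bp, windows
numbered 1-based by start, so a 502-bp query has windows #1–#353) and
merging runs of equal labels into segment calls. The merge is lossless
— expanding the calls reproduces the per-window label vector — and no
additional smoothing is applied beyond run-merging. BED export maps
window w to the 0-based half-open interval [w−1, w+149) and a merged
segment to the span from its first window's start to its last window's
end.

## What the synthetic generators emulate — and what they do not

The package ships no genomic training data, so two seeded generators
make every stage testable:

* `gen_gaussian()` draws two multivariate normal classes with identity
  covariance and a known mean shift on a chosen feature subset, and
  returns the true parameters plus the closed-form Bayes success rate
  Φ(‖μ⁺ − μ⁻‖/2) — used for parameter-recovery and calibration tests.
* `gen_sequences()` writes a positive class with the favoured
  dinucleotides AA/TT/TA/GC planted at ~10-bp phase-locked periodic
  slots over an i.i.d. uniform background, at a rate `effect_size`,
  and a negative class with A/T homopolymer runs in the same slots.
  At `effect_size = 0` both classes are the identical uniform
  background (the null).

Defaults are 200 sequences per class, 150 bp, `effect_size = 1` — a
desk-scale, strongly separable analogue of a curated benchmark of
top- and bottom-scoring fragments. These generators are test fixtures,
not biological models: real nucleosomal DNA has phase jitter, GC
heterogeneity, correlated positional structure and far weaker class
separation, and real linkers are not defined by homopolymer runs.
Passing tests therefore demonstrate that the machinery (encoding,
discriminant, selection, evaluation, scanning) is correct and that the
pipeline detects a planted physicochemical periodicity; they do not
certify any particular accuracy on genomic data, for which users
should train on a curated nucleosome/linker benchmark of their
organism.

```{r example, eval = FALSE}
s  <- gen_sequences(n_per_class = 200, effect_size = 1, seed = 1)
ts <- read_training_set(s$positive, s$negative)
curve <- ifs(ts$x, ts$y, folds = 5, seed = 1,
             k_grid = c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512))
cross_validate(ts$x, ts$y, features = curve$optimal_set, k = 5, seed = 1)
```

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at 200
sequences per class with strided IFS grids (powers of two up to 512)
and 5-fold cross-validation, and the oracle-equivalence checks use 30
random instances of 2–20 features — sizes chosen so the whole suite
runs in minutes on a single core while still exercising the
ill-conditioned regime where the ridge fallback engages. Other fixed
choices: covariance symmetrized as (C + Cᵀ)/2 before factorization to
absorb floating-point drift; fold assignment drawn by per-class
shuffling with `rep_len(1:k)` so class counts differ by at most one
across folds; `which.max`/`which.min` tie behaviour (first index)
aligns with the documented parsimony and positive-class tie-breaks.

## Known limitations

* The discriminant models each class as a single Gaussian in feature
  space; multimodal nucleosome classes would violate this.
* Features are read on the forward strand only; no reverse-complement
  averaging is applied.
* The reported margin is not a calibrated probability.
* With selection performed on the full dataset before cross-validation
  (as in the IFS procedure), the curve's absolute heights carry
  selection bias; the shipped null checks (effect 0 → chance-level
  accuracy *without* selection) bound the machinery, not the
  procedure's optimism.
* The 16 × 12 property table is fixed; adding scales beyond the twelve
  or k-mer features beyond dinucleotides is out of scope.
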
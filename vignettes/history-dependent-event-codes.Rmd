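---
title: "Detecting history-dependent event codes with leave-one-event-out RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting history-dependent event codes with leave-one-event-out RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemarsa)
```

## The problem

When people watch structured, temporally extended events -- here, animated
wedding ceremonies from a fictional island whose rituals follow
context-dependent rules -- the brain can represent "where we are" in the
event in several qualitatively different ways:

* an **abstract schema code** (North vs. South culture) that is constant
  across all rituals of a wedding and cannot be reduced to any specific
  ritual or sequence;
* a **path code** for the specific ritual sequence; each schema owns two
  paths, so this is less abstract than the schema;
* a **current ritual code** for whatever ritual is on screen, history-
  agnostic by construction;
* a **rotated preceding ritual code**: a working-memory trace of the just-
  finished ritual that is *anticorrelated* ("photo-negative") with the
  pattern that was active while that ritual was being watched. Its
  signature in similarity space is *especially low* correlation between a
  stage pattern and the template of its true predecessor;
* its mirror image, a **non-rotated preceding/upcoming code**, defined as
  the exact sign flip of the rotated contrast.

The design that makes these separable is a non-Markovian transition graph:
six rituals over three analyzed stages, where the successor of a stage-2
ritual depends on the schema (under North, campfire is followed by coin;
under South, by torch). `enumerate_paths()` and `next_ritual()` encode
this graph; `make_schedule()` reproduces the learning-day (24 weddings,
blocked) and test-day (12 weddings, interleaved S,N,N,S,S,N,N,S,S,N,N,S)
designs.

## The RSA procedure

For every held-out wedding we average the remaining weddings' stage
patterns into 12 **templates** (6 rituals x 2 schemas) and correlate
(Pearson) each template with the held-out wedding's three stage patterns:
36 comparisons per held-out wedding, looped over all weddings
(`compare_all()`). Each comparison carries a label taxonomy
(`comparison_frame()`): within/across stage, a four-way path relation
(same path; different path, same schema; different schema with/without a
within-stage ritual match), same-preceding-ritual, and
predecessor/successor match flags. Predecessor/successor matching uses
ritual identity only and ignores schema: the carried trace is treated as a
sensory trace of the ritual, not of its context.

Each code is then a difference of mean similarities (`code_score()`):

* schema: same-schema minus different-schema over all 36 cells;
* path: same-path minus different-path-same-schema; different-schema
  cells are omitted, which makes the path predictor matrix orthogonal to
  the schema predictor matrix (asserted numerically in the tests);
* current ritual: within-stage same-ritual minus other-ritual;
* rotated preceding: the average of two across-stage mismatch-minus-match
  differences (stage-2 templates vs. held-out stage 3, and stage-3
  templates vs. held-out stage 2); stage-4 comparisons are excluded
  because stage 4 can carry residue from multiple preceding stages.
  Positive values mean the anticorrelated trace is present;
* non-rotated: the sign flip of the rotated contrast.

Similarities are averaged raw (no Fisher z): the statistic of interest is
a difference of means, and the leave-one-out design keeps cell counts
balanced, so per-record averaging and cell-averaging coincide; per-wedding
scores use each held-out wedding's own 36 records and therefore average
exactly to the participant score.

Group inference runs the contrasts in 5x5x5 cubic searchlights
(`run_searchlights()`; radius 2, 125 voxels when fully interior; centers
with fewer than `min_members = 63` in-mask members -- just over half a full
cube -- are dropped, a choice the source design left open). Per center we
take a one-sample, one-tailed t against zero across participants and
convert p-values to q-values with Benjamini-Hochberg FDR over all retained
centers (`group_map()`); zero-variance centers are excluded from the FDR
family rather than assigned p = 1 so the family size stays honest.
`conjunction()` marks centers significant for two codes;
`disjunction(primary, excluded)` marks centers significant for one code
while the other fails even a liberal uncorrected threshold (p > 0.1,
one-tailed -- the tail convention for the excluded map was unstated in the
source design, so we reuse the primary convention and expose it).

`paired_contrast_test()` reproduces the post-hoc battery: two-tailed
paired t, gated to a Wilcoxon signed-rank test when Shapiro-Wilk rejects
normality of the differences at 0.05, with Cohen's d or rank-biserial
effect sizes. `jzs_bf01()` computes JZS Bayes factors (Cauchy prior scale
0.707) by adaptive quadrature of the noncentral-t marginal likelihood over
the effect-size prior; the tests check it against an independent
Gauss-Legendre quadrature in a different parameterization.

## Brain-behavior link

Per-wedding code strengths in a significant region
(`per_wedding_strengths()`: the wedding-scope contrast per searchlight,
averaged unweighted over the region's centers -- pooling voxels instead is
available via `pool = "voxels"`, since the source design did not specify
the pooling) are correlated with per-wedding memory scores (correct minus
incorrect recalled details or rituals, `memory_scores()`) across weddings
within each participant (Spearman, average ranks), averaged across
participants, and tested against a null built by shuffling behavior
within participants 1000 times (`strength_permutation_test()`). The
one-tailed p counts null means **at or above** the observed mean -- the
conservative reading of "proportion above" -- with a `(k+1)/(n+1)` option.
Shuffles are drawn independently per participant because weddings within
a participant are the exchangeable units. Bayes factors for these
correlations use the Fisher-z transform (`fisherz_bf()`).

## What the synthetic generator emulates

`generate_patterns()` plants each code in its own region of a voxel grid
as an additive component with known amplitude: per participant, each
region gets orthonormal basis vectors (Gram-Schmidt on Gaussian draws),
so planted components have analytically computable overlaps; the pattern
of wedding w at stage s adds the schema vector (scaled by a per-wedding
amplitude `a_w = max(0, 1 + N(0, 0.5))`), the path vector, the current-
ritual vector, and -- at stages 3 and 4 -- minus the preceding ritual's
vector, plus i.i.d. Gaussian noise. Memory scores couple to `a_w` alone
(`generate_behavior()`), so the brain-behavior null is true by
construction for every code except the schema code.

Defaults state the simulated world once: 40 participants, the 12-wedding
interleaved schedule with paths balanced three per path (needed so every
template cell stays estimable under leave-one-out; the source design did
not state per-path counts), a 20^3 voxel grid with five disjoint 5^3
regions, amplitudes `beta = 8` against unit noise. Eight was chosen so the
per-voxel signal SD inside a 125-voxel region is about 0.7 of the noise
SD, putting single-searchlight pattern correlations around 0.3-0.5 and
giving a 10-participant desk-scale run decision power comparable to the
40-participant study; behavior coupling defaults
(`gamma_details = 2`, score noise 1) likewise follow the stated
simulation conditions. Patterns are generated directly at the stage level
-- one vector per ritual viewing, the granularity the analysis operates on
-- with no TR-level time series, no HRF, and no autocorrelated or
physiological noise; MNI geometry is out of scope. Scores are rounded to
integers (memory scores are counts), which introduces rank ties: the
latent behavior is an exact monotone transform of `a_w`, the observed
scores only a near-perfect one.

## Numerical choices

* Constant patterns raise errors rather than returning NA similarities: a
  constant vector in this pipeline signals an upstream masking bug.
* Template estimation is a plain arithmetic mean; Pearson correlation
  already centers and scales, so no voxel-wise normalization is applied.
* An empty contrast condition cell raises an error naming the cell; the
  balanced design guarantees non-emptiness, so emptiness implies a
  labeling bug.
* The fast searchlight path computes all 432 similarities per center with
  one matrix product and one correlation call; the tests pin it to the
  record-by-record reference path at 1e-12.
* NIfTI-1 I/O is a minimal built-in codec (no R NIfTI package is
  assumed); it is validated against nibabel in the tests and stores
  doubles losslessly.

## What a green test does and does not establish

The planted-code recovery tests show that each contrast detects its own
planted component, that background FDR behaves, and that the conjunction
separates the rotated+current region from the current-only region. Three
limitations are intrinsic to the contrast definitions and are left as
deliberately failing acceptance expectations rather than papered over:

1. **A rotated-only region is invisible to the rotated contrast.** The
   contrast correlates stage-2 *templates* with stage-3 patterns (and
   vice versa). If a region carries only the carried-forward trace and no
   ritual information during stage 2, its stage-2 templates are noise and
   the expected contrast is exactly zero. Detecting "rotated without
   current" in real data is therefore a statement about thresholds (a
   sub-threshold current code), not about a mathematically current-free
   region; the generator's region 5 makes this explicit.
2. **Exclusivity fails between codes that share comparison cells.** A
   pure path region necessarily produces positive schema and current-
   ritual contrasts (same-path cells are a subset of same-schema cells,
   and within-stage same-ritual cells coincide with same-path cells), and
   a pure ritual region produces a positive path contrast. With desk-
   scale amplitudes these leaks pass FDR.
3. **A path code is also a non-rotated carryover.** Same-path templates
   correlate with adjacent-stage patterns, which is exactly what the
   non-rotated preceding/upcoming contrast measures, so the "empty
   non-rotated map" expectation fails at the planted path region.
4. **Leave-one-out count asymmetry biases the rotated contrast.** The
   predecessor-matching template cell always contains the held-out
   wedding, so after holding out it averages one fewer wedding than the
   mismatching cell and is noisier. Wherever same-schema patterns
   correlate (i.e., wherever a schema code lives), the noisier match
   template yields slightly lower similarity, mimicking a small positive
   rotated score (about 0.01 against 0.10 in the genuinely rotated
   region in the default simulation). This artifact is a property of the
   contrast itself, not of the generator, and applies equally to real
   data analyzed this way.

Statistical calibration (one-tailed size, BH false-discovery control,
permutation-test size and power) is checked by simulation with
scaled-down replicate counts noted in the test file.
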
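---
title: "Methods: bilateral shape asymmetry and dental-formula variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral shape asymmetry and dental-formula variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archasym)
```

## The problem

Cyprinid fishes carry their functional dentition on the paired fifth
branchial (pharyngeal) arches. Two kinds of questions arise for a clonal
fish living across heterogeneous sites: does the **discrete** phenotype —
the dental formula, written `a,b–c,d` for the minor/major tooth rows of the
left and right hemi-arch — vary with the environment or at random; and does
the **continuous** phenotype, the 3D shape of the arch, show *directional
asymmetry* (DA: a consistent left–right difference, the signature of a
side-specific developmental program) or *fluctuating asymmetry* (FA: random
left–right noise, the signature of developmental instability)?

`archasym` implements the complete analysis chain for both questions:
dental-formula statistics (Simpson diversity, frequency tables, contingency
tests), geometric morphometrics for paired structures (generalised
Procrustes analysis, sliding semi-landmarks, tangent projection, matching
symmetry), the Procrustes-ANOVA decomposition of asymmetry with permutation
inference, and redundancy-analysis variance partitioning — plus a seeded
synthetic generator so every stage is testable without any external data.

## Landmark model

One side of the arch is a 33-point, 3D configuration: 7 fixed landmarks and
two chains of 13 sliding semi-landmarks each, the outer ridge anchored at
fixed landmarks 4 and 18 and the inner (tooth-bearing) curve at 19 and 33.
The scheme is data, not code: `landmark_scheme()` accepts any point count,
dimension, fixed set and chain structure, under the invariants that fixed
and semi-landmark indices are disjoint, jointly cover all points, and chain
anchors are fixed landmarks. All indices are 1-based at every interface.
The anatomical meaning of individual landmarks is deliberately not
hard-coded.

## Superimposition

`gpa()` performs full generalised Procrustes analysis: every configuration
is centred, scaled to unit centroid size, and rotated (proper rotations
only — the SVD solution with determinant correction) onto the running
consensus; the consensus is the arithmetic mean of the superimposed
coordinates, re-standardised, iterated to a fixed point (default tolerance
`1e-6` on the consensus RMS change, at most 100 iterations; non-convergence
is an error carrying the last residual). Scaling is included because the
downstream matching-symmetry decomposition assumes size-free shape
variables. Reflections are never absorbed by the superimposition:
mirroring is an explicit, controlled operation (`reflect_side()`).

Two numerical choices matter here:

* **Canonical orientation.** After convergence the whole solution is
  rotated so the consensus lies along its principal axes, each axis signed
  so its largest-magnitude coordinate is positive. The construction is
  equivariant under rotations of the inputs, which makes GPA output
  strictly invariant (to machine precision) to the pose, scale and ordering
  of any input configuration — a property the test suite asserts at `1e-8`.
* **Reported deviation.** `$rss` is the summed squared deviation from the
  *arithmetic mean* of the superimposed coordinates (the quantity GPA
  minimises); the stored `$consensus` is that mean re-standardised to unit
  size.

## Sliding semi-landmarks

Semi-landmark positions along an outline are arbitrary; `slide_semilandmarks()`
removes that arbitrariness by the minimum bending-energy criterion. The
bending-energy matrix is the upper-left block of the inverted thin-plate-
spline system on the current consensus, with kernel `U(r) = r^2 log r` in 2D
and `U(r) = -r` in 3D (this sign convention yields a positive-semidefinite
matrix directly; energies are reported as absolute quadratic forms). The
matrix annihilates affine displacement fields exactly, which the tests
verify on random affine fields.

Each configuration's semi-landmarks are displaced only along their
estimated curve tangents — central differences over the chain neighbours,
anchors included, so every semi-landmark has two neighbours and no
one-sided case arises — and the tangent-direction coefficients solve the
resulting quadratic programme in closed form (a tiny ridge, `1e-10` of the
diagonal scale, guards rank-deficient tangent systems). Fixed landmarks
never move. Slide and re-superimposition alternate for at most 5 cycles or
until the total bending energy changes by less than `1e-6` relative;
within each cycle the slide step cannot increase the energy measured
against that cycle's consensus (asserted by the tests), while the
subsequent consensus update may move the target slightly.

`project_to_tangent()` flattens each superimposed configuration and removes
the component along the consensus vector — the orthogonal projection onto
the tangent space at the consensus. The consensus maps to zero, the
projection is idempotent, and for the small shape distances typical of this
design the tangent-space distance agrees with the Procrustes distance to
well under 1%.

## Matching symmetry and the asymmetry ANOVA

For paired structures the analysis uses *matching* symmetry: every right
configuration is reflected (`x -> -x`), so landmarks correspond
side-to-side, then left and reflected-right configurations are jointly
superimposed, slid against the joint consensus, and projected. The paper's
workflow leaves two details open, resolved here as defaults: sliding uses
the joint consensus of both sides (not per-side consensuses), and the
second superimposition re-slides semi-landmarks (`slide = TRUE`,
configurable).

`procrustes_anova()` decomposes the summed squared tangent-space deviations
of the balanced `individual x side` design with replicate digitising
sessions into Individual, Side (DA), Individual x Side (FA) and Measurement
error. Degrees of freedom follow the **design** (34/1/34/70 for 35
individuals x 2 sides x 2 sessions), not the design multiplied by the
shape-space dimension; mean squares are SS/df on that scale, which leaves
every F ratio unchanged and matches how such tables are conventionally
printed. Error terms follow the mixed-model logic: DA is tested against
the individual x side interaction, FA against measurement error, and the
individual effect against the interaction.

Permutation inference (default 999 permutations,
`P = (count >= observed + 1)/(n_perm + 1)`) permutes the exchangeable units
of each term: whole observations for the individual term, side labels
within individual for DA, and residuals of the additive (no-interaction)
model for FA. With `n_perm = 0` only the deterministic table is computed —
useful inside Monte-Carlo loops.

`variance_components()` inverts the expected mean squares of the balanced
design: with `q` shape variables, `r` sessions and `b = 2` sides,
`E(MS_err) = q s2_me`, `E(MS_int) = q (s2_me + r s2_fa)`,
`E(MS_ind) = q (s2_me + r s2_fa + b r s2_ind)`. The tests recover known
components within 10% (500 simulations at n = 50) by feeding the ANOVA
draws from this model directly; running the recovery through GPA first
would rescale every component by centroid size and the 7 degrees of freedom
the similarity projection removes, making "truth" ill-defined.

## Per-landmark asymmetry

The per-landmark left–right test is not fully specified in the source
workflow; the construction adopted here is documented as a design choice.
For landmark j the response is the session-averaged aligned coordinate
triple of every (individual, side) pair; a partial RDA of that response on
side, conditioned on site, gives the semipartial adjusted R² (difference of
Ezekiel-adjusted terms), and the permutation null **flips side labels
within individuals** rather than freely permuting rows — rows of the same
individual are correlated, so free permutation would violate
exchangeability. Raw and Benjamini–Hochberg-adjusted p-values are both
reported (the published analysis reported raw values only; its `P < 0.043`
significance remark is treated as a property of that dataset, not a
package constant — alpha defaults to 0.05). With a single site the test
degrades to the uncontrolled version and carries a warning record.

## Ordination statistics

`rda()` is multivariate least squares of the column-centred response on
the centred dummy-coded constraint; R² is the fitted fraction of the total
sum of squares, adjusted by the Ezekiel formula
`1 - (1 - R²)(n - 1)/(n - p - 1)` (negative values are legitimate and do
occur). `partial_rda()` reports the semipartial fraction
`R²(X+Z) − R²(Z)`, adjusted as the difference of Ezekiel-adjusted terms
(Peres-Neto convention), with Freedman–Lane permutation of the
conditioning-model residuals. `variance_partition()` composes the standard
two-factor partition; on the unadjusted scale the four fractions sum to one
exactly, and the shared fraction is reported without a p-value because it
is not permutable. The test suite cross-checks all fractions against
`vegan::varpart` and against explicit hat-matrix algebra.

`trajectory_analysis()` compares group contrasts as two-point trajectories
— the study compares static biotype differences, so only the magnitude
(norm of the mean-difference vector) and direction (pairwise angle between
difference vectors) attributes are implemented. Nulls reshuffle group
labels; when the number of distinct label assignments does not exceed
`n_perm` the null is enumerated completely and the p-values are exact
(the tests verify this against an independent enumeration). Homogeneous-
subset letters come from single-linkage grouping of non-significant
comparisons at alpha (default 0.05).

## Dental-formula statistics

`simpson_diversity()` fixes the variant `D = 1 - sum(p_i^2)` because it
reproduces every published per-lineage and per-biotype value to 4 decimals
from the printed counts; the finite-sample variant is available behind
`unbiased = TRUE`. `parse_formula()` accepts hyphen, en- and em-dash
separators and canonicalises to the en-dash. `chisq_2x2()` applies no
continuity correction by default — the published comparison value
reproduces only without it. The bundled hybrid count table totals 152
individuals while the survey text says 153; `dental_survey_counts(validate
= TRUE)` surfaces the discrepancy as a warning instead of silently
resolving it, and the 152-total table is used because it reproduces the
published pooled diversity.

## The synthetic generator

`simulate_shapes()` draws from the hierarchical model the asymmetry ANOVA
assumes: shape = crescent template + site shift + individual deviation; the
left side adds the directional offset (for everyone, or only
alternative-formula individuals under `coupling`) and an individual x side
deviation; the right side is the mirrored shape with its own deviation;
each digitising session adds independent error. All deviations are
isotropic Gaussian per coordinate (the source gives no noise model;
heavier-tailed options were deliberately deferred), and site effects are
applied in shape space *before* superimposition so the pipeline must
recover them through GPA, mimicking real data flow.

Defaults are the study conditions: 33-point scheme, 2 sessions,
`sigma_ind = 0.02`, `sigma_me = 0.002` in raw template units (template
centroid size about 5.6), and `sigma_fa = 5e-4` with a DA offset of
`0.0012` on 11 inner-margin landmarks — the last two calibrated once so
the FA and DA tests have roughly 0.8 power at 35 individuals, the size of
the largest single-group analysis this design emulates.
`study_mimic_dataset()` reproduces the design dimensions of the shape
study: 66 clonal individuals over 7 sites with site-dependent
alternative-formula frequencies (0.3–0.9), the offset coupled to the
alternative formula, 2 sides, 2 sessions.

What the generator does *not* emulate: digitising error correlated along
outlines, allometry, non-Gaussian tails, site effects confounded with true
asymmetry, or any tooth geometry. Passing tests therefore demonstrate that
the machinery recovers the structure it assumes — not that real arches
satisfy those assumptions.

## Test design and problem sizes

Monte-Carlo checks use sizes chosen to keep the default suite fast while
leaving the statistics meaningful: null-calibration and p-uniformity loops
run 200 simulations at 10 individuals on reduced schemes with 99
permutations; uniformity is judged against the 99% Kolmogorov band
`1.628/sqrt(200)` (the package's stated convention); variance-component
recovery averages 500 draws at n = 50; the directional-offset recovery
check runs one simulation at n = 200 on the full 33-point scheme and
requires vector cosine > 0.95. Oracles are independent of the code paths
they check: brute-force rotation searches, explicit hat-matrix and
block-inverse assemblies, dense line searches, and exhaustive label
enumeration.

## Known limitations

* Only matching symmetry is implemented — object symmetry (a midplane
  within one configuration) is out of scope.
* Balanced designs only, as in the emulated study; unbalanced data are
  rejected, not approximated.
* Procrustes ANOVA supports the two crossed designs the workflow needs
  (individual x side with sessions; individual x session), not arbitrary
  factorial models.
* The pipeline's analysis-group construction (biotype x formula class)
  assumes the metadata carry those columns; degenerate groupings fall back
  to whatever factor is informative and are recorded in the run log.
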
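---
title: "Predicting diastereomeric salt resolutions: models and methods"
author: "chirsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting diastereomeric salt resolutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chirsep)
```

# The problem

Diastereomeric salt crystallisation is the workhorse technique for
separating the enantiomers of a racemic acid or base at manufacturing
scale: an enantiopure resolving agent forms two diastereomeric salts with
the two enantiomers, and if one salt is sufficiently less soluble, it
crystallises enantio-enriched. Which resolving agent (and solvent) works
for which racemate is notoriously hard to predict, so screens are run by
trial and error with hit rates of a few percent. `chirsep` implements a
physics-based machine-learning pipeline that ranks racemate x agent x
solvent conditions by their predicted probability of success.

Each experiment is summarised by two figures of merit: the solid mass
fraction `m.frac = m_solid / m_initial` and the enantiomeric excess of the
solid `e.e. = |chi_R - chi_S|`, combined into `z = m.frac * e.e.`
(`z = 0.5` is the ideal resolution of a racemic feed: half of the material
crystallises, enantiopure). Retrospective success is defined as
`m.frac > 20%` and `e.e. > 25%`; records with `m.frac < 20%` carry highly
uncertain labels and form the complement of the "low-noise" subset.
Records whose `e.e.` exceeds the maximum attainable value for their mass
fraction (1 below `m.frac = 0.5`, `(1 - m.frac)/m.frac` above, assuming a
racemic feed) by more than a 5% experimental-error band are physically
inconsistent and are filtered out (`validateRecord()`).

# Representation

## Weighted atom densities

The central object is the acid-base *pair*, not the isolated molecules:
chirality only becomes observable in the interaction between the substrate
enantiomer and the enantiopure agent. For each complex we compute per-atom
radial density profiles on a grid of 160 radii from 0.7 to 8 Angstrom,

* two-body: `A2(i; w)(r) = sum_{j != i} w_ij G_ij(r)`,
* three-body: `A3(i; w, phi)(r) = sum_{j,k != i, j != k} w_ij w_ik w_jk
  G_ij(r) phi(theta_ijk)`,

where `G_ij` is a normal density of width `sigma = 0.0825` Angstrom centred
at the interatomic distance `d_ij`, and `phi` is the cosine or sine of the
angle at the central atom `i` between the bonds to `j` and `k`. Seven
weighting channels inject electronic structure: sigma/pi/delta orbital
overlaps (short-ranged, decaying exponentially with distance), the charge
product `q_i q_j`, and s/p/d orbital-population products (long-ranged).
With seven A1 identity features (nuclear charge, group, period, partial
charge, s/p/d populations) the per-atom vector has
`7 + 7*160 + 14*160 = 3367` entries. Only non-hydrogen atoms are centres;
hydrogens count as neighbours by default (they carry partial charge),
switchable via `includeHydrogens`.

Numerical choices worth stating:

* The double sum in A3 runs over ordered pairs `(j, k)` with `j != k`
  (the angle of an atom with itself is degenerate); the sum is symmetric,
  so each unordered pair contributes twice.
* "Angle" means the angle at the central atom; its sine is non-negative,
  so the representation is invariant under reflections as well as
  rotations and translations. Chirality information therefore only enters
  at the *pair* level (below), exactly as the physics dictates.
* Profiles are point-evaluated at the bin centres; the cutoff at 8
  Angstrom is hard, with no switching function — at `sigma = 0.0825`
  Angstrom the Gaussian tail at the last bins makes the discontinuity
  numerically negligible.
* The charge and population channels are distance-independent and exist to
  carry long-range information; by default they still honour the 8
  Angstrom neighbour cutoff (the conservative reading), with
  `longRangeUnbounded = TRUE` lifting the cutoff for exactly those
  channels.
* Trajectory aggregation concatenates the per-atom mean and standard
  deviation over frames (population convention, dividing by the number of
  frames), giving 6734 values per atom. The variance accumulates relative
  to the first frame, so entries that never move — the static A1 integer
  fields, or identical frames — get an exactly zero standard deviation.

## Electronic weights

The weighting channels of a production run come from a semi-empirical
calculation. The package keeps that backend *pluggable*: a
`WeightProvider` maps a geometry to the A1 features and the seven channel
matrices. Two providers ship:

* `surrogateProvider()` — fully deterministic, geometry-only:
  electronegativity-equalisation charges (summing to zero over the neutral
  complex; molecules are treated as neutral throughout), neutral valence
  configurations charge-adjusted for the populations, and overlaps
  `eps* = s*_i s*_j exp(-(d_ij - r_i - r_j)/lambda)` with per-element
  sigma/pi/delta capacities and `lambda = 0.5` Angstrom (the
  covalent-overlap length scale; configurable). The supported element set
  is H, C, N, O, F, P, S, Cl, Br, I; none has d valence, so all delta
  channels vanish.
* `externalProviderAdapter()` — parses a plain-text exchange file of
  charges, populations and overlap triplets produced by an external
  converter from a semi-empirical run. The library never executes
  external codes. Which quantities of such a run best represent the
  sigma/pi/delta overlaps is a choice the converter makes; the adapter
  only documents its file contract (symmetrised triplets, one geometry
  per complex, applied to every frame).

The pair-weight combination rule for the population channels is the
product `p*_i p*_j`, mirroring the defining product of the charge channel.

## Conformer ensembles

Production trajectories come from MD of the contact pair (warm-up to
500 K, Langevin sampling, 200 snapshots; the protocol constants are
recorded in `trajectoryProtocol()`). Running MD is out of scope here:
trajectory generation is pluggable behind the `FrameSet` interface, and
the test backend is a *jitter sampler* (`jitterEnsemble()`): seeded
Gaussian per-atom displacements plus a random rigid re-orientation of the
agent, re-posed so the closest intermolecular contact stays within a
configured band (default 1.8-2.6 Angstrom, emulating the contact
restraint). `makePairFrames()` draws one set of perturbations per frame
and applies it to the R complex directly and to the S complex through the
mirror (reflected displacements, reflection-conjugated rotation), so that
an achiral, mirror-plane agent yields S frames that are *exact* mirror
images of the R frames. What the jitter sampler does **not** emulate:
Boltzmann weighting, conformational transitions, intramolecular torsions,
solvent. Tests that pass on jittered ensembles therefore validate the
pipeline's mechanics and chirality logic, not the physical realism of any
particular MD protocol.

# Pair assembly

Per-atom trajectory vectors are compressed from 6734 to 20 dimensions.
The default compressor is a symmetric two-hidden-layer autoencoder
(ReLU hidden units, linear latent and output, Adam on squared
reconstruction error); `kind = "pca"` selects an exact dual-form PCA
projection instead. Inputs are standardised column-wise first — the raw
blocks (nuclear charges vs. density tails) differ by orders of magnitude.
The full 6734-vector is compressed, A1 included. Compressors are trained
*per split on training atoms only*; the `fingerprint` slot records the
training matrix so fold leakage is detectable.

For a pair, the two compressed token matrices (tokens = heavy atoms of
the complex, substrate first, identical ordering across the pair — the
generator enforces this by construction, external data must supply it)
are combined into a *mean stream* `(z_R + z_S)/2` and a *diff stream*
`|z_R - z_S|`. The absolute difference makes the input
enantiomer-label-free: swapping R and S changes nothing, and the diff
stream vanishes exactly when the two complexes are isometric (achiral
agent) — the chirality signal lives there. Solvents enter as descriptor
vectors (physical properties plus surface-charge-profile bins, consumed
from a table); mixtures are molar-fraction weighted sums of the pure
descriptors.

# Model

`DualStreamModel` processes the two streams with parameter-independent
transformer stacks (defaults: 2 pre-norm blocks per stream, 4 heads,
token width 64, feedforward 128, dropout 0.1 — all in `modelConfig()`;
systematic hyperparameter search is out of scope, these are conventional
small-transformer values). No positional encoding is used, so the output
is invariant under a consistent permutation of the atom tokens. Pooling
is cross-attention with the embedded solvent vector as the single query
over the concatenated processed tokens of both streams (an alternative
reading — solvent as an extra token — was considered and rejected as the
default because it dilutes the solvent's conditioning role into
self-attention; the cross-attention form makes the solvent a pure
query). A two-layer feedforward head maps the pooled vector to the
outputs.

The forward and backward passes are plain double-precision matrix
algebra written in R; analytic gradients are verified against finite
differences in the test suite, and a fixed seed gives bit-for-bit
reproducible single-threaded runs.

# Training

Two stages:

1. **Regression pre-training** on *all* training records, including the
   high-uncertainty low-mass subset, with squared error on the targets.
   The default target is the pair `(m.frac, e.e.)`; a single-target `z`
   variant is available (`stage1Target = "z"`) since either reading is
   defensible. 10% of the training *racemates* are carved out for early
   stopping, so the validation split never crosses a racemate.
2. **Classification fine-tuning** on the low-noise subset
   (`m.frac >= 20%`): the head is re-initialised as a classifier and
   everything else is frozen. Because the backbone is frozen, its pooled
   outputs are precomputed once and only the head is optimised — exactly
   equivalent, and the non-head parameters stay bit-identical (asserted
   via a parameter fingerprint). Batches are drawn by weighted sampling
   with equal expected class proportions; fine-tuning errors out if the
   subset is single-class.

Evaluation uses racemate-grouped k-fold plans (`groupKFold()`): racemates
are shuffled by seed and greedily assigned to the fold with the fewest
records, so no racemate ever spans folds. Ranking quality is measured by
the enrichment factor `EF(n) = hits_top_n / (n H / N)` (1 = random,
`EF(N) = 1` by construction) and by average precision; ties break by
stable record order. Ensembles average member probabilities and report
the member spread. `rankAgents()` scores an agent by its maximum
probability across solvent systems, the selection rule used when
designing a prospective screen.

# The synthetic study

`generateDataset()` emulates the structure of a historical resolution
screen: a full racemate x agent x solvent grid over toy tetrahedral
complexes (four distinct substituents around a stereocentre; agents carry
a carboxyl fragment, substrates an amine). Defaults are chosen once as
the study conditions:

* complexes at the small end (~12-14 heavy atoms) of the 12-72 heavy-atom
  range seen in real screening data;
* 16 jitter frames per complex — the sampler draws i.i.d. displacements,
  whose mean/std statistics converge quickly, unlike correlated MD
  trajectories that need hundreds of snapshots;
* base hit rate 3% with 2% label noise, and a 64/36 split of failure
  modes (low mass vs. low e.e.), which together put the hit rate inside
  the low-noise subset near 8% — both rates mirror historical screens and
  were fixed by closed-form arithmetic, not fitted;
* planted signal: hit probability
  `plogis(4 * proj + 0.5 * solvproj + b)`, where `proj` is the
  standardised projection of the pair's mean diff-stream vector (under an
  internal PCA) onto a random unit direction, and `b` is calibrated so the
  post-noise hit rate equals the target. Planting the signal in
  *compressed-diff space* means nothing short of the full pipeline
  (featurize, compress, pair, attend) can recover it — end-to-end
  coverage by construction.

Figures of merit are drawn consistently with the final label, so every
generated hit satisfies the retrospective thresholds, every non-hit
violates at least one, and all records respect the maximum-e.e. band.

The packaged acceptance checks run this study at 30 racemates x 20
agents x 2 solvents (1200 records), train a 3-member two-stage ensemble
on four folds of the grouped 5-fold plan and evaluate on the held-out
fold's low-noise subset; the learning-curve check reuses the same grid
with nested training fractions 0.25/0.5/1.0 and 3-member ensembles.
Stage-1 runs 300 Adam steps at batch size 16 — enough to overfit small
fixtures and to converge on this problem size. These sizes are the
package's chosen study scale; the same functions run unchanged at larger
scale.

# Attention vs. crystal contacts

For interpretation, `findContacts()` extracts heavy-atom pairs within
3.5 Angstrom of a (single asymmetric unit) crystal geometry — symmetry
images are out of scope — and `headStats()` compares, per stream, block
and head, the mean symmetrised attention `(A + t(A))/2` over contact
pairs vs. non-contact pairs, each as a ratio to the uniform baseline
`1/T`. Both streams are reported separately. Since representations are
trajectory-level, each pair has a single attention matrix — there is no
frame averaging. A uniform matrix gives ratios of exactly 1; untrained
models give ratios near 1 on average over seeds (a null check that any
neighbour preference is a *trained* effect). Whether attention equals
interaction energy is deliberately not claimed.

# Known limitations

* The surrogate electronic weights are a deterministic stand-in with the
  right symmetries and ranges, not a semi-empirical calculation; absolute
  channel values differ from a production backend.
* The jitter sampler explores no torsional space; diff-stream magnitudes
  on real conformer ensembles will be larger and noisier.
* The toy complexes sit at the small end of the realistic size range;
  token counts (and attention maps) are correspondingly small.
* Training is CPU-bound R matrix code: fine at the packaged study scale,
  not intended for datasets orders of magnitude larger.
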
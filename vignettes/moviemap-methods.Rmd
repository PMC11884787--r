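---
title: "Movie-evoked visual-cortex organization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movie-evoked visual-cortex organization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moviemap)
```

## The scientific question

Can the organization of visual cortex be read out from movie-watching fMRI
alone, without a controlled retinotopy task? `moviemap` implements three
complementary answers and the statistics behind them:

1. **Homotopy.** If visual areas are functionally distinct units, the time
   course of a visual area during a movie should resemble its mirror-image
   (homotopic) partner in the opposite hemisphere more than any other area,
   with similarity falling off along the visual hierarchy and across the
   dorsal/ventral streams.
2. **Spatial ICA.** If within-area retinotopic maps shape movie responses,
   a blind spatial decomposition of the movie data should contain components
   that look like spatial-frequency (eccentricity-like) and meridian maps,
   and those components should match task-derived ground truth better than
   the other components.
3. **Shared response modeling (SRM).** If movie responses occupy a
   low-dimensional space shared across people, a held-out participant's
   retinotopic maps should be predictable by carrying the group's maps
   through that shared space — functional alignment without anatomy.

Every analysis is validated end to end against a synthetic cortical sheet
whose ground truth is known by construction.

## The synthetic cortex

`build_cortical_sheet()` lays out eight retinotopic areas (V1v/V1d, V2v/V2d,
V3v/V3d, hV4, V3A-B) as contiguous bands on a square 32 x 32 grid per
hemisphere, mirrored across hemispheres. Eccentricity runs foveal to
peripheral along one axis (normalized 0 to 1); area identity changes along
the other, dorsal areas on top. Band heights are deliberately unequal
(5,4,4,3,3,4,4,5 rows from V3A-B to hV4) so that no rigid half-grid motion of
the sheet maps area boundaries onto area boundaries; V1 being smaller than
V3A-B/hV4 is a departure from anatomy that no analysis here is sensitive to.
The grid is square because the rolled-component null (below) exchanges the
two grid axes.

`generate_ground_truth_maps()` defines the two maps the analyses hunt for:

* **spatial frequency** = `cos(pi * ecc)`, strictly decreasing from fovea to
  periphery along any line parallel to the area boundaries;
* **meridian** = `cos(2 * polar)`, whose sign alternates at every area
  boundary by the sheet's polar-angle layout.

Both are lightly smoothed within area bands, which preserves the
monotonicity, sign-alternation and exact mirror-symmetry invariants.
`trace_gradient_lines()` provides the measurement paths: every row of every
area as a foveal-to-peripheral *parallel* line, and *perpendicular* lines
crossing V1 to V3A-B and V1 to hV4 at two eccentricities.

### The generative model of a recording

`simulate_movie_responses()` builds each participant's units x time matrix as

    X_i = L_i S + noise + motion,  then z-scored per movie per unit,

with one shared latent time course `S` (k = 10 features) per movie, identical
for every participant watching it. The loading matrix `L_i` mixes three
ingredients:

* **Area signatures** shared across hemispheres, giving every area a latent
  fingerprint. Signatures are constructed with an exact target Gram matrix
  (within-stream similarity 1, 0.85, 0.70, 0.60 at hierarchy distance
  0-3; same-level cross-stream 0.62), realizable exactly because k exceeds
  the number of areas. This builds the homotopy ordering — same area above
  adjacent above distal, same stream above cross stream — into the expected
  correlation structure rather than leaving it to sampling luck.
* **The two ground-truth maps** on two dedicated latent features, scaled so
  they carry a `map_coupling` fraction of loading variance (default 0.5).
  No study quantifies how strongly retinotopy shapes movie responses, so
  this coupling is a free, swept parameter rather than a calibrated one.
* **Participant-specific smooth fields**, drawn independently per
  hemisphere, which keep homotopic correlations below 1 and give ICA
  non-map structure to reject.

Two numerical choices deserve explanation because naive versions fail:

**Latent spectrum and time reversal.** The latents are smooth AR(2) draws
low-passed at 0.3 of the Nyquist frequency and then *parity-balanced*: the
even and odd parts of the draws (about the movie midpoint) are
orthonormalized separately and paired, so the time-reversed latent subspace
is exactly orthogonal to the latent subspace. The flipped-time baseline
assumes that a reversed recording shares no stimulus-locked structure with
the model; long broadband recordings satisfy this approximately, but a short
strongly low-passed movie does not (with only a handful of temporal modes, a
reversed series still lies close to the latent span and the "null" model
recovers the maps). The parity construction enforces the property exactly at
desk scale. Analyses that do not involve time reversal are insensitive to
this choice.

**Noise scale.** Unit noise is five times the shared-signal standard
deviation at `snr = 1`; `snr` is therefore an *area-level* signal-to-noise
knob (averaging the ~130 units of an area recovers a factor ~11, putting
area-level signal-to-noise near 2.3 at `snr = 1`, and homotopic area
correlations near 0.85-0.9). Per-unit signal-to-noise far below 1 is
characteristic of voxel data and is also what makes the flipped baseline a
null: with clean units, even a misfit basis locks onto the spatial loading
span, whose gradient profile is dominated by the planted map.

The motion confound is a fast, spiky time course (unlike the slow stimulus
drive, so that a motion regressor is nearly orthogonal to signal) times a
near-global positive spatial pattern; it adds correlated variance to every
area and is what `partial_corr()` must remove. The hemodynamic delay is an
integer-TR crop of the stimulus stream. A master seed fans out to every
stage and participant through a counter scheme (`child_seed()`), making the
full cohort bit-reproducible.

`sim_config(structure = "smooth_noise")` produces a null cohort whose
loadings are mirrored smooth fields only — spatially smooth and bilaterally
symmetric, with no area- or map-aligned structure — used to show that map
selection finds nothing when there is nothing to find.

## Homotopy analysis

`run_homotopy()` averages unit time courses within area
(`extract_area_timecourses()`), correlates every left area against every
right area (`cross_hemisphere_matrix()`; the matrix is deliberately not
symmetric), and groups the cells (`homotopy_contrasts()`) into same area /
same stream, same level / cross stream, adjacent within stream (hierarchy
distance 1) and distal within stream (distance 2 or more), with hierarchy
V1 < V2 < V3 < {hV4, V3A-B}. Both asymmetric cells of each heterotopic pair
enter their group. All averaging and differencing happens on Fisher-Z
values; displayed group means are transformed back to correlations.
Correlations are clipped at `1 - 1e-7` before the Fisher transform so the
unit diagonal stays finite; diagonal self-comparisons never reach the
contrasts.

Group inference uses the percentile bootstrap over participants
(`bootstrap_mean_difference()`): resample participants with replacement,
compute the mean contrast per pseudosample, and report twice the fraction of
pseudosample means whose sign opposes the observed mean, capped at 1. A zero
flip count is reported as `< 2/n_boot`; an observed mean of exactly zero is
flagged degenerate with p = 1 rather than guessed around. The 95% interval
is the raw 2.5/97.5 percentile interval, with no bias correction. This
estimator is mildly anti-conservative at small cohort sizes (its measured
type-I rate at a nominal 0.05 is about 0.07 for 15 participants), a known
property of sign-flip percentile bootstraps; it is retained because it is
the procedure the analyses are defined around, and the calibration test in
the suite checks consistency with the nominal level at the resolution 200
replicates affords.

`mds_of_group_matrix()` averages the matrices across participants, treats
each area's correlation profile as its feature vector, and embeds the
between-area Euclidean distances in 2-D by metric MDS. The MDS engine
(`mds_embed()`) is SMACOF-style stress majorization: best of 8 restarts (the
first from classical scaling, the rest seeded Gaussian configurations), 300
Guttman iterations, relative convergence 1e-9, reporting Kruskal stress-1
(conventionally acceptable below 0.2). A mean silhouette of the
dorsal/ventral labels in feature-distance space summarizes stream
separation.

## ICA map discovery

`spatial_ica()` re-implements spatial fixed-point ICA: the timepoint
dimension is PCA-whitened to `n_components` (or the smallest rank retaining
90% variance, bounded to [20, 170]), then rotated by fixed-point iteration
with the logcosh contrast and symmetric decorrelation, treating cortical
units as samples. Components are sign-arbitrary spatial maps with attached
time courses, ordered by explained variance; decomposition is deterministic
given the seed, and a non-converged fixed point returns the best iterate
with a flag.

Candidate maps are selected by a programmatic surrogate for visual
inspection (`auto_select_candidates()`), scoring each component on energy in
labeled cortex, left/right mirror symmetry, gradient monotonicity along
parallel lines (Spearman |rho| of the averaged profile), and the fraction of
area boundaries at which the perpendicular profile changes sign. Criteria
are computed on a lightly smoothed copy of the map — inspection judges
pattern-scale structure, not unit noise. Two amplitude guards accompany the
rank-based criteria, which are scale-free and would otherwise accept
near-flat profiles with tiny drifts: the profile must carry at least 20% of
the map's spread, and a spatial-frequency candidate's profile must be
*gradual* (at least 68% of successive steps in one direction), which
separates continuous gradients from staircases of discrete plateaus.
Thresholds live in configuration; the defaults were calibrated so that
mirrored smooth-noise components are selected at well under a 10% rate.
Meridian components are harder to recover than spatial-frequency components
at realistic noise — their stripes are finer than the smoothing scale and
their structure overlaps the area-band signatures — so meridian selections
are rarer and recovery claims in the test suite are correspondingly weaker.

Validation against ground truth is by gradient profiles:
`sample_gradient_profile()` reads a map along the traced lines and averages
position-wise, `score_component()` correlates component and truth profiles
(absolute value, since ICA signs are arbitrary), and
`rank_component_percentile()` converts the selected components' rank among
all components into a percentile (best = 100, chance = 50, ties share mean
rank, multiple selections averaged).

The specificity null (`make_rolled_component()`) transplants each
hemisphere's values onto the other hemisphere's grid *at a transposed
anchor*: the grid axes are exchanged in the transplant. On a square grid
this is an exact isometry and an involution — smoothness is perfectly
preserved, value histograms are untouched — yet the eccentricity gradient
lands on the area axis and the meridian stripes land on columns, so both
map types are decisively misaligned with the anatomy. A purely
translational roll would not work here: the meridian is a periodic stripe
pattern whose period divides the half-grid shift, so translated copies
re-phase onto the area bands. `rolled_null_experiment()` intermixes original
and rolled components under shuffled identities, selects blind, and tests
the original fraction against chance with the exact two-tailed binomial
test (doubling rule, capped at 1).

## Shared response modeling

`fit_srm()` is the deterministic SRM: minimize `sum_i ||X_i - W_i S||^2`
over per-participant orthonormal bases and a shared k x T time course by
alternating orthogonal Procrustes updates of each `W_i` with averaging of
the back-projected data, initialized from QR decompositions of seeded
Gaussian matrices (max 50 iterations, relative tolerance 1e-9). The
objective is recorded every iteration and is non-increasing by construction;
every basis is orthonormal to 1e-8 by construction. k defaults to 10, and
`select_k_crossval()` reproduces that choice by participant-wise
cross-validation with held-out time halves when given a grid.

Map transfer mirrors the frozen-model protocol: fit the SRM on training
participants, transform their ground-truth maps into the shared space
through their bases and average (`transform_map_to_shared()`), fit only the
held-out participant's basis against the frozen shared time course
(`fit_new_participant()`, a single Procrustes solve), and carry the group
map back through the inverse of that mapping (`predict_map()`; the inverse
of an orthonormal analysis map is exactly its transpose). Predictions are
scored by *signed* gradient correlation — unlike ICA there is no sign
ambiguity, and negative transfer is meaningful.

Two baselines bound the result: `flipped_baseline()` reverses each movie in
time (no stimulus-locked mapping can be learned; with the parity-balanced
latents the reversed data are exactly orthogonal to the true shared
course), and `anatomical_average_baseline()` averages the other
participants' maps on the common grid, emulating template-space anatomical
alignment. On a synthetic cohort whose sheets are exactly aligned the
anatomical average is perfect by construction, and functional alignment
cannot beat it — the ordering reverses as `jitter_maps()` displaces the
maps entering the average by a smooth seeded warp of increasing scale.
`leave_one_out_experiment()` runs the full protocol over every held-out
participant and movie, averages within participant across movies, and
bootstraps the Fisher-Z differences (real vs flipped, anatomical vs real).

## What the synthetic tests do and do not show

The generator reproduces the *statistical structure* the analyses assume:
shared low-rank stimulus drive, map-shaped spatial loadings, hierarchical
area similarity, hemispheric mirror symmetry, voxel-scale noise, and a
motion confound. It does not emulate hemodynamic convolution beyond an
integer-TR shift, eye movements, biological hemispheric asymmetry, surface
geometry, or the visual statistics of any actual movie. Passing tests
therefore demonstrate that the pipeline recovers known structure under the
stated generative assumptions at desk scale — not that any particular real
dataset satisfies those assumptions.

Problem sizes in the test suite (cohorts of 1-15 participants, one or two
movies of 150 timepoints, 2048 units, 10-25 replicate seeds) are the
package's chosen desk-scale study conditions; they keep every stage exactly
reproducible from a single master seed.

## Known limitations

* The selection surrogate is a fixed-threshold scorer; it does not model
  coder variability, and its specificity is bounded by structure the
  generator shares between maps and area signatures (an occasional
  transposed area-signature drift is indistinguishable from an eccentricity
  gradient at profile level).
* The percentile bootstrap is mildly anti-conservative at small n (see
  above).
* Meridian-map recovery through ICA is weak at realistic noise; the
  spatial-frequency map carries most of the planted-recovery evidence.
* Real-data adapters accept externally preprocessed matrices only;
  acquisition, registration and surface reconstruction are out of scope.
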